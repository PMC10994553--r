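# Omics-block preprocessing: log2 transform, unit-variance standardization
# with train/test semantics, low-variance filtering and iterative-SVD
# imputation.
#
# An omics block is a tibble whose first column (`sample_id`) holds sample
# identifiers and whose remaining columns are numeric molecule abundances.
# Two attributes track state: `log_scale` (values are log2 abundances) and
# `standardized` (columns were unit-variance scaled).

#' Read an abundance table
#'
#' Reads a delimited text table with samples in rows: first column sample id,
#' header row of molecule identifiers. The delimiter is auto-detected among
#' tab and comma.
#'
#' @param path File path.
#' @param omics_label Optional label for the omics type (stored as the
#'   `"omics_label"` attribute).
#' @return An omics block tibble.
#' @export
read_omics <- function(path, omics_label = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
               lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))) {
    "\t"
  } else {
    ","
  }
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(out)[1] <- "sample_id"
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) rlang::abort("Duplicate sample ids.")
  attr(out, "omics_label") <- omics_label
  out
}

#' Write an abundance table
#'
#' @param block An omics block tibble.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_omics <- function(block, path, delim = "\t") {
  readr::write_delim(block, path, delim = delim)
  invisible(path)
}

#' Log2-transform an abundance block
#'
#' @param block An omics block tibble of strictly positive raw abundances.
#' @return The block with all feature columns log2-transformed and the
#'   `log_scale` attribute set.
#' @export
log2_transform <- function(block) {
  if (isTRUE(attr(block, "log_scale"))) {
    rlang::abort("Block is already flagged as log-scale.")
  }
  m <- block_to_matrix(block)
  bad <- colnames(m)[apply(m, 2, function(x) any(x <= 0, na.rm = TRUE))]
  if (length(bad) > 0) {
    rlang::abort(paste0("Non-positive values in features: ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        if (length(bad) > 5) ", ..."))
  }
  out <- matrix_to_block(log2(m))
  attributes(out)[c("omics_label")] <- attributes(block)[c("omics_label")]
  attr(out, "log_scale") <- TRUE
  out
}

#' Fit a unit-variance standardizer
#'
#' Learns per-feature means and standard deviations (sample sd, `n - 1`
#' denominator) from a fitting set. Apply the fitted object to held-out data
#' with [apply_standardizer()] so that test samples are scaled with training
#' parameters only (no leakage).
#'
#' @param block The fitting omics block (>= 2 samples, no missing values).
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(block) {
  m <- block_to_matrix(block)
  if (nrow(m) < 2) rlang::abort("Need at least 2 samples to fit.")
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  zero <- colnames(m)[sdv == 0 | !is.finite(sdv)]
  if (length(zero) > 0) {
    rlang::abort(paste0("Zero-variance features at fit: ",
                        paste(utils::head(zero, 5), collapse = ", "),
                        if (length(zero) > 5) ", ..."))
  }
  structure(list(mean = mu, sd = sdv, features = colnames(m)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std A `standardizer` from [fit_standardizer()].
#' @param block An omics block containing all fitted features.
#' @return The standardized block (features in the fitted order) with the
#'   `standardized` attribute set.
#' @export
apply_standardizer <- function(std, block) {
  stopifnot(inherits(std, "standardizer"))
  m <- block_to_matrix(block)
  missing <- setdiff(std$features, colnames(m))
  if (length(missing) > 0) {
    rlang::abort(paste0("Features absent from block: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- m[, std$features, drop = FALSE]
  z <- sweep(sweep(m, 2, std$mean, "-"), 2, std$sd, "/")
  out <- matrix_to_block(z)
  attr(out, "omics_label") <- attr(block, "omics_label")
  attr(out, "log_scale") <- attr(block, "log_scale")
  attr(out, "standardized") <- TRUE
  out
}

#' Standardize a block in one step
#'
#' Convenience wrapper fitting on and applying to the same block.
#'
#' @inheritParams fit_standardizer
#' @return The standardized block.
#' @export
standardize <- function(block) {
  apply_standardizer(fit_standardizer(block), block)
}

#' Impute missing values by iterative truncated SVD
#'
#' Missing entries are initialised at column means, then refined by
#' repeatedly replacing them with their rank-`rank` SVD reconstruction until
#' successive imputations differ by less than `tol` in Frobenius norm.
#' Observed entries are never altered.
#'
#' @param block An omics block with `NA`s marking missing values.
#' @param rank Reconstruction rank; default `min(10, N - 1, M - 1)`.
#' @param max_iter Maximum number of refinement iterations (default 100).
#' @param tol Frobenius-norm convergence tolerance (default 1e-5).
#' @return The completed block.
#' @export
svd_impute <- function(block, rank = NULL, max_iter = 100, tol = 1e-5) {
  m <- block_to_matrix(block)
  n <- nrow(m); p <- ncol(m)
  if (is.null(rank)) rank <- max(1L, min(10L, n - 1L, p - 1L))
  if (rank >= min(n, p)) {
    rlang::abort("`rank` must be smaller than min(n_samples, n_features).")
  }
  miss <- is.na(m)
  if (!any(miss)) return(block)
  all_col <- colnames(m)[colSums(miss) == n]
  all_row <- rownames(m)[rowSums(miss) == p]
  if (length(all_col) > 0 || length(all_row) > 0) {
    rlang::abort("Fully missing rows/columns cannot be imputed.")
  }
  x <- m
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(p)) x[miss[, j], j] <- mu[j]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sv <- svd(x, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- sqrt(sum((recon[miss] - x[miss])^2))
    x[miss] <- recon[miss]
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(paste0("svd_impute did not converge in ", max_iter,
                       " iterations; returning last iterate."))
  }
  out <- matrix_to_block(x)
  for (a in c("omics_label", "log_scale", "standardized")) {
    attr(out, a) <- attr(block, a)
  }
  out
}

#' Drop low-variance features
#'
#' Removes features whose variance falls below the given percentile of the
#' per-feature variance distribution (e.g. 25 to drop the least variable
#' quartile of transcripts).
#'
#' @param block An omics block.
#' @param percentile Percentile cut in `[0, 100)`; 0 keeps everything.
#' @return The filtered block.
#' @export
filter_low_variance <- function(block, percentile) {
  stopifnot(percentile >= 0, percentile < 100)
  m <- block_to_matrix(block)
  v <- apply(m, 2, stats::var)
  cut <- stats::quantile(v, percentile / 100, names = FALSE)
  keep <- v >= cut
  out <- matrix_to_block(m[, keep, drop = FALSE])
  for (a in c("omics_label", "log_scale", "standardized")) {
    attr(out, a) <- attr(block, a)
  }
  out
}

#' Align omics blocks on shared samples
#'
#' Restricts every block (and optionally the outcome table) to the
#' intersection of sample ids, ordered as in the first block. Pathway-level
#' integration requires all omics measured on the same individuals; samples
#' missing from any block are dropped with a message.
#'
#' @param blocks A named list of omics block tibbles.
#' @param y Optional outcome vector named by sample id, or a tibble whose
#'   first column is `sample_id`.
#' @return A list with elements `blocks` (aligned list) and `y` (aligned
#'   outcome or `NULL`).
#' @export
align_samples <- function(blocks, y = NULL) {
  blocks <- as_block_list(blocks)
  ids <- lapply(blocks, function(b) as.character(b[[1]]))
  shared <- Reduce(intersect, ids)
  dropped <- length(unique(unlist(ids))) - length(shared)
  if (dropped > 0) {
    rlang::inform(paste0("Dropping ", dropped,
                         " sample(s) not present in every block."))
  }
  shared <- ids[[1]][ids[[1]] %in% shared]
  blocks <- lapply(blocks, function(b) b[match(shared, b[[1]]), , drop = FALSE])
  if (!is.null(y)) {
    if (is.data.frame(y)) {
      y <- y[match(shared, as.character(y[[1]])), , drop = FALSE]
    } else if (!is.null(names(y))) {
      y <- y[shared]
    }
  }
  list(blocks = blocks, y = y)
}

#' Column-concatenate omics blocks
#'
#' Joins blocks on `sample_id` into one wide multi-omics block, the input
#' shape for Single-View pathway scoring.
#'
#' @param blocks A named list of omics block tibbles with identical samples.
#' @return One omics block containing every feature of every block.
#' @export
concat_blocks <- function(blocks) {
  blocks <- as_block_list(blocks)
  mats <- lapply(blocks, block_to_matrix)
  ids <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), ids)) {
      rlang::abort("Blocks must share identical, ordered sample ids; run align_samples() first.")
    }
  }
  all_feats <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_feats)) {
    rlang::abort("Feature ids collide across blocks.")
  }
  out <- matrix_to_block(do.call(cbind, mats))
  attr(out, "standardized") <- all(vapply(
    blocks, function(b) isTRUE(attr(b, "standardized")), logical(1)))
  out
}
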