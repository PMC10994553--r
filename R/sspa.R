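# Single-sample pathway analysis (ssPA): per-pathway transforms that turn a
# standardized sample-by-molecule matrix into a sample-by-pathway activity
# score matrix.
#
# Two methods are provided. "svd" is PLAGE-style scoring: for each pathway
# the columns of its member molecules form a submatrix Z_i and the pathway
# activity is the projection of the (column-centred) Z_i onto its top
# right-singular direction, i.e. the first principal-component score.
# "kpca" scores each pathway by the first component of RBF kernel PCA on
# Z_i, capturing non-linear coordination among members. Both have strict
# fit/transform semantics so held-out samples are scored with training-set
# statistics only.

# sign convention: orient a loading vector so the sum of entries is
# positive; if the sum is (numerically) zero, make the largest-magnitude
# entry positive. Deterministic, and for coherent pathways higher score
# means higher average member abundance.
fix_sign <- function(v, tol = 1e-12) {
  s <- sum(v)
  if (s > tol) return(1)
  if (s < -tol) return(-1)
  if (v[which.max(abs(v))] >= 0) 1 else -1
}

rbf_kernel <- function(x, y = NULL, gamma) {
  y <- y %||% x
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a single-sample pathway analysis transformer
#'
#' Fits per-pathway scoring state on a standardized omics block (possibly
#' the column-concatenation of several blocks, so pathways may span omics).
#' Pathways are restricted to their members present in the block; those
#' covered by fewer than `min_coverage` molecules are excluded with a
#' warning.
#'
#' @param block A standardized omics block tibble.
#' @param pathways A pathway collection tibble (see [read_gmt()]).
#' @param method `"svd"` (PLAGE first principal component) or `"kpca"`
#'   (first RBF kernel-PCA component).
#' @param min_coverage Minimum observed members per pathway (default 2).
#' @param gamma RBF kernel width for `"kpca"`; default `1 / L_i` per pathway
#'   (the usual scale-free heuristic in the submatrix dimension).
#' @return An object of class `sspa_transformer`.
#' @export
fit_sspa <- function(block, pathways, method = c("svd", "kpca"),
                     min_coverage = 2, gamma = NULL) {
  method <- match.arg(method)
  check_collection(pathways)
  m <- block_to_matrix(block)
  flt <- filter_coverage(pathways, colnames(m), min_coverage = min_coverage)
  n_dropped <- nrow(pathways) - nrow(flt)
  if (n_dropped > 0) {
    rlang::warn(paste0(n_dropped, " pathway(s) below coverage ",
                       min_coverage, " excluded."))
  }
  if (nrow(flt) == 0) rlang::abort("No pathway passes the coverage filter.")
  states <- vector("list", nrow(flt))
  for (i in seq_len(nrow(flt))) {
    feats <- flt$members[[i]]
    z <- m[, feats, drop = FALSE]
    ctr <- colMeans(z)
    zc <- sweep(z, 2, ctr, "-")
    constant <- all(abs(zc) < 1e-12)
    if (method == "svd") {
      if (constant) {
        rlang::warn(paste0("Constant submatrix for pathway ",
                           flt$pathway_id[i], "; scores set to zero."))
        v <- rep(1 / sqrt(length(feats)), length(feats))
        states[[i]] <- list(members = feats, center = ctr, direction = v,
                            d1 = 0, constant = TRUE)
      } else {
        sv <- svd(zc, nu = 0, nv = 1)
        v <- drop(sv$v)
        v <- v * fix_sign(v)
        states[[i]] <- list(members = feats, center = ctr, direction = v,
                            d1 = sv$d[1], constant = FALSE)
      }
    } else {
      g <- if (is.null(gamma)) 1 / length(feats) else gamma
      if (constant) {
        rlang::warn(paste0("Constant submatrix for pathway ",
                           flt$pathway_id[i], "; scores set to zero."))
        states[[i]] <- list(members = feats, train = z, gamma = g,
                            constant = TRUE)
      } else {
        k <- rbf_kernel(z, gamma = g)
        n <- nrow(k)
        km <- colMeans(k)
        ka <- mean(k)
        kc <- k - matrix(km, n, n, byrow = TRUE) -
          matrix(km, n, n) + ka
        eg <- eigen(kc, symmetric = TRUE)
        lambda <- eg$values[1]
        vec <- eg$vectors[, 1]
        if (vec[which.max(abs(vec))] < 0) vec <- -vec
        states[[i]] <- list(members = feats, train = z, gamma = g,
                            col_means = km, all_mean = ka,
                            eigvec = vec, eigval = lambda, constant = FALSE)
      }
    }
  }
  structure(list(method = method,
                 pathway_id = flt$pathway_id,
                 pathway_name = flt$pathway_name,
                 coverage = flt$coverage,
                 states = states,
                 min_coverage = min_coverage),
            class = "sspa_transformer")
}

#' @export
print.sspa_transformer <- function(x, ...) {
  cat("ssPA transformer (", x$method, "), ", length(x$pathway_id),
      " pathways\n", sep = "")
  invisible(x)
}

#' Compute pathway activity scores from a fitted ssPA transformer
#'
#' Scores new samples with training-set statistics only: SVD scoring centres
#' the pathway submatrix with training column means before projecting onto
#' the stored direction; kernel-PCA scoring double-centres the train/new
#' cross-kernel with training centering statistics before projecting onto
#' the stored eigenvector.
#'
#' @param transformer A fitted `sspa_transformer`.
#' @param block A block standardized with the *training* standardizer,
#'   containing all member features of every fitted pathway.
#' @return A pathway score tibble: `sample_id` plus one column per pathway.
#' @export
transform_sspa <- function(transformer, block) {
  stopifnot(inherits(transformer, "sspa_transformer"))
  m <- block_to_matrix(block)
  p <- length(transformer$pathway_id)
  scores <- matrix(0, nrow(m), p,
                   dimnames = list(rownames(m), transformer$pathway_id))
  for (i in seq_len(p)) {
    st <- transformer$states[[i]]
    missing <- setdiff(st$members, colnames(m))
    if (length(missing) > 0) {
      rlang::abort(paste0("Pathway ", transformer$pathway_id[i],
                          " is missing features: ",
                          paste(utils::head(missing, 5), collapse = ", ")))
    }
    z <- m[, st$members, drop = FALSE]
    if (isTRUE(st$constant)) next
    if (transformer$method == "svd") {
      zc <- sweep(z, 2, st$center, "-")
      scores[, i] <- zc %*% st$direction
    } else {
      kn <- rbf_kernel(z, st$train, gamma = st$gamma)
      knc <- kn - rowMeans(kn) -
        matrix(st$col_means, nrow(kn), ncol(kn), byrow = TRUE) + st$all_mean
      scores[, i] <- knc %*% (st$eigvec / sqrt(st$eigval))
    }
  }
  out <- matrix_to_block(scores)
  attr(out, "sspa_method") <- transformer$method
  out
}

#' @rdname transform_sspa
#' @param object,... Method arguments (`predict` dispatch).
#' @param newdata Block to score.
#' @export
predict.sspa_transformer <- function(object, newdata, ...) {
  transform_sspa(object, newdata)
}

#' Per-molecule loadings of a pathway's first principal component
#'
#' For SVD-scored pathways, the entries of the stored unit direction measure
#' each member molecule's contribution to the pathway activity score.
#' Kernel-PCA scores have no per-molecule loadings.
#'
#' @param transformer A fitted `sspa_transformer` with `method = "svd"`.
#' @param pathway_id Pathway to query.
#' @return A tibble with columns `molecule` and `loading`.
#' @export
molecule_loadings <- function(transformer, pathway_id) {
  stopifnot(inherits(transformer, "sspa_transformer"))
  if (transformer$method != "svd") {
    rlang::abort("Molecule loadings are only defined for the svd method.")
  }
  i <- match(pathway_id, transformer$pathway_id)
  if (is.na(i)) rlang::abort(paste0("Unknown pathway: ", pathway_id))
  st <- transformer$states[[i]]
  tibble::tibble(molecule = st$members, loading = st$direction)
}

#' Bootstrap stability of per-molecule loadings
#'
#' Resamples samples with replacement, refits the SVD scoring for one
#' pathway per replicate, sign-aligns each replicate direction to the
#' full-data direction, and summarises each molecule's loading across
#' replicates.
#'
#' @param block A standardized omics block.
#' @param pathways A pathway collection.
#' @param pathway_id Pathway to bootstrap.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Random seed.
#' @return A tibble with columns `molecule`, `mean` and `sd` plus an
#'   `n_used` attribute counting non-degenerate replicates.
#' @export
bootstrap_loadings <- function(block, pathways, pathway_id, n_boot = 200,
                               seed = NULL) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  m <- block_to_matrix(block)
  row <- pathways[pathways$pathway_id == pathway_id, ]
  if (nrow(row) != 1) rlang::abort(paste0("Unknown pathway: ", pathway_id))
  feats <- intersect(row$members[[1]], colnames(m))
  if (length(feats) < 2) rlang::abort("Pathway needs >= 2 covered members.")
  z <- m[, feats, drop = FALSE]
  zc <- sweep(z, 2, colMeans(z), "-")
  full <- svd(zc, nu = 0, nv = 1)$v[, 1]
  full <- full * fix_sign(full)
  reps <- matrix(NA_real_, n_boot, length(feats))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(z), replace = TRUE)
    zb <- z[idx, , drop = FALSE]
    sds <- apply(zb, 2, stats::sd)
    if (any(sds == 0)) {
      skipped <- skipped + 1L
      next
    }
    zbc <- sweep(zb, 2, colMeans(zb), "-")
    v <- svd(zbc, nu = 0, nv = 1)$v[, 1]
    if (sum(v * full) < 0) v <- -v
    reps[b, ] <- v
  }
  if (skipped > 0) {
    rlang::warn(paste0(skipped,
                       " degenerate bootstrap replicate(s) skipped."))
  }
  out <- tibble::tibble(
    molecule = feats,
    mean = colMeans(reps, na.rm = TRUE),
    sd = apply(reps, 2, stats::sd, na.rm = TRUE)
  )
  attr(out, "n_used") <- n_boot - skipped
  out
}
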