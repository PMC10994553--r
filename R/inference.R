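# Permutation-based empirical p-values for feature-importance statistics,
# multiple-testing correction, bootstrap block importances and
# superscore-metadata correlation screening.

#' Permutation empirical p-values for a feature-importance statistic
#'
#' Shuffles the outcome labels `n_perm` times, refits the statistic each
#' time, and computes per-feature p-values by the counting rule
#' `p = #(permuted >= observed) / n_perm` — deliberately without the
#' `+1/(n+1)` small-sample correction, so p-values live exactly on the
#' `1/n_perm` grid and a statistic above every permuted value yields p = 0
#' (report such entries as `< 1/n_perm`). Benjamini-Hochberg FDR adjustment
#' is applied across features. With the conventional 10,000 permutations
#' the resolution is 0.0001.
#'
#' @param fit_fn Function `(blocks, y) -> named numeric vector` of
#'   per-feature statistics (e.g. MB-VIP values); must be deterministic
#'   given its inputs.
#' @param blocks Predictor blocks passed through to `fit_fn`.
#' @param y Outcome vector to permute.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Random seed.
#' @return An object of class `permutation_result`: a tibble with columns
#'   `feature`, `statistic`, `n_ge` (count of permuted values >= observed),
#'   `p_value`, `p_adjusted`, with attributes `n_perm` and `seed`.
#' @export
permutation_pvalues <- function(fit_fn, blocks, y, n_perm = 10000,
                                seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  observed <- fit_fn(blocks, y)
  if (is.null(names(observed))) {
    names(observed) <- paste0("feature", seq_along(observed))
  }
  counts <- integer(length(observed))
  yv <- if (is.data.frame(y)) y[[ncol(y)]] else y
  for (b in seq_len(n_perm)) {
    stat <- NULL
    for (attempt in 1:4) {
      yp <- sample(yv)
      stat <- tryCatch(fit_fn(blocks, yp), error = function(e) NULL)
      if (!is.null(stat)) break
      if (attempt == 4) {
        rlang::abort("fit_fn failed on 4 consecutive permutations.")
      }
    }
    counts <- counts + (stat >= observed)
  }
  p <- unname(counts) / n_perm
  out <- tibble::tibble(
    feature = names(observed),
    statistic = as.numeric(observed),
    n_ge = unname(counts),
    p_value = p,
    p_adjusted = bh_fdr(p)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permutation_result", class(out))
  out
}

#' Permutation p-values for MB-VIP pathway importances
#'
#' Convenience wrapper around [permutation_pvalues()] using the MB-VIP
#' statistic of an MB-PLS model refitted per label shuffle.
#'
#' @param blocks Pathway score blocks (list of tibbles).
#' @param y Outcome.
#' @param ncomp Latent variables for each refit (default 1).
#' @param n_perm,seed Passed to [permutation_pvalues()].
#' @return A `permutation_result` tibble.
#' @export
permute_mb_vip <- function(blocks, y, ncomp = 1, n_perm = 10000,
                           seed = NULL) {
  blocks <- lapply(as_block_list(blocks), block_to_matrix)
  fit_fn <- function(b, yy) {
    mod <- fit_mbpls(b, yy, ncomp = ncomp)
    w_all <- do.call(rbind, mod$w_blocks)
    stats::setNames(vip_core(w_all, mod$ssy, length(mod$block_index)),
                    unlist(mod$feature_names))
  }
  permutation_pvalues(fit_fn, blocks, y, n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  check_pvals(pvals)
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni adjustment
#'
#' `min(p * m, 1)` with `m = length(pvals)`.
#'
#' @inheritParams bh_fdr
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals) {
  check_pvals(pvals)
  stats::p.adjust(pvals, method = "bonferroni")
}

check_pvals <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  invisible(pvals)
}

#' Bootstrap distribution of MB-PLS block importances
#'
#' Resamples samples with replacement, refits the MB-PLS model per
#' replicate, aligns each replicate's latent variables to the full-data
#' model by maximal absolute superscore correlation, and summarises each
#' block's per-LV importance by its mean and standard error of the mean.
#'
#' @param blocks Pathway score blocks.
#' @param y Binary outcome.
#' @param ncomp Latent variables (default 1).
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Random seed.
#' @return A tibble: `lv`, `block`, `mean`, `sem`, `n_boot`.
#' @export
bootstrap_block_importance <- function(blocks, y, ncomp = 1, n_boot = 100,
                                       seed = NULL) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  blocks <- as_block_list(blocks)
  full <- fit_mbpls(blocks, y, ncomp = ncomp)
  yv <- if (is.data.frame(y)) y[[ncol(y)]] else y
  n <- nrow(blocks[[1]])
  res <- array(NA_real_, c(n_boot, length(blocks), ncomp))
  for (b in seq_len(n_boot)) {
    fit <- NULL
    for (attempt in 1:6) {
      idx <- sample.int(n, replace = TRUE)
      yb <- yv[idx]
      if (length(unique(yb)) < 2) next
      bb <- lapply(blocks, function(bl) bl[idx, , drop = FALSE])
      fit <- tryCatch(fit_mbpls(bb, yb, ncomp = ncomp),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      rlang::abort("Could not fit a bootstrap replicate after 6 attempts.")
    }
    # align replicate LVs to the full model's by |superscore correlation|
    # evaluated on the resampled rows
    ref <- full$superscores[idx, , drop = FALSE]
    perm <- integer(ncomp)
    avail <- seq_len(ncomp)
    for (r in seq_len(ncomp)) {
      cors <- vapply(avail, function(s) {
        suppressWarnings(abs(stats::cor(ref[, r], fit$superscores[, s])))
      }, numeric(1))
      cors[is.na(cors)] <- 0
      pick <- avail[which.max(cors)]
      perm[r] <- pick
      avail <- setdiff(avail, pick)
    }
    res[b, , ] <- fit$superweights[, perm, drop = FALSE]^2
  }
  out <- tidyr::expand_grid(lv = seq_len(ncomp),
                            block = names(blocks))
  out$mean <- as.vector(apply(res, c(2, 3), mean))
  out$sem <- as.vector(apply(res, c(2, 3),
                             function(x) stats::sd(x) / sqrt(length(x))))
  out$n_boot <- n_boot
  out
}

#' Screen superscores against clinical metadata
#'
#' Correlates each latent variable's superscore with each numeric metadata
#' variable (Spearman), Bonferroni-adjusts over all (LV, variable) tests,
#' and flags pairs passing both an absolute-correlation floor and the
#' adjusted significance level.
#'
#' @param model A fitted `mbpls` model.
#' @param metadata A tibble of metadata: optional `sample_id` first column
#'   (ignored for the tests), remaining columns numeric or binary-encoded.
#' @param rho_min Minimum absolute Spearman correlation (default 0.3).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A tibble: `lv`, `variable`, `rho`, `p_value`, `p_adjusted`,
#'   `pass`.
#' @export
correlate_superscores <- function(model, metadata, rho_min = 0.3,
                                  alpha = 0.05) {
  stopifnot(inherits(model, "mbpls"))
  md <- metadata
  if ("sample_id" %in% names(md)) md <- md[setdiff(names(md), "sample_id")]
  if (!all(vapply(md, is.numeric, logical(1)))) {
    rlang::abort("Metadata variables must be numeric or binary-encoded.")
  }
  constant <- names(md)[vapply(md, function(v) {
    all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0
  }, logical(1))]
  for (v in constant) {
    rlang::warn(paste0("Metadata variable '", v,
                       "' is constant; correlation undefined."))
  }
  grid <- tidyr::expand_grid(lv = seq_len(model$ncomp),
                             variable = names(md))
  res <- purrr::pmap_dfr(grid, function(lv, variable) {
    v <- md[[variable]]
    if (variable %in% constant) {
      return(tibble::tibble(lv = lv, variable = variable,
                            rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(model$superscores[, lv], v, method = "spearman"))
    tibble::tibble(lv = lv, variable = variable,
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  ok <- !is.na(res$p_value)
  res$p_adjusted <- NA_real_
  res$p_adjusted[ok] <- pmin(res$p_value[ok] * sum(ok), 1)
  res$pass <- !is.na(res$rho) & abs(res$rho) >= rho_min &
    res$p_adjusted <= alpha
  res
}
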