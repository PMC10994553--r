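# Multi-block partial least squares fitted by NIPALS with superscore
# deflation, plus VIP and MB-VIP feature importances.
#
# Model structure for R latent variables (LVs) over k predictor blocks X_k
# (samples x features, unit-variance columns) and a centred outcome y:
#
#   X_k = T_k V_k' + E_k          block scores and loadings
#   Y   = T_s C'  + F             superscores predict the outcome
#
# Per LV the block weights w_k (unit norm within block) give block scores
# t_k = X_k w_k; the superweights a (unit norm across blocks) combine block
# scores into the superscore t_s = sum_k a_k t_k. Every block and Y are
# deflated by the superscore (the Westerhuis & Coenegracht variant), which
# renders superscores orthogonal across LVs. With k = 1 the model reduces
# exactly to single-block PLS.
#
# Because all blocks share the superscore deflation, the model is
# algebraically a single PLS on the concatenated matrix whose r-th global
# weight stacks a_{k,r} w_{k,r} (itself unit norm), so the usual regression
# form beta = W (P'W)^{-1} C' applies to the concatenation.

#' Fit a multi-block PLS model
#'
#' Fits NIPALS MB-PLS with superscore deflation on one or more predictor
#' blocks (typically pathway score matrices, one per omics view) against a
#' binary or continuous outcome. Binary outcomes are encoded 0/1 and
#' centred (PLS-DA convention).
#'
#' @param blocks A data frame or named list of data frames, first column
#'   `sample_id`, remaining columns unit-variance predictors.
#' @param y Outcome: 2-level factor/character, binary or continuous numeric,
#'   aligned with the block rows.
#' @param ncomp Number of latent variables R (default 2).
#' @param tol Convergence tolerance on the relative superscore change
#'   (default 1e-10).
#' @param max_iter Maximum NIPALS iterations per LV (default 500).
#' @return An object of class `mbpls`.
#' @export
fit_mbpls <- function(blocks, y, ncomp = 2, tol = 1e-10, max_iter = 500) {
  blocks <- as_block_list(blocks)
  mats <- lapply(blocks, block_to_matrix)
  n <- nrow(mats[[1]])
  for (m in mats) stopifnot(nrow(m) == n)
  if (n < 3) rlang::abort("Need at least 3 samples.")
  if (ncomp < 1) rlang::abort("`ncomp` must be >= 1.")
  enc <- encode_outcome(y)
  stopifnot(length(enc$values) == n)
  y_mean <- mean(enc$values)
  yc <- matrix(enc$values - y_mean, ncol = 1)

  xcat <- do.call(cbind, mats)
  jk <- vapply(mats, ncol, integer(1))
  j_total <- sum(jk)
  blk_index <- rep(seq_along(mats), jk)
  x_rank <- qr(xcat)$rank
  if (ncomp > x_rank) {
    rlang::abort(paste0("`ncomp` (", ncomp,
                        ") exceeds the rank of the concatenated blocks (",
                        x_rank, ")."))
  }

  nblk <- length(mats)
  w_blocks <- lapply(seq_len(length(mats)), function(k)
    matrix(0, jk[k], ncomp, dimnames = list(colnames(mats[[k]]), NULL)))
  t_blocks <- lapply(seq_len(nblk), function(i) matrix(0, n, ncomp))
  superw <- matrix(0, nblk, ncomp,
                   dimnames = list(names(blocks), NULL))
  t_super <- matrix(0, n, ncomp)
  u_scores <- matrix(0, n, ncomp)
  cvec <- numeric(ncomp)
  w_global <- matrix(0, j_total, ncomp,
                     dimnames = list(colnames(xcat), NULL))
  p_global <- matrix(0, j_total, ncomp,
                     dimnames = list(colnames(xcat), NULL))
  ssy <- numeric(ncomp)
  iters <- integer(ncomp)

  xd <- mats
  yd <- yc
  for (r in seq_len(ncomp)) {
    u <- yd[, 1]
    if (all(abs(u) < 1e-14)) {
      rlang::abort(paste0("Y fully deflated before LV ", r,
                          "; reduce `ncomp`."))
    }
    ts_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      tk <- matrix(0, n, nblk)
      wk <- vector("list", nblk)
      for (k in seq_len(nblk)) {
        w <- crossprod(xd[[k]], u)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14) {
          rlang::abort(paste0("Degenerate weights in block ", k, " at LV ",
                              r, "."))
        }
        w <- w / nw
        wk[[k]] <- drop(w)
        tk[, k] <- xd[[k]] %*% w
      }
      a <- crossprod(tk, u)
      a <- a / sqrt(sum(a^2))
      ts <- drop(tk %*% a)
      cr <- sum(yd * ts) / sum(ts^2)
      u <- drop(yd %*% cr) / (cr^2)
      if (sqrt(sum((ts - ts_old)^2)) < tol * max(sqrt(sum(ts^2)), 1)) {
        converged <- TRUE
        break
      }
      ts_old <- ts
    }
    if (!converged) {
      rlang::abort(paste0("NIPALS did not converge for LV ", r, " within ",
                          max_iter, " iterations."))
    }
    iters[r] <- it
    # deterministic sign: largest-magnitude superweight entry positive
    if (a[which.max(abs(a))] < 0) {
      a <- -a
      ts <- -ts
      cr <- -cr
      u <- -u
    }
    cr <- sum(yd * ts) / sum(ts^2)
    for (k in seq_len(nblk)) {
      w_blocks[[k]][, r] <- wk[[k]]
      t_blocks[[k]][, r] <- tk[, k]
    }
    superw[, r] <- a
    t_super[, r] <- ts
    u_scores[, r] <- u
    cvec[r] <- cr
    w_global[, r] <- unlist(lapply(seq_len(nblk),
                                   function(k) a[k] * wk[[k]]))
    # deflate everything by the superscore
    ss_before <- sum(yd^2)
    p_r <- numeric(j_total)
    for (k in seq_len(nblk)) {
      pk <- crossprod(xd[[k]], ts) / sum(ts^2)
      p_r[blk_index == k] <- pk
      xd[[k]] <- xd[[k]] - tcrossprod(ts, drop(pk))
    }
    p_global[, r] <- p_r
    yd <- yd - matrix(ts * cr, ncol = 1)
    ssy[r] <- ss_before - sum(yd^2)
  }

  # regression coefficients on the concatenated scale, per component count
  beta_by_ncomp <- vector("list", ncomp)
  for (r in seq_len(ncomp)) {
    wg <- w_global[, seq_len(r), drop = FALSE]
    pg <- p_global[, seq_len(r), drop = FALSE]
    wstar <- wg %*% solve(crossprod(pg, wg))
    beta_by_ncomp[[r]] <- drop(wstar %*% matrix(cvec[seq_len(r)], ncol = 1))
  }

  structure(list(
    ncomp = ncomp,
    block_names = names(blocks),
    feature_names = lapply(mats, colnames),
    block_index = blk_index,
    w_blocks = w_blocks,
    t_blocks = t_blocks,
    superweights = superw,
    superscores = t_super,
    u_scores = u_scores,
    c = cvec,
    w_global = w_global,
    p_global = p_global,
    beta = beta_by_ncomp[[ncomp]],
    beta_by_ncomp = beta_by_ncomp,
    ssy = ssy,
    ssy_cum = sum(ssy),
    ss_total = sum(yc^2),
    y_mean = y_mean,
    y_levels = enc$levels,
    binary = enc$binary,
    iterations = iters,
    n = n
  ), class = "mbpls")
}

#' @export
print.mbpls <- function(x, ...) {
  cat("MB-PLS model: ", length(x$block_names), " block(s), ",
      x$ncomp, " latent variable(s), N = ", x$n, "\n", sep = "")
  cat("Proportion of Y sum of squares explained: ",
      round(x$ssy_cum / x$ss_total, 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted MB-PLS model
#'
#' Applies the regression form of the model (`yhat = X beta + mean`) to new
#' blocks standardized with the training parameters. For binary outcomes
#' the continuous score is the quantity to feed into AUROC; `type = "class"`
#' thresholds it at the midpoint of the encoded class means.
#'
#' @param object A fitted `mbpls` model.
#' @param blocks New data with the training feature sets.
#' @param ncomp Number of LVs to use (default: all fitted).
#' @param type `"response"` (continuous score) or `"class"`.
#' @param ... Unused.
#' @return A numeric vector, or a factor when `type = "class"`.
#' @export
predict.mbpls <- function(object, blocks, ncomp = object$ncomp,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  blocks <- as_block_list(blocks)
  if (length(blocks) != length(object$block_names)) {
    rlang::abort("Number of blocks differs from the fitted model.")
  }
  mats <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    m <- block_to_matrix(blocks[[k]])
    feats <- object$feature_names[[k]]
    missing <- setdiff(feats, colnames(m))
    if (length(missing) > 0) {
      rlang::abort(paste0("Block ", k, " is missing features: ",
                          paste(utils::head(missing, 5), collapse = ", ")))
    }
    mats[[k]] <- m[, feats, drop = FALSE]
  }
  xcat <- do.call(cbind, mats)
  yhat <- drop(xcat %*% object$beta_by_ncomp[[ncomp]]) + object$y_mean
  names(yhat) <- rownames(xcat)
  if (type == "response") return(yhat)
  if (!object$binary) rlang::abort("`type = 'class'` needs a binary outcome.")
  cls <- ifelse(yhat >= 0.5, object$y_levels[2], object$y_levels[1])
  factor(cls, levels = object$y_levels)
}

#' Per-block contribution to the outcome prediction
#'
#' For each latent variable the importance of block k is the squared
#' superweight, so per-LV importances sum to 1. The `"overall"` rows weight
#' the per-LV fractions by each LV's share of the Y sum of squares
#' explained.
#'
#' @param model A fitted `mbpls` model.
#' @param aggregate Include the SSY-weighted overall rows (default TRUE).
#' @return A tibble with columns `lv` (integer, or `NA` for overall rows),
#'   `block` and `importance`.
#' @export
block_importance <- function(model, aggregate = TRUE) {
  stopifnot(inherits(model, "mbpls"))
  per_lv <- tidyr::expand_grid(lv = seq_len(model$ncomp),
                               block = model$block_names)
  per_lv$importance <- as.vector(model$superweights^2)
  if (!aggregate) return(per_lv)
  wts <- model$ssy / model$ssy_cum
  overall <- tibble::tibble(
    lv = NA_integer_,
    block = model$block_names,
    importance = drop(model$superweights^2 %*% wts)
  )
  dplyr::bind_rows(per_lv, overall)
}

vip_core <- function(w, ssy, f) {
  # w: features x R matrix of weights; ssy: per-LV explained Y sum of squares
  drop(sqrt(f * (w^2 %*% ssy) / sum(ssy)))
}

#' Variable importance in projection (single-block PLS)
#'
#' VIP for feature j: `sqrt(J * sum_r(w_rj^2 * SSY_r) / SSY_cum)`, where the
#' weights are those of the deflated matrices (W, not W*). The mean of
#' squared VIPs over all J features is exactly 1, which motivates the
#' common "VIP > 1" screening rule.
#'
#' @param model A fitted `mbpls` model with a single block.
#' @return A tibble with columns `feature`, `block`, `vip` and `rank`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "mbpls"))
  if (length(model$block_names) > 1) {
    rlang::abort("Model has more than one block; use mb_vip().")
  }
  v <- vip_core(model$w_blocks[[1]], model$ssy, length(model$feature_names[[1]]))
  out <- tibble::tibble(feature = model$feature_names[[1]],
                        block = model$block_names[1], vip = v)
  out <- dplyr::arrange(out, dplyr::desc(.data$vip), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' Multi-block variable importance in projection
#'
#' MB-VIP for feature j in block k:
#' `sqrt(f * sum_r(w_krj^2 * SSY_r) / SSY_cum)` with f the total feature
#' count across all blocks, block weights unit-norm within each block and
#' SSY computed from the superscores. The total sum of squared MB-VIPs
#' equals `f * k`, so the mean squared importance per block is 1. With one
#' block MB-VIP coincides with [vip()].
#'
#' @param model A fitted `mbpls` model.
#' @param per_lv If TRUE, also return the per-LV decomposition (column
#'   `lv`), useful for asking which pathways drive each orthogonal latent
#'   variable.
#' @return A tibble with columns `feature`, `block`, `vip` and `rank`
#'   (plus `lv` when `per_lv = TRUE`).
#' @export
mb_vip <- function(model, per_lv = FALSE) {
  stopifnot(inherits(model, "mbpls"))
  f <- length(model$block_index)
  feats <- unlist(model$feature_names)
  blk <- model$block_names[model$block_index]
  w_all <- do.call(rbind, model$w_blocks)
  if (per_lv) {
    out <- purrr::map_dfr(seq_len(model$ncomp), function(r) {
      tibble::tibble(
        feature = feats, block = blk, lv = r,
        vip = drop(sqrt(f * (w_all[, r]^2 * model$ssy[r]) / model$ssy_cum))
      )
    })
    return(out)
  }
  out <- tibble::tibble(feature = feats, block = blk,
                        vip = vip_core(w_all, model$ssy, f))
  out <- dplyr::arrange(out, dplyr::desc(.data$vip), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MB-PLS model into a per-feature table
#'
#' @param x A fitted `mbpls` model.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature`, `block`,
#'   `estimate` (regression coefficient on the standardized scale) and
#'   `vip` (MB-VIP).
#' @export
tidy.mbpls <- function(x, ...) {
  imp <- mb_vip(x)
  tibble::tibble(
    feature = unlist(x$feature_names),
    block = x$block_names[x$block_index],
    estimate = x$beta
  ) |>
    dplyr::left_join(imp[, c("feature", "vip")], by = "feature")
}

#' One-row summary of an MB-PLS model
#'
#' @param x A fitted `mbpls` model.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_blocks`, `n_features`, `ncomp`,
#'   `prop_y_explained`.
#' @export
glance.mbpls <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_blocks = length(x$block_names),
    n_features = length(x$block_index),
    ncomp = x$ncomp,
    prop_y_explained = x$ssy_cum / x$ss_total
  )
}
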