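# Single-View modelling: one multi-omics pathway score matrix, one
# pluggable predictor. The omics blocks are column-concatenated so that a
# pathway's submatrix can mix molecules from different omics (a metabolite
# and a protein of the same pathway end up in the same Z_i), then a single
# predictive model f(A; theta) is fitted on the resulting score matrix A.

#' Specify a predictor for Single-View modelling
#'
#' Defines the supervised model applied to the pathway score matrix. Built
#' in: `"pls"` (single-block PLS, importance = VIP), `"random_forest"`
#' (importance = normalized mean decrease in Gini impurity), `"logistic"`
#' (importance = absolute standardized coefficient). `"custom"` takes
#' user-supplied `fit_fn(x, y)`, `predict_fn(fit, x)` and optionally
#' `importance_fn(fit)` (feature-named numeric vector).
#'
#' Random-forest defaults follow commonly tuned values for pathway-score
#' inputs: 200 trees, minimum node size 4, bootstrap sampling.
#'
#' @param kind One of `"pls"`, `"random_forest"`, `"logistic"`, `"custom"`.
#' @param ncomp Latent variables for `"pls"` (default 2).
#' @param ntree,nodesize,maxnodes Random-forest hyperparameters.
#' @param fit_fn,predict_fn,importance_fn Functions for `"custom"`.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(kind = c("pls", "random_forest", "logistic",
                                    "custom"),
                           ncomp = 2, ntree = 200, nodesize = 4,
                           maxnodes = NULL,
                           fit_fn = NULL, predict_fn = NULL,
                           importance_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && (is.null(fit_fn) || is.null(predict_fn))) {
    rlang::abort("Custom predictors need `fit_fn` and `predict_fn`.")
  }
  structure(list(kind = kind, ncomp = ncomp, ntree = ntree,
                 nodesize = nodesize, maxnodes = maxnodes,
                 fit_fn = fit_fn, predict_fn = predict_fn,
                 importance_fn = importance_fn),
            class = "predictor_spec")
}

fit_predictor <- function(spec, scores, y) {
  stopifnot(inherits(spec, "predictor_spec"))
  x <- block_to_matrix(scores)
  enc <- encode_outcome(y)
  fit <- switch(
    spec$kind,
    pls = fit_mbpls(list(scores = scores), y,
                    ncomp = min(spec$ncomp, qr(x)$rank)),
    random_forest = {
      yy <- if (enc$binary) factor(enc$values, levels = c(0, 1)) else
        enc$values
      randomForest::randomForest(
        x = x, y = yy, ntree = spec$ntree, nodesize = spec$nodesize,
        maxnodes = spec$maxnodes)
    },
    logistic = {
      df <- data.frame(.y = enc$values, x, check.names = FALSE)
      fam <- if (enc$binary) stats::binomial() else stats::gaussian()
      suppressWarnings(stats::glm(.y ~ ., data = df, family = fam))
    },
    custom = spec$fit_fn(x, enc$values)
  )
  list(spec = spec, fit = fit, encoding = enc, features = colnames(x))
}

predict_predictor <- function(pred, scores) {
  x <- block_to_matrix(scores)
  missing <- setdiff(pred$features, colnames(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing score columns: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- x[, pred$features, drop = FALSE]
  out <- switch(
    pred$spec$kind,
    pls = predict(pred$fit, list(scores = matrix_to_block(x))),
    random_forest = {
      if (pred$encoding$binary) {
        stats::predict(pred$fit, x, type = "prob")[, "1"]
      } else {
        stats::predict(pred$fit, x)
      }
    },
    logistic = stats::predict(pred$fit,
                              data.frame(x, check.names = FALSE),
                              type = "response"),
    custom = pred$spec$predict_fn(pred$fit, x)
  )
  out <- as.numeric(out)
  names(out) <- rownames(x)
  out
}

predictor_importance <- function(pred) {
  switch(
    pred$spec$kind,
    pls = {
      v <- vip(pred$fit)
      stats::setNames(v$vip, v$feature)
    },
    random_forest = {
      gi <- randomForest::importance(pred$fit, type = 2)[, 1]
      gi / sum(gi)
    },
    logistic = {
      cf <- stats::coef(pred$fit)
      cf <- cf[setdiff(names(cf), "(Intercept)")]
      names(cf) <- gsub("^`|`$", "", names(cf))
      abs(cf)[pred$features]
    },
    custom = {
      if (is.null(pred$spec$importance_fn)) {
        rlang::abort(paste0(
          "This predictor exposes no importance; use ",
          "permutation_pvalues() with a custom statistic instead."))
      }
      pred$spec$importance_fn(pred$fit)
    }
  )
}

#' Fit a Single-View pathway model
#'
#' Concatenates the omics blocks, fits the ssPA transformer on the
#' concatenation (multi-omics pathway scoring), and fits the chosen
#' predictor on the pathway score matrix.
#'
#' @param blocks A data frame or named list of standardized omics blocks
#'   sharing sample ids.
#' @param y Outcome aligned with the samples.
#' @param pathways A (multi-omics) pathway collection tibble.
#' @param sspa_method `"svd"` or `"kpca"`.
#' @param predictor A [predictor_spec()] (default PLS).
#' @param min_coverage Minimum observed members per pathway (default 2).
#' @return An object of class `singleview`.
#' @export
fit_singleview <- function(blocks, y, pathways, sspa_method = "svd",
                           predictor = predictor_spec("pls"),
                           min_coverage = 2) {
  concat <- concat_blocks(blocks)
  transformer <- fit_sspa(concat, pathways, method = sspa_method,
                          min_coverage = min_coverage)
  scores <- transform_sspa(transformer, concat)
  pred <- fit_predictor(predictor, scores, y)
  structure(list(transformer = transformer, predictor = pred,
                 pathway_id = transformer$pathway_id,
                 pathway_name = transformer$pathway_name,
                 scores = scores),
            class = "singleview")
}

#' @export
print.singleview <- function(x, ...) {
  cat("Single-View model (", x$predictor$spec$kind, " on ",
      length(x$pathway_id), " pathway scores)\n", sep = "")
  invisible(x)
}

#' Predict from a Single-View model
#'
#' @param object A fitted `singleview` model.
#' @param blocks New omics blocks (standardized with training parameters).
#' @param ... Unused.
#' @return Named numeric vector of continuous scores.
#' @export
predict.singleview <- function(object, blocks, ...) {
  concat <- concat_blocks(blocks)
  scores <- transform_sspa(object$transformer, concat)
  predict_predictor(object$predictor, scores)
}

#' Ranked pathway importances of a Single-View model
#'
#' The importance metric follows the predictor: VIP for PLS, normalized
#' Gini impurity decrease for random forests, absolute coefficients for
#' logistic regression. Ties are broken by pathway id for determinism.
#'
#' @param model A fitted `singleview` model.
#' @return A tibble: `pathway_id`, `pathway_name`, `importance`, `rank`.
#' @export
pathway_importance <- function(model) {
  stopifnot(inherits(model, "singleview"))
  imp <- predictor_importance(model$predictor)
  out <- tibble::tibble(
    pathway_id = model$pathway_id,
    pathway_name = model$pathway_name,
    importance = as.numeric(imp[model$pathway_id])
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance),
                        .data$pathway_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' @rdname pathway_importance
#' @param x A fitted `singleview` model.
#' @param ... Unused.
#' @export
tidy.singleview <- function(x, ...) pathway_importance(x)

#' @export
glance.singleview <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_pathways = length(x$pathway_id),
    sspa_method = x$transformer$method,
    predictor = x$predictor$spec$kind
  )
}

#' Recursive feature elimination with cross-validation
#'
#' Per fold, repeatedly drops the lowest-importance 10% of remaining score
#' columns (at least one per step) on the training part and records the
#' held-out AUROC at every feature count; the count maximizing the mean CV
#' curve wins, smaller counts winning ties (parsimony). A final elimination
#' pass on the full data returns the selected pathway subset.
#'
#' @param scores A pathway score tibble (`sample_id` + score columns).
#' @param y Binary outcome.
#' @param predictor A [predictor_spec()] with an importance metric.
#' @param n_folds Cross-validation folds (default 5).
#' @param drop_frac Fraction of remaining features dropped per step
#'   (default 0.1).
#' @param seed Random seed.
#' @return A list: `selected` (character vector), `n_selected`, and
#'   `curve` (tibble of `n_features`, `mean_auc`, `sd_auc`).
#' @export
rfe_select <- function(scores, y, predictor = predictor_spec("pls"),
                       n_folds = 5, drop_frac = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- block_to_matrix(scores)
  if (ncol(x) < 2) rlang::abort("Need at least 2 features.")
  if (nrow(x) < n_folds) rlang::abort("Fewer samples than folds.")
  enc <- encode_outcome(y)
  folds <- stratified_folds(y, n_folds)

  elim_path <- function(xm, yy) {
    # returns list of feature sets, from all features down to 1
    sets <- list(colnames(xm))
    feats <- colnames(xm)
    while (length(feats) > 1) {
      pred <- fit_predictor(predictor, matrix_to_block(xm[, feats,
                                                          drop = FALSE]), yy)
      imp <- predictor_importance(pred)
      n_drop <- max(1L, floor(drop_frac * length(feats)))
      drop <- names(sort(imp))[seq_len(n_drop)]
      feats <- setdiff(feats, drop)
      sets[[length(sets) + 1L]] <- feats
    }
    sets
  }

  fold_curves <- list()
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    sets <- elim_path(x[tr, , drop = FALSE], enc$values[tr])
    aucs <- vapply(sets, function(s) {
      pred <- fit_predictor(predictor,
                            matrix_to_block(x[tr, s, drop = FALSE]),
                            enc$values[tr])
      sc <- predict_predictor(pred, matrix_to_block(x[!tr, s, drop = FALSE]))
      rank_auc(enc$values[!tr] == 1, sc)
    }, numeric(1))
    fold_curves[[f]] <- tibble::tibble(
      n_features = lengths(sets), auc = aucs, fold = f)
  }
  curve <- dplyr::bind_rows(fold_curves) |>
    dplyr::group_by(.data$n_features) |>
    dplyr::summarise(mean_auc = mean(.data$auc),
                     sd_auc = stats::sd(.data$auc), .groups = "drop") |>
    dplyr::arrange(.data$n_features)
  best_auc <- max(curve$mean_auc)
  n_best <- min(curve$n_features[curve$mean_auc == best_auc])

  full_sets <- elim_path(x, enc$values)
  sel <- full_sets[[which(lengths(full_sets) == n_best)[1]]]
  list(selected = sel, n_selected = n_best, curve = curve)
}
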