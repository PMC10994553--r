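# Semi-synthetic spike-in benchmarking: a synthetic multi-omics base-data
# generator, constant-log2-effect spike-in realisations with a known target
# pathway, the univariate pathway-vs-molecular power experiment,
# leakage-safe repeated-CV AUROC, nested latent-variable selection and
# target-pathway detection scoring.

#' Generate a synthetic multi-omics base dataset
#'
#' Builds k omics blocks over shared samples from a correlated Gaussian
#' factor model: each pathway owns a latent factor and its member features
#' load on it so that any two same-pathway features correlate at `rho`
#' (plus an optional global factor inducing correlation `cross_block_rho`
#' between all features, including across blocks). Features are on a log2
#' abundance scale by construction; each block is unit-variance
#' standardized. The matching pathway collection (with optional membership
#' overlap between neighbouring pathways) and a balanced binary outcome
#' carrying no signal complete the base dataset, ready for [make_realisation()].
#'
#' @param n_samples Number of samples N (default 200).
#' @param n_pathways Number of pathways across all blocks (default 100).
#' @param n_blocks Number of omics blocks (default 2); pathways are
#'   assigned to blocks round-robin.
#' @param pathway_size Integer range `c(min, max)` of molecules per pathway
#'   (default `c(4, 8)`).
#' @param rho Within-pathway correlation in `[0, 1)` (default 0.5).
#' @param cross_block_rho Baseline correlation among all features
#'   (default 0, matching a design with independent omics blocks);
#'   must not exceed `rho`.
#' @param overlap_frac Fraction of pathways that additionally borrow one
#'   member from the next pathway of their block, making pathway sets
#'   overlap (default 0.1).
#' @param block_names Names for the blocks.
#' @param seed Random seed; identical seeds give bit-identical output.
#' @return A list of class `synthetic_base`: `blocks` (named list of
#'   standardized omics block tibbles), `y` (balanced 2-level factor),
#'   `pathways` (collection tibble), and `config`.
#' @export
generate_base <- function(n_samples = 200, n_pathways = 100, n_blocks = 2,
                          pathway_size = c(4, 8), rho = 0.5,
                          cross_block_rho = 0, overlap_frac = 0.1,
                          block_names = paste0("omics", seq_len(n_blocks)),
                          seed = NULL) {
  stopifnot(rho >= 0, rho < 1, cross_block_rho >= 0,
            cross_block_rho <= rho, length(block_names) == n_blocks,
            n_pathways >= n_blocks)
  if (!is.null(seed)) set.seed(seed)
  size_range <- seq(pathway_size[1], pathway_size[2])
  sizes <- size_range[sample.int(length(size_range), n_pathways,
                                 replace = TRUE)]
  home_block <- rep_len(seq_len(n_blocks), n_pathways)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  g_global <- stats::rnorm(n_samples)
  a <- sqrt(cross_block_rho)
  b <- sqrt(rho - cross_block_rho)
  c0 <- sqrt(1 - rho)

  feat_ids <- vector("list", n_pathways)
  blocks <- vector("list", n_blocks)
  cols <- vector("list", n_blocks)
  for (p in seq_len(n_pathways)) {
    k <- home_block[p]
    ids <- sprintf("%s_P%03d_M%02d", block_names[k], p, seq_len(sizes[p]))
    feat_ids[[p]] <- ids
    g_p <- stats::rnorm(n_samples)
    x <- a * g_global + b * g_p +
      c0 * matrix(stats::rnorm(n_samples * sizes[p]), n_samples)
    colnames(x) <- ids
    cols[[k]] <- c(cols[[k]], list(x))
  }
  for (k in seq_len(n_blocks)) {
    m <- do.call(cbind, cols[[k]])
    rownames(m) <- sample_ids
    bl <- standardize(matrix_to_block(m))
    attr(bl, "omics_label") <- block_names[k]
    attr(bl, "log_scale") <- TRUE
    blocks[[k]] <- bl
  }
  names(blocks) <- block_names

  members <- feat_ids
  n_overlap <- floor(overlap_frac * n_pathways)
  if (n_overlap > 0) {
    which_ov <- sample.int(n_pathways, n_overlap)
    for (p in which_ov) {
      same_block <- setdiff(which(home_block == home_block[p]), p)
      if (length(same_block) == 0) next
      donor <- same_block[(match(p, which(home_block == home_block[p])) %%
                             length(same_block)) + 1L]
      members[[p]] <- c(members[[p]], feat_ids[[donor]][1])
    }
  }
  pathways <- tibble::tibble(
    pathway_id = sprintf("PW%03d", seq_len(n_pathways)),
    pathway_name = sprintf("Synthetic pathway %03d (%s)", seq_len(n_pathways),
                           block_names[home_block]),
    members = members
  )
  y <- factor(sample(rep_len(c("control", "case"), n_samples)),
              levels = c("control", "case"))
  structure(list(
    blocks = blocks, y = y, pathways = pathways,
    config = list(n_samples = n_samples, n_pathways = n_pathways,
                  n_blocks = n_blocks, pathway_size = pathway_size,
                  rho = rho, cross_block_rho = cross_block_rho,
                  overlap_frac = overlap_frac, seed = seed)
  ), class = "synthetic_base")
}

#' Create one semi-synthetic spike-in realisation
#'
#' Shuffles the outcome labels (removing any outcome-correlated effects
#' while preserving the molecular covariance structure) and adds a constant
#' `alpha` — a log2 fold change — to the target pathway's covered member
#' molecules in the new case group only, across every block containing
#' them. All other entries are untouched, so the target pathway is the
#' single ground-truth enriched pathway of the realisation.
#'
#' @param base A `synthetic_base` list, or any list with elements `blocks`,
#'   `y` and `pathways` on a log2 scale.
#' @param target_id Pathway id to enrich; must be covered by at least 3
#'   molecules in the data.
#' @param alpha Effect size (log2 fold change) added to case samples.
#' @param seed Random seed for the label shuffle.
#' @return A list of class `semisynth_realisation`: spiked `blocks`,
#'   shuffled `y`, `pathways`, `target_id`, `alpha`.
#' @export
make_realisation <- function(base, target_id, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- base$blocks
  pathways <- base$pathways
  row <- pathways[pathways$pathway_id == target_id, ]
  if (nrow(row) != 1) rlang::abort(paste0("Unknown target: ", target_id))
  all_feats <- unlist(lapply(blocks, function(b) setdiff(names(b),
                                                         "sample_id")))
  covered <- intersect(row$members[[1]], all_feats)
  if (length(covered) < 3) {
    rlang::abort(paste0("Target pathway ", target_id,
                        " has coverage < 3 in the data."))
  }
  y <- base$y
  yv <- if (is.data.frame(y)) y[[ncol(y)]] else y
  y_shuffled <- sample(yv)
  case_level <- levels(factor(yv))[2]
  case_rows <- which(y_shuffled == case_level)
  for (k in seq_along(blocks)) {
    hit <- intersect(covered, names(blocks[[k]]))
    if (length(hit) == 0) next
    for (f in hit) {
      blocks[[k]][[f]][case_rows] <- blocks[[k]][[f]][case_rows] + alpha
    }
  }
  structure(list(blocks = blocks, y = y_shuffled, pathways = pathways,
                 target_id = target_id, alpha = alpha,
                 covered_members = covered, seed = seed),
            class = "semisynth_realisation")
}

#' Create a pathway-free molecular spike-in realisation
#'
#' Database-agnostic variant of [make_realisation()]: instead of enriching
#' a curated pathway, spikes a random set of molecules whose size is drawn
#' from the pathway-size distribution of the supplied collection, so
#' molecular-level simulations remain comparable to pathway-level ones
#' without assuming any pathway membership.
#'
#' @param base A `synthetic_base` list (or list with `blocks`, `y`,
#'   `pathways`).
#' @param alpha Effect size (log2 fold change).
#' @param n_molecules Number of molecules to spike; default: drawn from
#'   the collection's coverage-size distribution.
#' @param seed Random seed.
#' @return A `semisynth_realisation` whose `covered_members` are the
#'   spiked molecules and whose `target_id` is `NA`.
#' @export
make_molecular_realisation <- function(base, alpha, n_molecules = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_feats <- unlist(lapply(base$blocks,
                             function(b) setdiff(names(b), "sample_id")))
  if (is.null(n_molecules)) {
    sizes <- vapply(base$pathways$members,
                    function(m) length(intersect(m, all_feats)),
                    integer(1))
    sizes <- sizes[sizes >= 1]
    n_molecules <- sizes[sample.int(length(sizes), 1)]
  }
  stopifnot(n_molecules >= 1, n_molecules <= length(all_feats))
  chosen <- sample(all_feats, n_molecules)
  blocks <- base$blocks
  yv <- if (is.data.frame(base$y)) base$y[[ncol(base$y)]] else base$y
  y_shuffled <- sample(yv)
  case_rows <- which(y_shuffled == levels(factor(yv))[2])
  for (k in seq_along(blocks)) {
    hit <- intersect(chosen, names(blocks[[k]]))
    for (f in hit) {
      blocks[[k]][[f]][case_rows] <- blocks[[k]][[f]][case_rows] + alpha
    }
  }
  structure(list(blocks = blocks, y = y_shuffled,
                 pathways = base$pathways, target_id = NA_character_,
                 alpha = alpha, covered_members = chosen, seed = seed),
            class = "semisynth_realisation")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two groups: exact enumeration when both
#' groups have fewer than 8 untied values, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b Numeric value vectors for the two groups.
#' @return A one-row tibble with columns `statistic` (U for group `a`) and
#'   `p_value`.
#' @export
mwu_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  use_exact <- (length(a) < 8 || length(b) < 8) &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Conditional Fisher combination of member p-values
#'
#' Combines the molecule-level p-values of a pathway into one pathway-level
#' p-value, gated on pathway-wide support: if at least `frac` of the member
#' p-values reach `sig_threshold` (after Bonferroni adjustment by default),
#' all m member p-values are combined with Fisher's method — the upper-tail
#' chi-square probability of `-2 * sum(log(p))` on 2m degrees of freedom —
#' otherwise the combined p-value is 1.
#'
#' @param pvals Member p-values in `(0, 1]`; zeros are clamped to the
#'   smallest positive double with a warning.
#' @param sig_threshold Per-molecule significance threshold for the gate
#'   (default 0.05).
#' @param frac Minimum significant fraction to open the gate (default 0.5,
#'   inclusive).
#' @param gate Whether the gate checks Bonferroni-`"adjusted"` (default) or
#'   `"raw"` member p-values.
#' @param n_tests Multiplicity for the Bonferroni gate (default: the
#'   number of member p-values; a screening context may pass the total
#'   number of molecules tested).
#' @return The combined p-value (a scalar).
#' @export
fisher_combine_conditional <- function(pvals, sig_threshold = 0.05,
                                       frac = 0.5,
                                       gate = c("adjusted", "raw"),
                                       n_tests = length(pvals)) {
  gate <- match.arg(gate)
  if (length(pvals) == 0) rlang::abort("Empty p-value vector.")
  check_pvals(pvals)
  if (any(pvals == 0)) {
    rlang::warn("p-values of 0 clamped to the smallest positive double.")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  gate_p <- if (gate == "adjusted") pmin(pvals * n_tests, 1) else pvals
  if (mean(gate_p <= sig_threshold) >= frac) {
    stat <- -2 * sum(log(pvals))
    stats::pchisq(stat, df = 2 * length(pvals), lower.tail = FALSE)
  } else {
    1
  }
}

eligible_targets <- function(base, min_members = 3) {
  all_feats <- unlist(lapply(base$blocks,
                             function(b) setdiff(names(b), "sample_id")))
  cov <- vapply(base$pathways$members,
                function(m) length(intersect(m, all_feats)), integer(1))
  base$pathways$pathway_id[cov >= min_members]
}

#' Univariate pathway-level vs molecular-level detection power
#'
#' For a grid of effect sizes, repeatedly spikes a random target pathway
#' and tests for a case-control difference either on the pathway activity
#' score (Mann-Whitney U on the target's ssPA score, Bonferroni-adjusted
#' over all scored pathways) or on the individual member molecules
#' (Mann-Whitney U per molecule, Bonferroni over all molecules measured in
#' the data — the multiplicity a molecular screen carries — then the
#' conditional Fisher combination across the target's members). Reports
#' the fraction of realisations
#' significant at adjusted/combined p <= 0.05. Target pathway and label
#' shuffle are shared across effect sizes within a realisation index, so
#' power curves are paired.
#'
#' @param base A `synthetic_base` dataset.
#' @param alphas Numeric effect-size grid (log2 fold changes).
#' @param level `"pathway"`, `"molecular"`, or both (default).
#' @param n_realisations Realisations per effect size (default 100).
#' @param sspa_method ssPA method for pathway-level scoring (default
#'   `"kpca"`).
#' @param min_coverage Coverage filter for the scored pathway universe
#'   (default 2).
#' @param sig_level Final significance threshold (default 0.05).
#' @param seed Master seed; realisation seeds are derived children.
#' @return A tibble: `level`, `alpha`, `n_significant`, `n_realisations`,
#'   `proportion`.
#' @export
univariate_experiment <- function(base, alphas,
                                  level = c("pathway", "molecular"),
                                  n_realisations = 100,
                                  sspa_method = "kpca", min_coverage = 2,
                                  sig_level = 0.05, seed = NULL) {
  level <- match.arg(level, several.ok = TRUE)
  stopifnot(length(alphas) >= 1)
  targets_ok <- eligible_targets(base)
  if (length(targets_ok) == 0) rlang::abort("No pathway has coverage >= 3.")
  seeds <- child_seeds(seed %||% sample.int(1e6, 1), n_realisations + 1)
  set.seed(seeds[n_realisations + 1])
  targets <- sample(targets_ok, n_realisations, replace = TRUE)

  all_feats <- unlist(lapply(base$blocks,
                             function(b) setdiff(names(b), "sample_id")))
  n_tested <- sum(vapply(base$pathways$members,
                         function(m) length(intersect(m, all_feats)),
                         integer(1)) >= min_coverage)

  grid <- tidyr::expand_grid(level = level, alpha = alphas)
  hits <- matrix(0L, nrow(grid), 1)
  for (i in seq_len(n_realisations)) {
    for (a in alphas) {
      real <- make_realisation(base, targets[i], a, seed = seeds[i])
      concat <- concat_blocks(real$blocks)
      grp <- real$y == levels(factor(real$y))[2]
      if ("pathway" %in% level) {
        z <- standardize(concat)
        target_coll <- real$pathways[
          real$pathways$pathway_id == targets[i], ]
        tr <- suppressWarnings(
          fit_sspa(z, target_coll, method = sspa_method,
                   min_coverage = min_coverage))
        sc <- block_to_matrix(transform_sspa(tr, z))[, 1]
        p <- mwu_test(sc[grp], sc[!grp])$p_value
        p_adj <- min(p * n_tested, 1)
        if (p_adj <= sig_level) {
          j <- which(grid$level == "pathway" & grid$alpha == a)
          hits[j] <- hits[j] + 1L
        }
      }
      if ("molecular" %in% level) {
        m <- block_to_matrix(concat)
        mem <- intersect(real$covered_members, colnames(m))
        pv <- vapply(mem, function(f) {
          mwu_test(m[grp, f], m[!grp, f])$p_value
        }, numeric(1))
        # gate on screening-wide Bonferroni (all measured molecules),
        # combine the raw member p-values
        p_comb <- fisher_combine_conditional(pv, sig_threshold = sig_level,
                                             gate = "adjusted",
                                             n_tests = ncol(m))
        if (p_comb <= sig_level) {
          j <- which(grid$level == "molecular" & grid$alpha == a)
          hits[j] <- hits[j] + 1L
        }
      }
    }
  }
  grid$n_significant <- as.integer(hits)
  grid$n_realisations <- n_realisations
  grid$proportion <- grid$n_significant / n_realisations
  grid
}

# Shared per-fold pipeline: standardize each block on the training rows,
# fit ssPA on the standardized training data, and score train and test.
fold_pathway_scores <- function(blocks, train_idx, pathways, sspa_method,
                                min_coverage, concat = FALSE) {
  if (concat) blocks <- list(all = concat_blocks(blocks))
  train_scores <- vector("list", length(blocks))
  test_scores <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    bl <- blocks[[k]]
    std <- fit_standardizer(bl[train_idx, , drop = FALSE])
    tr <- apply_standardizer(std, bl[train_idx, , drop = FALSE])
    te <- apply_standardizer(std, bl[-train_idx, , drop = FALSE])
    sspa <- suppressWarnings(
      fit_sspa(tr, pathways, method = sspa_method,
               min_coverage = min_coverage))
    train_scores[[k]] <- transform_sspa(sspa, tr)
    test_scores[[k]] <- transform_sspa(sspa, te)
  }
  names(train_scores) <- names(blocks)
  names(test_scores) <- names(blocks)
  list(train = train_scores, test = test_scores)
}

#' Leakage-safe repeated cross-validated AUROC
#'
#' Repeated stratified k-fold cross-validation of the full pathway
#' pipeline. Within every fold, standardization and ssPA are fitted on the
#' training portion only and applied to the held-out portion, then the
#' chosen framework (Multi-View MB-PLS or Single-View predictor) is fitted
#' and the held-out continuous scores are evaluated by AUROC.
#'
#' @param blocks Named list of omics blocks (raw/spiked, log2 scale).
#' @param y Binary outcome.
#' @param pathways Pathway collection.
#' @param framework `"multiview"` or `"singleview"`.
#' @param ncomp Latent variables for the Multi-View MB-PLS (default 1).
#' @param predictor [predictor_spec()] for Single-View (default PLS).
#' @param sspa_method ssPA method (default `"kpca"`).
#' @param n_repeats,n_folds Repeats and folds (defaults 5 and 5).
#' @param min_coverage Pathway coverage filter (default 2).
#' @param seed Random seed.
#' @return A list: `mean_auc`, `ci_lower`, `ci_upper` (normal-approximation
#'   95% CI over fold scores), and `folds` (tibble of per-fold AUCs).
#' @export
cv_auroc <- function(blocks, y, pathways,
                     framework = c("multiview", "singleview"),
                     ncomp = 1, predictor = predictor_spec("pls"),
                     sspa_method = "kpca", n_repeats = 5, n_folds = 5,
                     min_coverage = 2, seed = NULL) {
  framework <- match.arg(framework)
  if (!is.null(seed)) set.seed(seed)
  blocks <- as_block_list(blocks)
  enc <- encode_outcome(y)
  if (!enc$binary) rlang::abort("cv_auroc needs a binary outcome.")
  res <- list()
  for (rep_i in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      train_idx <- which(folds != f)
      sc <- fold_pathway_scores(blocks, train_idx, pathways, sspa_method,
                                min_coverage,
                                concat = framework == "singleview")
      y_train <- enc$values[train_idx]
      y_test <- enc$values[-train_idx]
      if (framework == "multiview") {
        mod <- fit_mbpls(sc$train, y_train, ncomp = ncomp)
        pred <- predict(mod, sc$test)
      } else {
        fitp <- fit_predictor(predictor, sc$train[[1]], y_train)
        pred <- predict_predictor(fitp, sc$test[[1]])
      }
      auc <- as.numeric(pROC::auc(
        response = y_test, predictor = pred,
        levels = c(0, 1), direction = "<", quiet = TRUE))
      res[[length(res) + 1L]] <- tibble::tibble(
        rep = rep_i, fold = f, auc = auc)
    }
  }
  folds_tbl <- dplyr::bind_rows(res)
  m <- mean(folds_tbl$auc)
  se <- stats::sd(folds_tbl$auc) / sqrt(nrow(folds_tbl))
  list(mean_auc = m,
       ci_lower = m - stats::qnorm(0.975) * se,
       ci_upper = m + stats::qnorm(0.975) * se,
       folds = folds_tbl)
}

#' Select the number of latent variables by inner cross-validation
#'
#' Stratified k-fold cross-validation of the Multi-View pipeline over a
#' grid of latent-variable counts. The model is fitted once per fold at the
#' largest grid value and evaluated at every smaller count via truncated
#' prediction. The smallest count whose mean AUC is within one standard
#' error of the maximum is selected.
#'
#' @param blocks,y,pathways,sspa_method,min_coverage,seed As [cv_auroc()].
#' @param ncomp_grid Candidate latent-variable counts (default 1:5).
#' @param n_folds Inner folds (default 5).
#' @return A list: `selected` (integer) and `curve`
#'   (tibble of `ncomp`, `mean_auc`, `se_auc`).
#' @export
nested_lv_selection <- function(blocks, y, pathways, ncomp_grid = 1:5,
                                n_folds = 5, sspa_method = "kpca",
                                min_coverage = 2, seed = NULL) {
  stopifnot(length(ncomp_grid) >= 1)
  if (!is.null(seed)) set.seed(seed)
  blocks <- as_block_list(blocks)
  enc <- encode_outcome(y)
  ncomp_grid <- sort(unique(as.integer(ncomp_grid)))
  r_max <- max(ncomp_grid)
  folds <- stratified_folds(y, n_folds)
  aucs <- matrix(NA_real_, n_folds, length(ncomp_grid))
  for (f in seq_len(n_folds)) {
    train_idx <- which(folds != f)
    sc <- fold_pathway_scores(blocks, train_idx, pathways, sspa_method,
                              min_coverage)
    mod <- fit_mbpls(sc$train, enc$values[train_idx], ncomp = r_max)
    for (j in seq_along(ncomp_grid)) {
      pred <- predict(mod, sc$test, ncomp = ncomp_grid[j])
      aucs[f, j] <- rank_auc(enc$values[-train_idx] == 1, pred)
    }
  }
  curve <- tibble::tibble(
    ncomp = ncomp_grid,
    mean_auc = colMeans(aucs),
    se_auc = apply(aucs, 2, stats::sd) / sqrt(n_folds)
  )
  best <- which.max(curve$mean_auc)
  threshold <- curve$mean_auc[best] - curve$se_auc[best]
  selected <- curve$ncomp[min(which(curve$mean_auc >= threshold))]
  list(selected = selected, curve = curve)
}

#' Score target-pathway detection for one realisation
#'
#' Builds the confusion matrix at adjusted p <= 0.05 — the target pathway
#' is the single positive — and a threshold-free ranking AUC: the fraction
#' of non-target pathways whose p-value is strictly larger than the
#' target's, counting ties as one half (midrank rule, since permutation
#' p-values tie heavily on the `1/n_perm` grid).
#'
#' @param pvals Named numeric vector of adjusted p-values, or a tibble with
#'   a pathway id column (`pathway_id` or `feature`) and `p_adjusted`.
#' @param target_id The ground-truth enriched pathway.
#' @param threshold Significance threshold (default 0.05).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `auc`, `n_pathways`.
#' @export
evaluate_detection <- function(pvals, target_id, threshold = 0.05) {
  if (is.data.frame(pvals)) {
    idcol <- intersect(c("pathway_id", "feature"), names(pvals))[1]
    if (is.na(idcol) || !"p_adjusted" %in% names(pvals)) {
      rlang::abort("Need a pathway id column and a `p_adjusted` column.")
    }
    pv <- stats::setNames(pvals$p_adjusted, pvals[[idcol]])
  } else {
    pv <- pvals
  }
  if (!target_id %in% names(pv)) {
    rlang::abort(paste0("Target ", target_id, " not among tested pathways."))
  }
  p_t <- pv[[target_id]]
  p_others <- pv[setdiff(names(pv), target_id)]
  tp <- as.integer(p_t <= threshold)
  fn <- 1L - tp
  fp <- sum(p_others <= threshold)
  tn <- sum(p_others > threshold)
  auc <- if (length(p_others) == 0) NA_real_ else
    mean((p_others > p_t) + 0.5 * (p_others == p_t))
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, auc = auc,
                 n_pathways = length(pv))
}

#' Classification performance as a function of sample size
#'
#' Subsamples the data to each requested size keeping a 1:1 class ratio and
#' reruns the repeated-CV AUROC pipeline, reporting the mean AUC, its 95%
#' CI and the spread across CV repeats at every size.
#'
#' @param blocks,y,pathways Passed to [cv_auroc()].
#' @param sizes Even total sample sizes; each must satisfy
#'   `size >= 2 * n_folds` and `size / 2` available per class.
#' @param ... Further arguments to [cv_auroc()] (framework, ncomp, ...).
#' @param n_folds Folds (default 5).
#' @param seed Master seed.
#' @return A tibble: `size`, `mean_auc`, `ci_lower`, `ci_upper`,
#'   `sd_repeats`.
#' @export
downsample_experiment <- function(blocks, y, pathways, sizes, ...,
                                  n_folds = 5, seed = NULL) {
  blocks <- as_block_list(blocks)
  yv <- if (is.data.frame(y)) y[[ncol(y)]] else y
  lv <- levels(factor(yv))
  seeds <- child_seeds(seed %||% sample.int(1e6, 1), length(sizes) + 1)
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    size <- sizes[i]
    if (size %% 2 != 0) rlang::abort("Sizes must be even (1:1 classes).")
    if (size < 2 * n_folds) {
      rlang::abort("Each size must be at least 2 * n_folds.")
    }
    per_class <- size / 2
    if (any(table(yv)[lv] < per_class)) {
      rlang::abort("Not enough samples per class for the requested size.")
    }
    set.seed(seeds[i])
    idx <- c(sample(which(yv == lv[1]), per_class),
             sample(which(yv == lv[2]), per_class))
    sub_blocks <- lapply(blocks, function(b) b[idx, , drop = FALSE])
    sub_y <- yv[idx]
    cv <- cv_auroc(sub_blocks, sub_y, pathways, ..., n_folds = n_folds,
                   seed = seeds[i])
    rep_means <- cv$folds |>
      dplyr::group_by(.data$rep) |>
      dplyr::summarise(m = mean(.data$auc), .groups = "drop")
    out[[i]] <- tibble::tibble(
      size = size, mean_auc = cv$mean_auc,
      ci_lower = cv$ci_lower, ci_upper = cv$ci_upper,
      sd_repeats = stats::sd(rep_means$m))
  }
  dplyr::bind_rows(out)
}
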