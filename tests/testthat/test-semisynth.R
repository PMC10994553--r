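# Synthetic base generation, spike-in realisations, the univariate
# pathway-vs-molecular experiment, CV pipelines and detection scoring.

test_that("generate_base is deterministic and honours the correlations", {
  b1 <- generate_base(n_samples = 50, n_pathways = 10, seed = 101)
  b2 <- generate_base(n_samples = 50, n_pathways = 10, seed = 101)
  expect_identical(b1$blocks, b2$blocks)
  expect_identical(b1$pathways, b2$pathways)
  expect_identical(b1$y, b2$y)

  # rho = 0: empirical off-diagonal correlations are small
  b0 <- generate_base(n_samples = 400, n_pathways = 8, rho = 0,
                      overlap_frac = 0, seed = 102)
  m <- pathblend:::block_to_matrix(b0$blocks[[1]])
  cm <- cor(m)
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(400) * 1.6)

  # rho = 0.7: mean within-pathway correlation close to 0.7 at N = 500
  b7 <- generate_base(n_samples = 500, n_pathways = 10, rho = 0.7,
                      overlap_frac = 0, seed = 103)
  within <- unlist(lapply(seq_len(nrow(b7$pathways)), function(i) {
    mem <- b7$pathways$members[[i]]
    k <- which(vapply(b7$blocks, function(b) all(mem %in% names(b)),
                      logical(1)))[1]
    cm <- cor(pathblend:::block_to_matrix(b7$blocks[[k]])[, mem])
    cm[upper.tri(cm)]
  }))
  expect_gt(mean(within), 0.6)
  expect_lt(mean(within), 0.8)

  # balanced outcome, standardized blocks
  expect_equal(unname(table(b1$y)["case"]), 25)
  z <- pathblend:::block_to_matrix(b1$blocks[[1]])
  expect_lt(max(abs(colMeans(z))), 1e-8)
})

test_that("spike-in changes exactly the target entries by exactly alpha", {
  base <- generate_base(n_samples = 40, n_pathways = 8, overlap_frac = 0,
                        seed = 104)
  target <- base$pathways$pathway_id[1]
  members <- base$pathways$members[[1]]

  r0 <- make_realisation(base, target, alpha = 0, seed = 7)
  expect_identical(lapply(r0$blocks, as.data.frame),
                   lapply(base$blocks, as.data.frame))
  expect_false(identical(r0$y, base$y) && all(r0$y == base$y))

  alpha <- 0.5
  r <- make_realisation(base, target, alpha = alpha, seed = 7)
  case_rows <- which(r$y == "case")
  for (k in seq_along(base$blocks)) {
    m0 <- pathblend:::block_to_matrix(base$blocks[[k]])
    m1 <- pathblend:::block_to_matrix(r$blocks[[k]])
    diffm <- m1 - m0
    hit <- intersect(members, colnames(m0))
    expect_equal(unname(diffm[case_rows, hit]),
                 matrix(alpha, length(case_rows), length(hit)))
    diffm[case_rows, hit] <- 0
    expect_true(all(diffm == 0))  # locality: nothing else moved
  }
  # class sizes preserved by the shuffle
  expect_equal(table(r$y), table(base$y))

  small <- base
  small$pathways$members[[2]] <- small$pathways$members[[2]][1:2]
  expect_error(make_realisation(small, small$pathways$pathway_id[2], 1),
               "coverage")
})

test_that("molecular realisations spike sizes from the collection", {
  base <- generate_base(n_samples = 30, n_pathways = 6,
                        pathway_size = c(4, 4), overlap_frac = 0,
                        seed = 130)
  r <- make_molecular_realisation(base, alpha = 1, seed = 131)
  expect_equal(length(r$covered_members), 4)  # all pathways have size 4
  expect_true(is.na(r$target_id))
  m0 <- do.call(cbind, lapply(base$blocks, pathblend:::block_to_matrix))
  m1 <- do.call(cbind, lapply(r$blocks, pathblend:::block_to_matrix))
  changed <- colnames(m0)[colSums(m1 != m0) > 0]
  expect_setequal(changed, r$covered_members)

  r2 <- make_molecular_realisation(base, alpha = 1, n_molecules = 7,
                                   seed = 132)
  expect_equal(length(r2$covered_members), 7)
})

test_that("mwu_test matches exact enumeration and symmetry", {
  same <- mwu_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 3 * 3 / 2)

  sep <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(sep$statistic %in% c(0, 9))
  expect_equal(sep$p_value, 0.1)  # 2/20 arrangements as extreme

  a <- rnorm(10); b <- rnorm(12)
  expect_equal(mwu_test(a, b)$p_value, mwu_test(b, a)$p_value)
})

test_that("conditional Fisher combination applies the 50% gate", {
  expect_equal(fisher_combine_conditional(c(0.5, 0.6, 0.7)), 1)

  # both p = 0.01 significant: -2*sum(log p) = 18.4207 on 4 df
  comb <- fisher_combine_conditional(c(0.01, 0.01))
  stat <- -2 * (log(0.01) + log(0.01))
  expect_equal(stat, 18.42068, tolerance = 1e-5)
  expect_equal(comb, pchisq(stat, df = 4, lower.tail = FALSE))
  expect_equal(comb, 1.02e-3, tolerance = 1e-2)

  # exactly 50% significant opens the gate (inclusive rule); gate on raw p
  at_half <- fisher_combine_conditional(c(0.01, 0.9), gate = "raw")
  expect_lt(at_half, 1)

  expect_error(fisher_combine_conditional(numeric(0)), "Empty")
  expect_warning(fisher_combine_conditional(c(0, 0.001), gate = "raw"),
                 "clamped")
})

test_that("univariate experiment is calibrated at alpha = 0 and powered", {
  base <- generate_base(n_samples = 80, n_pathways = 12, rho = 0.5,
                        seed = 105)
  res <- univariate_experiment(base, alphas = c(0, 1.5),
                               n_realisations = 30, sspa_method = "svd",
                               seed = 106)
  null_rows <- res[res$alpha == 0, ]
  se <- sqrt(0.05 * 0.95 / 30)
  expect_true(all(null_rows$proportion <= 0.05 + 3 * se))
  # power grows with alpha for the pathway-level route
  pw <- res[res$level == "pathway", ]
  expect_gte(pw$proportion[pw$alpha == 1.5],
             pw$proportion[pw$alpha == 0])
  expect_gt(pw$proportion[pw$alpha == 1.5], 0.5)
})

test_that("cv_auroc is near 0.5 under the null and 1 for strong signal", {
  base <- generate_base(n_samples = 60, n_pathways = 10, rho = 0.5,
                        seed = 107)
  target <- pathblend:::eligible_targets(base)[1]
  r0 <- make_realisation(base, target, alpha = 0, seed = 8)
  cv0 <- cv_auroc(r0$blocks, r0$y, base$pathways, framework = "multiview",
                  ncomp = 1, sspa_method = "svd", n_repeats = 1,
                  n_folds = 5, seed = 108)
  expect_gt(cv0$mean_auc, 0.3)
  expect_lt(cv0$mean_auc, 0.7)

  r5 <- make_realisation(base, target, alpha = 5, seed = 9)
  cv5 <- cv_auroc(r5$blocks, r5$y, base$pathways, framework = "multiview",
                  ncomp = 1, sspa_method = "svd", n_repeats = 1,
                  n_folds = 5, seed = 109)
  expect_equal(cv5$mean_auc, 1)

  # single-view route runs through the same leakage-safe pipeline
  cvsv <- cv_auroc(r5$blocks, r5$y, base$pathways, framework = "singleview",
                   predictor = predictor_spec("pls", ncomp = 1),
                   sspa_method = "svd", n_repeats = 1, n_folds = 5,
                   seed = 110)
  expect_gt(cvsv$mean_auc, 0.95)
})

test_that("nested LV selection returns grid singletons and sane curves", {
  base <- generate_base(n_samples = 60, n_pathways = 10, rho = 0.5,
                        seed = 111)
  target <- pathblend:::eligible_targets(base)[1]
  r <- make_realisation(base, target, alpha = 1, seed = 10)
  one <- nested_lv_selection(r$blocks, r$y, base$pathways, ncomp_grid = 2,
                             sspa_method = "svd", seed = 112)
  expect_equal(one$selected, 2)

  sel <- nested_lv_selection(r$blocks, r$y, base$pathways, ncomp_grid = 1:3,
                             sspa_method = "svd", seed = 113)
  expect_true(sel$selected %in% 1:3)
  expect_equal(nrow(sel$curve), 3)
  expect_true(all(sel$curve$mean_auc >= 0 & sel$curve$mean_auc <= 1))
})

test_that("evaluate_detection builds the confusion matrix and ranking AUC", {
  p <- c(T1 = 0, A = 1, B = 1, C = 1)
  d <- evaluate_detection(p, "T1")
  expect_equal(unlist(d[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 3, fn = 0))
  expect_equal(d$auc, 1)
  expect_equal(d$tp + d$fn, 1)
  expect_equal(d$tp + d$fp + d$tn + d$fn, 4)

  p2 <- c(T1 = 1, A = 0, B = 0)
  d2 <- evaluate_detection(p2, "T1")
  expect_equal(unlist(d2[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 2, tn = 0, fn = 1))
  expect_equal(d2$auc, 0)

  # random uniform p-values: mean AUC = 0.5
  set.seed(114)
  aucs <- replicate(1000, {
    pv <- runif(20)
    names(pv) <- paste0("P", 1:20)
    evaluate_detection(pv, "P1")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  expect_error(evaluate_detection(p, "nope"), "not among")
})

test_that("downsampling keeps a 1:1 class ratio and runs the pipeline", {
  base <- generate_base(n_samples = 60, n_pathways = 8, seed = 115)
  target <- pathblend:::eligible_targets(base)[1]
  r <- make_realisation(base, target, alpha = 2, seed = 11)
  ds <- downsample_experiment(r$blocks, r$y, base$pathways, sizes = c(40),
                              framework = "multiview", ncomp = 1,
                              sspa_method = "svd", n_repeats = 1,
                              seed = 116)
  expect_equal(nrow(ds), 1)
  expect_true(ds$mean_auc > 0.5)
  expect_error(downsample_experiment(r$blocks, r$y, base$pathways,
                                     sizes = 6, framework = "multiview",
                                     seed = 1),
               "2 \\* n_folds")
  expect_error(downsample_experiment(r$blocks, r$y, base$pathways,
                                     sizes = 41, framework = "multiview",
                                     seed = 1),
               "even")
})
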