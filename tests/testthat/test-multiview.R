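# MB-PLS engine: NIPALS with superscore deflation, prediction, block
# importances, VIP and MB-VIP.

test_that("k=1 MB-PLS reduces exactly to single-block NIPALS PLS", {
  x <- make_block(20, 6, seed = 41)
  y <- rnorm(20)
  for (r in 1:3) {
    m <- fit_mbpls(list(A = x), y, ncomp = r)
    o <- oracle_pls(pathblend:::block_to_matrix(x), y, ncomp = r)
    pred <- predict(m, list(A = x))
    expect_equal(unname(pred), o$fitted, tolerance = 1e-8)
    expect_equal(abs(m$w_blocks[[1]]), abs(o$W), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(m$ssy, o$ssy, tolerance = 1e-8)
  }
})

test_that("a small 2-block model matches a plain-loop MB-PLS oracle", {
  # independent step-by-step NIPALS with superscores, written with explicit
  # loops and no shared code
  set.seed(42)
  x1 <- matrix(rnorm(8 * 2), 8, dimnames = list(sprintf("S%03d", 1:8),
                                                c("a1", "a2")))
  x2 <- matrix(rnorm(8 * 2), 8, dimnames = list(sprintf("S%03d", 1:8),
                                                c("b1", "b2")))
  x1 <- scale(x1); x2 <- scale(x2)
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  yc <- y - mean(y)

  u <- yc
  for (it in 1:1000) {
    w1 <- drop(t(x1) %*% u); w1 <- w1 / sqrt(sum(w1^2))
    w2 <- drop(t(x2) %*% u); w2 <- w2 / sqrt(sum(w2^2))
    t1 <- drop(x1 %*% w1); t2 <- drop(x2 %*% w2)
    Tb <- cbind(t1, t2)
    a <- drop(t(Tb) %*% u); a <- a / sqrt(sum(a^2))
    ts <- drop(Tb %*% a)
    cc <- sum(yc * ts) / sum(ts^2)
    u_new <- yc * cc / cc^2
    if (sum((u_new - u)^2) < 1e-30) { u <- u_new; break }
    u <- u_new
  }
  if (a[which.max(abs(a))] < 0) { a <- -a; ts <- -ts }

  m <- fit_mbpls(list(A = pathblend:::matrix_to_block(x1),
                      B = pathblend:::matrix_to_block(x2)),
                 y, ncomp = 1)
  expect_equal(drop(m$superweights), a, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(m$superscores), ts, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m$w_blocks[[1]][, 1], w1, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m$w_blocks[[2]][, 1], w2, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("y proportional to a single-column block is fitted exactly", {
  x <- make_block(15, 1, seed = 43)
  y <- 3 * pathblend:::block_to_matrix(x)[, 1] + 2
  m <- fit_mbpls(list(A = x), y, ncomp = 1)
  rss <- sum((predict(m, list(A = x)) - y)^2)
  expect_lt(rss, 1e-12)
})

test_that("prediction identities hold on training and held-out data", {
  x1 <- make_block(30, 5, prefix = "a", seed = 44)
  x2 <- make_block(30, 4, prefix = "b", seed = 45)
  y <- make_binary_y(30)
  m <- fit_mbpls(list(A = x1, B = x2), y, ncomp = 3)

  # Y-hat = T_s C' + offset on training data
  scores_route <- drop(m$superscores %*% m$c) + m$y_mean
  expect_equal(unname(predict(m, list(A = x1, B = x2))), scores_route,
               tolerance = 1e-8)

  # all-zero rows predict the training outcome mean
  z1 <- x1[1, ]; z1[-1] <- 0
  z2 <- x2[1, ]; z2[-1] <- 0
  expect_equal(unname(predict(m, list(A = z1, B = z2))), m$y_mean)

  # beta route equals the scores route on held-out data: project new rows
  # through the per-LV pipeline by hand
  new1 <- make_block(5, 5, prefix = "a", seed = 46)
  new2 <- make_block(5, 4, prefix = "b", seed = 47)
  xcat <- cbind(pathblend:::block_to_matrix(new1),
                pathblend:::block_to_matrix(new2))
  xr <- xcat
  yhat <- rep(m$y_mean, 5)
  for (r in seq_len(m$ncomp)) {
    ts <- drop(xr %*% m$w_global[, r])
    yhat <- yhat + ts * m$c[r]
    xr <- xr - ts %*% t(m$p_global[, r])
  }
  expect_equal(unname(predict(m, list(A = new1, B = new2))), unname(yhat),
               tolerance = 1e-8)
})

test_that("superscores are orthogonal and deflation is complete", {
  x1 <- make_block(25, 6, prefix = "a", seed = 48)
  x2 <- make_block(25, 5, prefix = "b", seed = 49)
  y <- rnorm(25)
  m <- fit_mbpls(list(A = x1, B = x2), y, ncomp = 4)
  g <- crossprod(m$superscores)
  off <- abs(g[upper.tri(g)])
  norms <- sqrt(diag(g))
  expect_lt(max(off / tcrossprod(norms)[upper.tri(g)]), 1e-6)

  # with R = rank(X), the PLS residual equals the least-squares residual
  xf <- make_block(20, 4, seed = 50)
  yf <- rnorm(20)
  mf <- fit_mbpls(list(A = xf), yf, ncomp = 4)
  xm <- pathblend:::block_to_matrix(xf)
  ls_rss <- sum(resid(lm(I(yf - mean(yf)) ~ xm - 1))^2)
  pls_rss <- sum((yf - predict(mf, list(A = xf)))^2)
  expect_equal(pls_rss, ls_rss, tolerance = 1e-6)
})

test_that("block order permutes outputs consistently", {
  x1 <- make_block(20, 4, prefix = "a", seed = 51)
  x2 <- make_block(20, 3, prefix = "b", seed = 52)
  y <- make_binary_y(20)
  m12 <- fit_mbpls(list(A = x1, B = x2), y, ncomp = 2)
  m21 <- fit_mbpls(list(B = x2, A = x1), y, ncomp = 2)
  expect_equal(predict(m12, list(A = x1, B = x2)),
               predict(m21, list(B = x2, A = x1)), tolerance = 1e-10)
  v12 <- dplyr::arrange(mb_vip(m12), feature)
  v21 <- dplyr::arrange(mb_vip(m21), feature)
  expect_equal(v12$vip, v21$vip, tolerance = 1e-10)
})

test_that("ncomp beyond the rank of the concatenated blocks errors", {
  x <- make_block(6, 3, seed = 53)
  expect_error(fit_mbpls(list(A = x), rnorm(6), ncomp = 5), "rank")
})

test_that("block importances are unit-sum squared superweights", {
  x1 <- make_block(20, 4, prefix = "a", seed = 54)
  y <- make_binary_y(20)
  m1 <- fit_mbpls(list(A = x1), y, ncomp = 2)
  bi <- block_importance(m1, aggregate = FALSE)
  expect_true(all(bi$importance == 1))

  # two identical blocks split the importance evenly
  x1b <- x1
  names(x1b)[-1] <- paste0("dup_", names(x1b)[-1])
  m2 <- fit_mbpls(list(A = x1, B = x1b), y, ncomp = 2)
  bi2 <- block_importance(m2, aggregate = FALSE)
  expect_equal(bi2$importance, rep(0.5, 4), tolerance = 1e-8)

  x2 <- make_block(20, 3, prefix = "b", seed = 55)
  m3 <- fit_mbpls(list(A = x1, B = x2), y, ncomp = 3)
  sums <- block_importance(m3, aggregate = FALSE) |>
    dplyr::group_by(lv) |>
    dplyr::summarise(s = sum(importance))
  expect_equal(sums$s, rep(1, 3), tolerance = 1e-10)
  agg <- block_importance(m3)
  expect_equal(sum(agg$importance[is.na(agg$lv)]), 1, tolerance = 1e-10)
})

test_that("VIP and MB-VIP satisfy their normalization identities", {
  # R=1: VIP_j = sqrt(J)*|w_j|
  x <- make_block(20, 5, seed = 56)
  y <- make_binary_y(20)
  m <- fit_mbpls(list(A = x), y, ncomp = 1)
  v <- dplyr::arrange(vip(m), feature)
  expect_equal(v$vip, sqrt(5) * abs(m$w_blocks[[1]][, 1]),
               tolerance = 1e-10, ignore_attr = TRUE)

  # random fitted models: mean squared VIP = 1; SS(MB-VIP)/(f*k) = 1
  for (seed in 57:59) {
    xa <- make_block(25, 7, prefix = "a", seed = seed)
    xb <- make_block(25, 4, prefix = "b", seed = seed + 10)
    yy <- rnorm(25)
    m1 <- fit_mbpls(list(A = xa), yy, ncomp = 3)
    expect_equal(mean(vip(m1)$vip^2), 1, tolerance = 1e-8)
    m2 <- fit_mbpls(list(A = xa, B = xb), yy, ncomp = 3)
    expect_equal(sum(mb_vip(m2)$vip^2) / (11 * 2), 1, tolerance = 1e-8)
    # k=1: mb_vip equals vip exactly
    expect_equal(dplyr::arrange(mb_vip(m1), feature)$vip,
                 dplyr::arrange(vip(m1), feature)$vip)
  }

  # R=1, blocks of sizes (2,3): MB-VIP = sqrt(5)*|w|
  xa <- make_block(20, 2, prefix = "a", seed = 60)
  xb <- make_block(20, 3, prefix = "b", seed = 61)
  mm <- fit_mbpls(list(A = xa, B = xb), y, ncomp = 1)
  w <- c(mm$w_blocks[[1]][, 1], mm$w_blocks[[2]][, 1])
  got <- dplyr::arrange(mb_vip(mm), match(feature, names(w)))$vip
  expect_equal(got, sqrt(5) * abs(w), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(vip(mm), "mb_vip")
})

test_that("tidy and glance summarise the model", {
  x <- make_block(20, 4, seed = 62)
  y <- make_binary_y(20)
  m <- fit_mbpls(list(A = x), y, ncomp = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_true(all(c("feature", "block", "estimate", "vip") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$ncomp, 2)
  expect_true(gl$prop_y_explained > 0 && gl$prop_y_explained <= 1)
})
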