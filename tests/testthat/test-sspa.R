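# Single-sample pathway analysis: SVD (PLAGE) and kernel-PCA scoring with
# fit/transform semantics, loadings and bootstrap stability.

test_that("svd scores of a single-molecule pathway equal the column", {
  b <- make_block(20, 3, seed = 21)
  coll <- make_collection(list("f1"))
  tr <- fit_sspa(b, coll, method = "svd", min_coverage = 1)
  sc <- pathblend:::block_to_matrix(transform_sspa(tr, b))[, 1]
  z <- pathblend:::block_to_matrix(b)[, "f1"]
  # sign convention makes the single loading +1
  expect_equal(unname(sc), unname(z - mean(z)), tolerance = 1e-12)
  expect_equal(molecule_loadings(tr, "PW01")$loading, 1)
})

test_that("two perfectly correlated columns give direction (1,1)/sqrt(2)", {
  set.seed(22)
  base <- rnorm(30)
  m <- cbind(f1 = base, f2 = base * 1.000)
  rownames(m) <- sprintf("S%03d", 1:30)
  b <- standardize(pathblend:::matrix_to_block(m))
  tr <- fit_sspa(b, make_collection(list(c("f1", "f2"))), method = "svd")
  expect_equal(tr$states[[1]]$direction, rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  # anticorrelated: loadings (1,-1)/sqrt(2) up to sign
  m2 <- cbind(f1 = base, f2 = -base)
  rownames(m2) <- rownames(m)
  b2 <- standardize(pathblend:::matrix_to_block(m2))
  tr2 <- fit_sspa(b2, make_collection(list(c("f1", "f2"))), method = "svd")
  expect_equal(abs(tr2$states[[1]]$direction), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
})

test_that("svd scores match a full eigendecomposition oracle", {
  b <- make_block(25, 10, seed = 23)
  coll <- make_collection(list(paste0("f", 1:6), paste0("f", c(2, 5, 9, 10))))
  tr <- fit_sspa(b, coll, method = "svd")
  sc <- pathblend:::block_to_matrix(transform_sspa(tr, b))
  m <- pathblend:::block_to_matrix(b)
  for (i in 1:2) {
    z <- m[, coll$members[[i]], drop = FALSE]
    zc <- sweep(z, 2, colMeans(z))
    v <- eigen(crossprod(zc), symmetric = TRUE)$vectors[, 1]
    proj <- drop(zc %*% v)
    if (sum(proj * sc[, i]) < 0) proj <- -proj
    expect_equal(unname(sc[, i]), unname(proj), tolerance = 1e-8)
  }
})

test_that("transform reproduces fit-time scores and handles new samples", {
  b <- make_block(24, 6, seed = 24)
  coll <- make_collection(list(paste0("f", 1:4), paste0("f", 4:6)))
  for (method in c("svd", "kpca")) {
    tr <- fit_sspa(b, coll, method = method)
    s1 <- transform_sspa(tr, b)
    s2 <- transform_sspa(tr, b)
    expect_equal(s1, s2)
    # duplicating a training sample as "new" yields its training score
    dup <- b[3, ]
    dup$sample_id <- "NEW"
    sd3 <- pathblend:::block_to_matrix(transform_sspa(tr, dup))
    expect_equal(unname(sd3[1, ]),
                 unname(pathblend:::block_to_matrix(s1)[3, ]),
                 tolerance = 1e-10)
  }
  tr <- fit_sspa(b, coll, method = "svd")
  expect_error(transform_sspa(tr, b[, 1:4]), "missing features")
})

test_that("kpca projection matches the centred out-of-sample formula", {
  b <- make_block(30, 5, seed = 25)
  train <- b[1:20, ]
  test <- b[21:30, ]
  coll <- make_collection(list(paste0("f", 1:5)))
  tr <- fit_sspa(train, coll, method = "kpca")
  got <- pathblend:::block_to_matrix(transform_sspa(tr, test))[, 1]

  # oracle: refit kernel PCA from scratch and project out-of-sample
  xtr <- pathblend:::block_to_matrix(train)
  xte <- pathblend:::block_to_matrix(test)
  gam <- 1 / 5
  kf <- function(a, b) exp(-gam * sum((a - b)^2))
  K <- outer(1:20, 1:20, Vectorize(function(i, j) kf(xtr[i, ], xtr[j, ])))
  H <- diag(20) - matrix(1 / 20, 20, 20)
  Kc <- H %*% K %*% H
  eg <- eigen(Kc, symmetric = TRUE)
  v <- eg$vectors[, 1]; lam <- eg$values[1]
  Kt <- outer(1:10, 1:20, Vectorize(function(i, j) kf(xte[i, ], xtr[j, ])))
  Ktc <- Kt - matrix(rowMeans(Kt), 10, 20) -
    matrix(colMeans(K), 10, 20, byrow = TRUE) + mean(K)
  oracle <- drop(Ktc %*% v / sqrt(lam))
  if (sum(oracle * got) < 0) oracle <- -oracle
  expect_equal(unname(got), oracle, tolerance = 1e-8)
})

test_that("svd scores are centred with variance d1^2/(N-1)", {
  b <- make_block(40, 8, seed = 26)
  coll <- make_collection(list(paste0("f", 1:5), paste0("f", 6:8)))
  tr <- fit_sspa(b, coll, method = "svd")
  sc <- pathblend:::block_to_matrix(transform_sspa(tr, b))
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  for (i in 1:2) {
    expect_equal(var(sc[, i]), tr$states[[i]]$d1^2 / 39, tolerance = 1e-10)
  }
})

test_that("pathway order permutes columns; refit is sign-deterministic", {
  b <- make_block(20, 6, seed = 27)
  coll <- make_collection(list(paste0("f", 1:3), paste0("f", 4:6)),
                          ids = c("P1", "P2"))
  s1 <- transform_sspa(fit_sspa(b, coll, method = "svd"), b)
  s2 <- transform_sspa(fit_sspa(b, coll[2:1, ], method = "svd"), b)
  expect_equal(s1[c("sample_id", "P1", "P2")], s2[c("sample_id", "P1", "P2")])
  s3 <- transform_sspa(fit_sspa(b, coll, method = "svd"), b)
  expect_identical(s1, s3)
})

test_that("coverage exclusion warns and constant submatrix scores zero", {
  b <- make_block(15, 4, seed = 28)
  coll <- make_collection(list(paste0("f", 1:3), c("f4", "zzz")),
                          ids = c("P1", "P2"))
  expect_warning(tr <- fit_sspa(b, coll, method = "svd"), "coverage")
  expect_equal(tr$pathway_id, "P1")
  expect_error(molecule_loadings(tr, "P2"), "Unknown")

  cm <- pathblend:::matrix_to_block(
    matrix(1, 10, 2, dimnames = list(sprintf("s%02d", 1:10), c("a", "b"))))
  expect_warning(trc <- fit_sspa(cm, make_collection(list(c("a", "b"))),
                                 method = "svd"), "Constant")
  expect_true(all(pathblend:::block_to_matrix(
    transform_sspa(trc, cm)) == 0))
})

test_that("kpca transformer has no molecule loadings", {
  b <- make_block(15, 3, seed = 29)
  tr <- fit_sspa(b, make_collection(list(paste0("f", 1:3))), method = "kpca")
  expect_error(molecule_loadings(tr, "PW01"), "svd")
})

test_that("bootstrap loadings: unit norm, convergence on rank-1 data", {
  # noiseless rank-1 two-column pathway: every resample recovers the same
  # direction, so means match the full-data loadings and sds are ~0
  set.seed(30)
  base <- rnorm(40)
  m <- cbind(f1 = base, f2 = 2 * base)
  rownames(m) <- sprintf("S%03d", 1:40)
  b <- standardize(pathblend:::matrix_to_block(m))
  coll <- make_collection(list(c("f1", "f2")))
  bl <- bootstrap_loadings(b, coll, "PW01", n_boot = 50, seed = 1)
  full <- fit_sspa(b, coll, method = "svd")$states[[1]]$direction
  expect_equal(bl$mean, full, tolerance = 1e-8)
  expect_lt(max(bl$sd), 1e-8)

  # loadings always have unit sum of squares
  b2 <- make_block(30, 5, seed = 31)
  tr <- fit_sspa(b2, make_collection(list(paste0("f", 1:5))), method = "svd")
  expect_equal(sum(molecule_loadings(tr, "PW01")$loading^2), 1,
               tolerance = 1e-10)
})
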