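# Fixtures built in code: small random blocks, pathway collections and an
# independent single-block NIPALS PLS oracle used to cross-check MB-PLS.

make_block <- function(n, p, prefix = "f", seed = NULL, standardized = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              paste0(prefix, seq_len(p))))
  b <- pathblend:::matrix_to_block(m)
  if (standardized) b <- standardize(b)
  b
}

make_binary_y <- function(n) {
  factor(rep_len(c("control", "case"), n), levels = c("control", "case"))
}

make_collection <- function(members_list, ids = NULL) {
  ids <- ids %||% sprintf("PW%02d", seq_along(members_list))
  tibble::tibble(pathway_id = ids,
                 pathway_name = paste("Pathway", ids),
                 members = members_list)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-loop single-block NIPALS PLS with y-deflation, written directly
# from the textbook recursion; independent of the package implementation.
oracle_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y_mean <- mean(y)
  yr <- matrix(y - y_mean, ncol = 1)
  xr <- x
  n <- nrow(x); j <- ncol(x)
  W <- matrix(0, j, ncomp); P <- matrix(0, j, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  ssy <- numeric(ncomp)
  for (r in seq_len(ncomp)) {
    u <- yr[, 1]
    for (it in 1:500) {
      w <- drop(t(xr) %*% u); w <- w / sqrt(sum(w^2))
      tt <- drop(xr %*% w)
      cc <- sum(yr * tt) / sum(tt^2)
      u_new <- drop(yr) * cc / cc^2
      if (sqrt(sum((u_new - u)^2)) < 1e-12) { u <- u_new; break }
      u <- u_new
    }
    p <- drop(t(xr) %*% tt) / sum(tt^2)
    ss0 <- sum(yr^2)
    xr <- xr - tt %*% t(p)
    yr <- yr - matrix(tt * cc, ncol = 1)
    ssy[r] <- ss0 - sum(yr^2)
    W[, r] <- w; P[, r] <- p; Tm[, r] <- tt; cvec[r] <- cc
  }
  wstar <- W %*% solve(t(P) %*% W)
  beta <- drop(wstar %*% cvec)
  list(W = W, P = P, scores = Tm, c = cvec, beta = beta, ssy = ssy,
       y_mean = y_mean,
       fitted = unname(drop(x %*% beta) + y_mean))
}
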