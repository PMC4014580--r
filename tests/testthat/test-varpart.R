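test_that("dbMEM basis is orthonormal, centred, ordered low to high frequency", {
  B <- dbmem(0:19)
  G <- crossprod(B)
  expect_equal(G, diag(ncol(B)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(colSums(B)) < 1e-8))
  expect_true(all(attr(B, "eigenvalues") > 0))
  expect_equal(order(attr(B, "eigenvalues"), decreasing = TRUE),
               seq_len(ncol(B)))
  sign_changes <- sum(diff(sign(B[, 1])) != 0)
  expect_equal(sign_changes, 1)
  expect_error(dbmem(c(1, 1, 1)), "degenerate")
  expect_error(dbmem(1:2), ">= 3")
})

test_that("dbMEM eigenvalues match an independent principal-coordinate oracle", {
  tt <- c(0, 1, 2, 3, 4)
  thr <- 1
  D <- abs(outer(tt, tt, "-"))
  D[D > thr] <- 4 * thr
  pc <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 4, eig = TRUE))
  B <- dbmem(tt)
  expect_equal(attr(B, "eigenvalues"),
               pc$eig[pc$eig > max(abs(pc$eig)) * 1e-9],
               tolerance = 1e-10)
})

test_that("a matching dbMEM eigenfunction captures a grid sinusoid almost fully", {
  n <- 120
  B <- dbmem(0:(n - 1))
  y <- sin(2 * pi * (0:(n - 1)) / 12)
  r2 <- summary(lm(y ~ B))$r.squared
  expect_gt(r2, 0.99)
})

test_that("adjusted R2 agrees with lm and the Ezekiel formula; noise averages to zero", {
  set.seed(101)
  n <- 40
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("p1", "p2")))
  y <- X[, 1] + rnorm(n)
  fit <- summary(lm(y ~ X))
  expect_equal(adjusted_r2(y, X), fit$adj.r.squared, tolerance = 1e-12)
  r2 <- fit$r.squared
  expect_equal(adjusted_r2(y, X), 1 - (1 - r2) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-12)
  expect_equal(adjusted_r2(matrix(1:10), matrix(1:10)), 1)
  vals <- vapply(1:300, function(i) {
    set.seed(200 + i)
    adjusted_r2(rnorm(50), matrix(rnorm(50 * 3), 50))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(300))
  Xs <- cbind(a = rnorm(n), b = 0)
  Xs <- cbind(Xs, c = Xs[, "a"])
  expect_error(adjusted_r2(y, Xs), "collinear")
})

test_that("forward selection recovers planted predictors and rejects pure noise", {
  recovered <- 0L
  for (i in 1:10) {
    set.seed(70000 + i)
    n <- 500
    cand <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("c", 1:20)))
    y <- cand[, 3] + 0.8 * cand[, 11] + 0.6 * cand[, 17] + rnorm(n)
    fs <- forward_select(y, cand, n_perm = 99, seed = i)
    if (all(c("c3", "c11", "c17") %in% fs$selected)) recovered <- recovered + 1L
  }
  expect_gte(recovered, 9L)
  n_sel <- vapply(1:10, function(i) {
    set.seed(80000 + i)
    cand <- matrix(rnorm(100 * 10), 100, dimnames = list(NULL, paste0("c", 1:10)))
    length(forward_select(rnorm(100), cand, n_perm = 99, seed = i)$selected)
  }, numeric(1))
  expect_lte(mean(n_sel), 0.6)   # near-empty selection under the null
  # single candidate equal to the response is always selected
  y <- rnorm(30)
  expect_equal(forward_select(y, matrix(y, dimnames = list(NULL, "self")),
                              n_perm = 99, seed = 1)$selected, "self")
})

test_that("partition identities, symmetry and degenerate cases hold exactly", {
  set.seed(55)
  n <- 80
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  W <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("w1", "w2")))
  Y <- cbind(y1 = X[, 1] + W[, 1] + rnorm(n), y2 = rnorm(n))
  vp <- vent_varpart(Y, X, W, n_perm = 99, seed = 1)
  f <- vp$fractions
  expect_equal(f$a + f$b, unname(vp$r2["ab"]), tolerance = 1e-10)
  expect_equal(f$b + f$c, unname(vp$r2["bc"]), tolerance = 1e-10)
  expect_equal(f$a + f$b + f$c + f$d, 1, tolerance = 1e-10)
  sw <- vent_varpart(Y, W, X, n_perm = 99, seed = 1)
  expect_equal(sw$fractions$a, f$c, tolerance = 1e-12)
  expect_equal(sw$fractions$c, f$a, tolerance = 1e-12)
  expect_equal(sw$fractions$b, f$b, tolerance = 1e-12)
  expect_equal(sw$fractions$d, f$d, tolerance = 1e-12)
  expect_message(deg <- vent_varpart(Y, X, NULL, n_perm = 99, seed = 1),
                 "degenerate")
  expect_equal(deg$fractions$b, 0)
  expect_equal(deg$fractions$c, 0)
  expect_equal(deg$fractions$a, adjusted_r2(Y, X), tolerance = 1e-12)
})

test_that("orthogonal predictor sets share (almost) no joint fraction", {
  n <- 200
  B <- dbmem(0:(n - 1))
  X <- B[, 1:2]; colnames(X) <- c("x1", "x2")   # exactly orthogonal pairs
  W <- B[, 3:4]; colnames(W) <- c("w1", "w2")
  set.seed(66)
  Y <- cbind(y = X[, 1] + W[, 1] + rnorm(n, 0, 0.1))
  vp <- suppressWarnings(vent_varpart(Y, X, W, n_perm = 99, seed = 2))
  expect_lt(abs(vp$fractions$b), 0.02)
})

test_that("fractions agree with an independent variation-partitioning implementation", {
  skip_if_not_installed("vegan")
  set.seed(77)
  n <- 60
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  W <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("w1", "w2", "w3")))
  Y <- cbind(y1 = X[, 1] + W[, 2] + rnorm(n), y2 = X[, 2] + rnorm(n))
  vp <- vent_varpart(Y, X, W, n_perm = 99, seed = 3)
  # vegan's indfract rows: unique X, unique W, joint, residual
  vv <- vegan::varpart(Y, X, W)$part$indfract$Adj.R.square
  expect_equal(vp$fractions$a, vv[1], tolerance = 1e-8)
  expect_equal(vp$fractions$c, vv[2], tolerance = 1e-8)
  expect_equal(vp$fractions$b, vv[3], tolerance = 1e-8)
  expect_equal(vp$fractions$d, vv[4], tolerance = 1e-8)
})

test_that("planted variance fractions are recovered at the study's sample size", {
  set.seed(88)
  n <- 536
  # exactly orthonormal variance components: one signal shared by X and W,
  # one X-only, one W-only, plus noise, each contributing 1/4 of var(Y)
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 4), n), scale = FALSE))) * sqrt(n - 1)
  s1 <- Q[, 1]; s2 <- Q[, 2]; s3 <- Q[, 3]; e <- Q[, 4]
  X <- cbind(shared = s1, xonly = s2)
  W <- cbind(sharedW = s1 + rnorm(n, 0, 0.05), wonly = s3)
  Y <- cbind(y = s1 + s2 + s3 + e)
  vp <- suppressWarnings(vent_varpart(Y, X, W, n_perm = 199, seed = 4))
  for (fr in unlist(vp$fractions)) expect_lt(abs(fr - 0.25), 0.05)
  expect_lt(vp$p_values["a"], 0.05)
  expect_lt(vp$p_values["c"], 0.05)
  expect_lt(vp$p_values["abc"], 0.05)
})
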