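test_that("eigen context reconstructs the combined kinship and its inverse", {
  pr <- make_problem(n = 20, m = 10, seed = 2)
  vc <- list(lambda_a = 0.8, lambda_aa = 0.4)
  ec <- build_eigen_context(pr$K, vc, pr$y)
  Hmat <- 0.8 * pr$K$K_a + 0.4 * pr$K$K_aa
  expect_lt(max(abs(ec$U %*% diag(ec$delta) %*% t(ec$U) - Hmat)), 1e-8)
  expect_true(all(ec$Wdiag > 0 & ec$Wdiag <= 1))
  # (H+I)^-1 via U diag(W) U' equals the direct inverse
  inv1 <- ec$U %*% diag(ec$Wdiag) %*% t(ec$U)
  expect_lt(max(abs(inv1 - solve(Hmat + diag(20)))), 1e-8)
  expect_equal(drop(crossprod(ec$U, pr$y$values)), ec$y_star)

  # zero-ratio limit: delta all 0, weights all 1
  ec0 <- build_eigen_context(pr$K, list(lambda_a = 0, lambda_aa = 0), pr$y)
  expect_equal(ec0$delta, rep(0, 20))
  expect_equal(ec0$Wdiag, rep(1, 20))
})

test_that("fit_gls with identity weights equals ordinary least squares", {
  pr <- make_problem(n = 30, m = 6, seed = 3)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0, lambda_aa = 0), pr$y)
  P <- cbind(1, pr$Z$values[1, ])
  fit <- fit_gls(P, ec)
  ols <- lm(pr$y$values ~ P[, 2])
  expect_equal(fit$b_hat, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(sqrt(diag(fit$var_b)), unname(coef(summary(ols))[, 2]),
               tolerance = 1e-10)
})

test_that("eigen-accelerated GLS equals the direct dense-inverse GLS", {
  pr <- make_problem(n = 30, m = 10, seed = 4)
  vc <- estimate_variance_components(pr$y, pr$K)
  ec <- build_eigen_context(pr$K, vc, pr$y)
  Hmat <- vc$lambda_a * pr$K$K_a + vc$lambda_aa * pr$K$K_aa
  Zc <- t(pr$Z$values)
  worst <- 0
  # model I designs, all 10 markers
  for (i in 1:10) {
    P <- cbind(1, Zc[, i])
    a <- fit_gls(P, ec)
    b <- direct_gls(P, Hmat, pr$y$values)
    worst <- max(worst, max(abs(a$b_hat - b$b_hat)),
                 max(abs(a$var_b - b$var_b)), abs(a$sigma2_hat - b$sigma2_hat))
  }
  # model II designs, all 45 pairs
  for (i in 1:9) for (j in (i + 1):10) {
    P <- cbind(1, Zc[, i], Zc[, j], Zc[, i] * Zc[, j])
    a <- fit_gls(P, ec)
    b <- direct_gls(P, Hmat, pr$y$values)
    worst <- max(worst, max(abs(a$b_hat - b$b_hat)),
                 max(abs(a$var_b - b$var_b)))
  }
  expect_lt(worst, 1e-8)
})

test_that("rank-deficient designs report singular status", {
  pr <- make_problem(n = 25, m = 5, seed = 6)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0.5, lambda_aa = 0.2), pr$y)
  x <- pr$Z$values[1, ]
  expect_equal(fit_gls(cbind(1, x, x, x * x)[, c(1, 2, 3, 4)], ec)$status,
               "singular")
})

test_that("a planted additive signal tops the 1D scan", {
  Z <- simulate_ril_genotypes(n = 50, m = 30, seed = 9)
  yv <- 2 * Z$values[17, ] + withr::with_seed(10, rnorm(50, sd = 1e-3))
  y <- trait_vector(yv, individual_ids(Z), "y")
  K <- compute_kinships(Z)
  ec <- build_eigen_context(K, list(lambda_a = 0, lambda_aa = 0), y)
  res <- scan_1d(Z, ec)
  expect_equal(res$marker_id[which.max(res$neglog10p)], "m17")
  expect_true(all(is.finite(res$neglog10p[res$status == "ok"])))
})

test_that("1D Wald with identity weights equals the squared OLS z-score", {
  pr <- make_problem(n = 40, m = 15, seed = 12)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0, lambda_aa = 0), pr$y)
  res <- scan_1d(pr$Z, ec)
  for (i in seq_len(15)) {
    sm <- summary(lm(pr$y$values ~ pr$Z$values[i, ]))$coefficients
    z2 <- (sm[2, 1] / sm[2, 2])^2
    expect_equal(res$wald[i], z2, tolerance = 1e-8)
  }
  # p and neglog10p are mutually consistent
  expect_equal(res$neglog10p, -log10(res$p), tolerance = 1e-10)
})

test_that("constant markers yield singular rows without aborting the scan", {
  Z <- rand_panel(5, 20, seed = 13)
  Zv <- Z$values
  Zv[3, ] <- 1
  Z <- marker_matrix(Zv)
  y <- rand_trait(20, seed = 14)
  K <- compute_kinships(Z)
  ec <- build_eigen_context(K, list(lambda_a = 0.1, lambda_aa = 0.1), y)
  res <- scan_1d(Z, ec)
  expect_equal(res$status[3], "singular")
  expect_equal(sum(res$status == "ok"), 4L)
})

test_that("2D scan agrees with pair-by-pair direct GLS", {
  pr <- make_problem(n = 30, m = 10, seed = 15)
  vc <- estimate_variance_components(pr$y, pr$K)
  ec <- build_eigen_context(pr$K, vc, pr$y)
  res <- scan_2d(pr$Z, ec, chunk_size = 7)
  Hmat <- vc$lambda_a * pr$K$K_a + vc$lambda_aa * pr$K$K_aa
  Zc <- t(pr$Z$values)
  k <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    k <- k + 1
    P <- cbind(1, Zc[, i], Zc[, j], Zc[, i] * Zc[, j])
    d <- direct_gls(P, Hmat, pr$y$values)
    expect_equal(res$gamma[k], d$b_hat[4], tolerance = 1e-8)
    expect_equal(res$wald[k], d$b_hat[4]^2 / d$var_b[4, 4], tolerance = 1e-6)
  }
  expect_equal(res$p, pmax(pchisq(res$wald, 1, lower.tail = FALSE), 1e-300),
               tolerance = 1e-12)
})

test_that("pair order does not matter and chunking never changes output", {
  pr <- make_problem(n = 25, m = 8, seed = 16)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0.3, lambda_aa = 0.6), pr$y)
  full <- scan_2d(pr$Z, ec, chunk_size = 1000)
  for (cs in c(1L, 3L, 10L)) {
    expect_equal(tibble::as_tibble(scan_2d(pr$Z, ec, chunk_size = cs)),
                 tibble::as_tibble(full), tolerance = 1e-14)
  }
  # symmetric semantics: requesting (j, i) returns the (i, j) fit
  sub <- scan_2d(pr$Z, ec, pair_subset = cbind(5L, 2L))
  ref <- full[full$marker_i == "m2" & full$marker_j == "m5", ]
  expect_equal(sub$p, ref$p, tolerance = 1e-12)
})

test_that("identical pair markers give a collinear, singular design", {
  Zv <- withr::with_seed(17, matrix(sample(c(-1, 1), 4 * 20, TRUE), 4, 20))
  Zv[2, ] <- Zv[1, ]   # duplicated marker: W_12 is constant 1
  Z <- marker_matrix(Zv)
  y <- rand_trait(20, seed = 18)
  ec <- build_eigen_context(compute_kinships(Z),
                            list(lambda_a = 0, lambda_aa = 0), y)
  res <- scan_2d(Z, ec)
  expect_equal(res$status[res$marker_i == "m1" & res$marker_j == "m2"],
               "singular")
})

test_that("scan output is invariant to consistent individual permutation", {
  pr <- make_problem(n = 30, m = 8, seed = 19)
  vc <- estimate_variance_components(pr$y, pr$K)
  ec <- build_eigen_context(pr$K, vc, pr$y)
  res <- scan_1d(pr$Z, ec)
  perm <- withr::with_seed(20, sample(30))
  Zp <- marker_matrix(pr$Z$values[, perm])
  yp <- trait_vector(pr$y$values[perm], individual_ids(pr$y)[perm], "y")
  Kp <- compute_kinships(Zp)
  ecp <- build_eigen_context(Kp, vc, yp)
  resp <- scan_1d(Zp, ecp)
  expect_equal(resp$p, res$p, tolerance = 1e-8)
})

test_that("null p-values are approximately uniform", {
  # trait independent of markers, ratios fixed at zero
  K <- compute_kinships(simulate_ril_genotypes(n = 120, m = 15, seed = 30))
  Z <- simulate_ril_genotypes(n = 120, m = 15, seed = 30)
  ps <- unlist(lapply(1:40, function(s) {
    y <- rand_trait(120, seed = 4000 + s)
    ec <- build_eigen_context(K, list(lambda_a = 0, lambda_aa = 0), y)
    scan_1d(Z, ec)$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("conditional slice reads the 2D matrix at one marker", {
  pr <- make_problem(n = 25, m = 5, seed = 22)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0.2, lambda_aa = 0.1), pr$y)
  res <- scan_2d(pr$Z, ec)
  sl <- conditional_slice(res, "m2")
  expect_equal(nrow(sl), 4L)
  expect_equal(sl$marker_id, c("m1", "m3", "m4", "m5"))
  expect_equal(sl$p[1], res$p[res$marker_i == "m1" & res$marker_j == "m2"])
  expect_equal(sl$p[2], res$p[res$marker_i == "m2" & res$marker_j == "m3"])
  expect_error(conditional_slice(res, "nope"), "not present")
})

test_that("thresholding matches a naive filter and sorts as documented", {
  pr <- make_problem(n = 30, m = 12, seed = 23)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0.5, lambda_aa = 0.5), pr$y)
  res <- scan_2d(pr$Z, ec)
  th <- stats::quantile(res$neglog10p, 0.7, na.rm = TRUE)
  out <- threshold_pairs(res, th)
  naive <- res[res$status == "ok" & res$neglog10p >= th, ]
  expect_equal(nrow(out), nrow(naive))
  expect_equal(sort(out$p), sort(naive$p))
  expect_true(all(diff(out$neglog10p) <= 1e-12))
  expect_equal(nrow(threshold_pairs(res, Inf)), 0L)
  expect_equal(nrow(threshold_pairs(res, 0)), sum(res$status == "ok"))
})

test_that("the dense cap demands a storage threshold and sparse mode filters", {
  pr <- make_problem(n = 20, m = 10, seed = 24)
  ec <- build_eigen_context(pr$K, list(lambda_a = 0, lambda_aa = 0), pr$y)
  expect_error(scan_2d(pr$Z, ec, dense_limit = 5), "store_threshold")
  sp <- scan_2d(pr$Z, ec, dense_limit = 5, store_threshold = 0.5)
  full <- scan_2d(pr$Z, ec)
  expect_equal(nrow(sp), sum(full$neglog10p >= 0.5, na.rm = TRUE))
  expect_true(all(sp$neglog10p >= 0.5))
})
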