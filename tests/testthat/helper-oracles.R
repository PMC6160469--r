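# Shared fixtures and independent oracles. Every oracle here deliberately
# uses the direct textbook formula (dense inverses, explicit loops, explicit
# refits) rather than the package's accelerated code paths.

rand_panel <- function(m, n, seed) {
  withr::with_seed(seed, {
    marker_matrix(matrix(rnorm(m * n), m, n),
                  marker_ids = paste0("m", seq_len(m)),
                  individual_ids = paste0("s", seq_len(n)))
  })
}

rand_trait <- function(n, seed, ids = paste0("s", seq_len(n))) {
  withr::with_seed(seed, trait_vector(rnorm(n), ids, "y"))
}

# restricted log-likelihood evaluated without profiling shortcuts:
# plug V = C * sigma2 and beta_hat explicitly into the likelihood
unprofiled_loglik <- function(lambda_a, lambda_aa, y, K) {
  yv <- y$values
  n <- length(yv)
  C <- lambda_a * K$K_a + lambda_aa * K$K_aa + diag(n)
  X <- matrix(1, n, 1)
  Cinv <- solve(C)
  beta <- drop(solve(t(X) %*% Cinv %*% X, t(X) %*% Cinv %*% yv))
  r <- yv - X %*% beta
  sigma2 <- drop(t(r) %*% Cinv %*% r) / (n - 1)
  V <- C * sigma2
  Vinv <- solve(V)
  ld_V <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld_X <- log(drop(t(X) %*% Vinv %*% X))
  drop(-0.5 * ld_V - 0.5 * ld_X - 0.5 * t(r) %*% Vinv %*% r)
}

# direct GLS through a dense (H + I) inverse, no eigen shortcut
direct_gls <- function(P, Hmat, yv) {
  n <- length(yv)
  Cinv <- solve(Hmat + diag(n))
  M <- t(P) %*% Cinv %*% P
  b <- drop(solve(M, t(P) %*% Cinv %*% yv))
  r <- yv - drop(P %*% b)
  sigma2 <- drop(t(r) %*% Cinv %*% r) / (n - ncol(P))
  list(b_hat = b, var_b = solve(M) * sigma2, sigma2_hat = sigma2)
}

# explicit leave-one-out predicted residuals for the mixed model at fixed
# ratios: drop individual i, refit beta by GLS on the rest, BLUP-predict the
# held-out genetic value from the remaining individuals
loo_press_oracle <- function(wv, K, lambda) {
  n <- length(wv)
  Hm <- lambda[1] * K$K_a + lambda[2] * K$K_aa
  press <- 0
  for (i in seq_len(n)) {
    Ci <- Hm[-i, -i] + diag(n - 1)
    Ciinv <- solve(Ci)
    one <- rep(1, n - 1)
    beta <- drop((one %*% Ciinv %*% wv[-i]) / (one %*% Ciinv %*% one))
    ghat <- drop(Hm[i, -i] %*% Ciinv %*% (wv[-i] - beta))
    press <- press + unname(wv[i] - beta - ghat)^2
  }
  press
}

# a small aligned problem used by several scan tests; switch_prob = 0.5
# gives independent markers (no duplicated rows that would trip the dense
# oracle on tiny panels)
make_problem <- function(n = 40, m = 12, seed = 1, h2a = 0.4, h2aa = 0.3,
                         switch_prob = 0.5) {
  Z <- simulate_ril_genotypes(n = n, m = m, seed = seed,
                              switch_prob = switch_prob)
  sim <- simulate_trait(Z, h2a, h2aa, 1 - h2a - h2aa, seed = seed + 100)
  K <- compute_kinships(Z)
  list(Z = Z, y = sim$y, K = K, truth = sim$truth)
}
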