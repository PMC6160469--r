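#' Profiled restricted log-likelihood of the two-ratio mixed model
#'
#' The trait model is \eqn{y = X\beta + \xi + \zeta + e} with
#' \eqn{var(y) = K_a\sigma_a^2 + K_{aa}\sigma_{aa}^2 + I\sigma^2}. Writing the
#' variance ratios \eqn{\lambda_a = \sigma_a^2/\sigma^2} and
#' \eqn{\lambda_{aa} = \sigma_{aa}^2/\sigma^2}, the covariance factors as
#' \eqn{var(y) = C\sigma^2} with \eqn{C = \lambda_a K_a + \lambda_{aa} K_{aa} + I}.
#' \eqn{\beta} and \eqn{\sigma^2} profile out in closed form
#' (\eqn{X} is the intercept column of ones, rank 1):
#' \deqn{\hat\beta = (X^TC^{-1}X)^{-1}X^TC^{-1}y, \quad
#'       \hat\sigma^2 = (y-X\hat\beta)^TC^{-1}(y-X\hat\beta)/(n-1)}
#' \deqn{L = -\tfrac12\ln|C| - \tfrac12\ln|X^TC^{-1}X|
#'       - \tfrac{n-1}{2}\ln\hat\sigma^2 - \tfrac{n-1}{2}.}
#'
#' @param lambda_a,lambda_aa Non-negative variance ratios.
#' @param y A [trait_vector()] aligned with `K`.
#' @param K A [kinship_set()].
#' @return A list with `loglik`, the profiled `sigma2` and `beta`.
#' @export
restricted_loglik <- function(lambda_a, lambda_aa, y, K) {
  stopifnot(lambda_a >= 0, lambda_aa >= 0)
  yv <- y$values
  n <- length(yv)
  if (K$n != n) stop("trait and kinship dimensions differ; align first",
                     call. = FALSE)
  C <- lambda_a * K$K_a + lambda_aa * K$K_aa
  diag(C) <- diag(C) + 1
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    stop(sprintf("covariance matrix numerically singular (condition number ~ %.3g)",
                 kappa(C)), call. = FALSE)
  }
  ldetC <- 2 * sum(log(diag(R)))
  # solve C z = [y, 1] through the Cholesky factor
  rhs <- cbind(yv, 1)
  z <- backsolve(R, forwardsolve(t(R), rhs))
  Cinv_y <- z[, 1L]
  Cinv_1 <- z[, 2L]
  xtcx <- sum(Cinv_1)                    # X'C^-1 X, X = 1
  beta <- sum(Cinv_y) / xtcx
  r <- yv - beta
  # r'C^-1 r = y'C^-1 y - 2 beta 1'C^-1 y + beta^2 1'C^-1 1
  quad <- sum(yv * Cinv_y) - 2 * beta * sum(Cinv_y) + beta^2 * xtcx
  sigma2 <- quad / (n - 1)
  ll <- -0.5 * ldetC - 0.5 * log(xtcx) - ((n - 1) / 2) * log(sigma2) -
    (n - 1) / 2
  list(loglik = ll, sigma2 = sigma2, beta = beta)
}

#' Estimate the three variance components by REML
#'
#' Maximizes the profiled restricted log-likelihood over
#' \eqn{(\ln\lambda_a, \ln\lambda_{aa})} with a derivative-free Nelder–Mead
#' simplex and multiple restarts (the two-ratio profile surface is cheap but
#' can be multimodal). The residual variance and the component variances are
#' recovered from the profile:
#' \eqn{\sigma_a^2 = \lambda_a\hat\sigma^2}, \eqn{\sigma_{aa}^2 = \lambda_{aa}\hat\sigma^2}.
#' Variance fractions are \eqn{\sigma_x^2/(\sigma_a^2+\sigma_{aa}^2+\sigma^2)}
#' and broad-sense heritability is their biological part,
#' \eqn{H = ratio_a + ratio_{aa}}.
#'
#' Ratios that converge to the lower box bound (1e-6) are reported as 0 with
#' `boundary = TRUE`.
#'
#' @param y A [trait_vector()] aligned with `K`.
#' @param K A [kinship_set()].
#' @param restarts Matrix of `(lambda_a, lambda_aa)` starting points; the
#'   default uses five spread over the box.
#' @param lambda_box Lower/upper bounds for both ratios.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return An object of class `episcan_vc`; see [tidy.episcan_vc()] and
#'   [glance.episcan_vc()].
#' @examples
#' Z <- simulate_ril_genotypes(n = 80, m = 60, seed = 7)
#' K <- compute_kinships(Z)
#' sim <- simulate_trait(Z, sigma2_a = 1, sigma2_aa = 0.5, sigma2_e = 0.5, seed = 7)
#' fit <- estimate_variance_components(sim$y, K)
#' glance(fit)
#' @export
estimate_variance_components <- function(y, K,
                                         restarts = NULL,
                                         lambda_box = c(1e-6, 1e6),
                                         tol = 1e-9) {
  if (is.null(restarts)) {
    restarts <- rbind(c(0.01, 0.01), c(1, 1), c(10, 0.1), c(0.1, 10), c(5, 5))
  }
  lo <- log(lambda_box[1L])
  hi <- log(lambda_box[2L])
  negll <- function(theta) {
    th <- pmin(pmax(theta, lo), hi)
    val <- tryCatch(
      restricted_loglik(exp(th[1L]), exp(th[2L]), y, K)$loglik,
      error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    -val
  }
  best <- NULL
  n_conv <- 0L
  for (s in seq_len(nrow(restarts))) {
    fit <- stats::optim(log(restarts[s, ]), negll, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = 2000))
    ok <- fit$convergence == 0L && fit$value < 1e9
    if (ok) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$ok <- ok
    }
  }
  if (best$value >= 1e9) {
    stop("restricted likelihood non-finite at every restart", call. = FALSE)
  }
  if (n_conv == 0L) {
    stop(sprintf(paste0("no REML restart converged; best point lambda_a = %.4g,",
                        " lambda_aa = %.4g, loglik = %.6g"),
                 exp(best$par[1L]), exp(best$par[2L]), -best$value),
         call. = FALSE)
  }
  th <- pmin(pmax(best$par, lo), hi)
  lambda_a <- exp(th[1L])
  lambda_aa <- exp(th[2L])
  at_boundary <- c(a = lambda_a <= lambda_box[1L] * (1 + 1e-8),
                   aa = lambda_aa <= lambda_box[1L] * (1 + 1e-8))
  if (at_boundary[["a"]]) lambda_a <- 0
  if (at_boundary[["aa"]]) lambda_aa <- 0
  prof <- restricted_loglik(lambda_a, lambda_aa, y, K)
  sigma2_e <- prof$sigma2
  sigma2_a <- lambda_a * sigma2_e
  sigma2_aa <- lambda_aa * sigma2_e
  total <- sigma2_a + sigma2_aa + sigma2_e
  structure(list(
    sigma2_a = sigma2_a, sigma2_aa = sigma2_aa, sigma2_e = sigma2_e,
    lambda_a = lambda_a, lambda_aa = lambda_aa,
    ratio_a = sigma2_a / total, ratio_aa = sigma2_aa / total,
    ratio_e = sigma2_e / total,
    H = (sigma2_a + sigma2_aa) / total,
    beta = prof$beta,
    loglik = prof$loglik,
    converged = best$ok,
    boundary = at_boundary,
    n_restarts_used = nrow(restarts),
    n = length(y$values),
    trait_name = y$trait_name
  ), class = "episcan_vc")
}

#' Broad-sense heritability of a variance-component fit
#'
#' \eqn{H = (\sigma_a^2 + \sigma_{aa}^2)/(\sigma_a^2 + \sigma_{aa}^2 + \sigma^2)}:
#' the fraction of phenotypic variance the additive and epistatic components
#' jointly explain. Invariant to rescaling all three components.
#'
#' @param vc An `episcan_vc` fit, or a numeric vector
#'   `c(sigma2_a, sigma2_aa, sigma2_e)`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  if (inherits(vc, "episcan_vc")) {
    comps <- c(vc$sigma2_a, vc$sigma2_aa, vc$sigma2_e)
  } else {
    comps <- as.numeric(vc)
    stopifnot(length(comps) == 3L)
  }
  total <- sum(comps)
  if (total <= 0) stop("all variance components are zero", call. = FALSE)
  (comps[1L] + comps[2L]) / total
}

#' @export
print.episcan_vc <- function(x, ...) {
  cat(sprintf("<episcan_vc> trait '%s', n = %d\n", x$trait_name, x$n))
  cat(sprintf("  sigma2_a  = %.6g  (ratio %.4f)\n", x$sigma2_a, x$ratio_a))
  cat(sprintf("  sigma2_aa = %.6g  (ratio %.4f)\n", x$sigma2_aa, x$ratio_aa))
  cat(sprintf("  sigma2_e  = %.6g  (ratio %.4f)\n", x$sigma2_e, x$ratio_e))
  cat(sprintf("  H = %.4f; loglik = %.6g; converged = %s\n",
              x$H, x$loglik, x$converged))
  invisible(x)
}
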