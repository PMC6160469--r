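#' Leave-one-out predictability of an intermediate omic marker
#'
#' Treats one transcript or metabolite as an intermediate phenotype `w` and
#' scores how well the genotype panel predicts it:
#' \eqn{PRED = R^2 = 1 - PRESS/SS}, where SS is the total sum of squares of
#' `w` and PRESS is the predicted residual error sum of squares of the mixed
#' model \eqn{w = X\beta + \xi + \zeta + e} with genotype kinships.
#'
#' PRESS is computed by the HAT shortcut rather than `n` refits: with
#' \eqn{C = H + I} and the REML projection
#' \eqn{Q = C^{-1} - C^{-1}X(X^TC^{-1}X)^{-1}X^TC^{-1}}, the fitted values of
#' the BLUP-inclusive smoother \eqn{S} satisfy \eqn{I - S = Q} and the
#' leverage-corrected residual \eqn{(w_i - \hat w_i)/(1 - S_{ii}) = (Qw)_i/Q_{ii}}
#' equals the exact leave-one-out residual (fixed effect refit, held-out
#' individual BLUP-predicted) at fixed variance ratios.
#'
#' PRED can be negative when the model predicts worse than the trait mean; it
#' is reported as-is, never clamped.
#'
#' @param w A [trait_vector()] holding one omic marker, aligned with `K_geno`.
#' @param K_geno A [kinship_set()] built from the genotype panel.
#' @param lambda Optional fixed `c(lambda_a, lambda_aa)`; when `NULL`
#'   (default) the ratios are re-estimated by REML for this marker.
#' @param additive_only Use only the additive kinship (forces
#'   `lambda_aa = 0`).
#' @return A one-row tibble with `marker_id`, `pred`, `press`, `ss`.
#' @export
press_r2 <- function(w, K_geno, lambda = NULL, additive_only = FALSE) {
  wv <- w$values
  n <- length(wv)
  if (K_geno$n != n) stop("marker trait and kinship dimensions differ",
                          call. = FALSE)
  if (stats::var(wv) <= 0) stop("constant omic marker: zero variance",
                                call. = FALSE)
  if (is.null(lambda)) {
    if (additive_only) {
      # one-dimensional profile: lambda_aa pinned at 0
      opt <- stats::optimize(function(th) {
        -restricted_loglik(exp(th), 0, w, K_geno)$loglik
      }, interval = log(c(1e-6, 1e6)), tol = 1e-8)
      la <- exp(opt$minimum)
      if (la <= 1e-6 * (1 + 1e-8)) la <- 0
      lambda <- c(la, 0)
    } else {
      vc <- estimate_variance_components(w, K_geno)
      lambda <- c(vc$lambda_a, vc$lambda_aa)
    }
  }
  if (additive_only) lambda[2L] <- 0
  C <- lambda[1L] * K_geno$K_a + lambda[2L] * K_geno$K_aa
  diag(C) <- diag(C) + 1
  Cinv <- chol2inv(chol(C))
  c1 <- Cinv %*% rep(1, n)
  Q <- Cinv - tcrossprod(c1) / sum(c1)
  dq <- diag(Q)
  if (any(dq <= 1e-10)) {
    stop("degenerate leverage: a diagonal smoother element reaches 1",
         call. = FALSE)
  }
  r_loo <- drop(Q %*% wv) / dq
  press <- sum(r_loo^2)
  ss <- sum((wv - mean(wv))^2)
  tibble::tibble(marker_id = w$trait_name, pred = 1 - press / ss,
                 press = press, ss = ss)
}

#' Predictability scores for a whole omic panel
#'
#' Applies [press_r2()] to every row of an omic marker matrix (each
#' transcript/metabolite treated as an intermediate trait) against the
#' genotype kinships.
#'
#' @param Zomic A [marker_matrix()] of intermediate omic markers, columns
#'   aligned with `K_geno`'s individuals.
#' @param K_geno A [kinship_set()] from the genotype panel.
#' @param lambda Optional fixed ratios reused for every marker (fast,
#'   approximate mode); default re-estimates per marker.
#' @param additive_only Passed to [press_r2()].
#' @return A tibble with one row per omic marker: `marker_id`, `pred`,
#'   `press`, `ss`.
#' @export
predictability_scan <- function(Zomic, K_geno, lambda = NULL,
                                additive_only = FALSE) {
  rows <- lapply(seq_len(n_markers(Zomic)), function(i) {
    w <- trait_vector(Zomic$values[i, ], individual_ids(Zomic),
                      trait_name = marker_ids(Zomic)[i])
    press_r2(w, K_geno, lambda = lambda, additive_only = additive_only)
  })
  dplyr::bind_rows(rows)
}

#' Heritability against PRED-threshold marker selection
#'
#' For each threshold, keeps the omic markers whose predictability meets it,
#' rebuilds the additive/epistatic kinships from the reduced panel, re-runs
#' REML on the trait and records broad-sense heritability and the panel size.
#' Thresholds where fewer than 2 markers survive yield `NA` heritability.
#'
#' @param Zomic A [marker_matrix()] of omic markers.
#' @param preds Predictability tibble from [predictability_scan()], covering
#'   all markers of `Zomic`.
#' @param y A [trait_vector()] aligned with `Zomic`.
#' @param thresholds Increasing numeric PRED thresholds.
#' @return An `episcan_predcurve` tibble with columns `threshold`,
#'   `n_selected`, `H`.
#' @export
pred_threshold_curve <- function(Zomic, preds, y, thresholds) {
  if (!all(marker_ids(Zomic) %in% preds$marker_id)) {
    stop("`preds` does not cover every marker of `Zomic`", call. = FALSE)
  }
  pr <- preds$pred[match(marker_ids(Zomic), preds$marker_id)]
  rows <- lapply(thresholds, function(t) {
    keep <- which(pr >= t)
    if (length(keep) < 2L) {
      return(tibble::tibble(threshold = t, n_selected = length(keep),
                            H = NA_real_))
    }
    Zt <- marker_matrix(Zomic$values[keep, , drop = FALSE])
    vc <- estimate_variance_components(y, compute_kinships(Zt))
    tibble::tibble(threshold = t, n_selected = length(keep), H = vc$H)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("episcan_predcurve", class(out)))
}
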