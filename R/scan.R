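#' One-time eigen-decomposition context for the association scans
#'
#' With the variance ratios fixed at their REML estimates, every per-marker or
#' per-pair generalized least squares fit shares the covariance
#' \eqn{V = (H + I)\sigma^2} with \eqn{H = \lambda_a K_a + \lambda_{aa} K_{aa}}.
#' Eigen-decomposing \eqn{H = U D U^T} once turns each fit into a weighted
#' least squares problem in the rotated coordinates: weights
#' \eqn{W_i = 1/(\delta_i + 1)} and transformed trait \eqn{y^* = U^T y}.
#'
#' @param K A [kinship_set()].
#' @param vc An `episcan_vc` fit (or any list with `lambda_a`, `lambda_aa`)
#'   estimated on the same `K` and `y`.
#' @param y A [trait_vector()] aligned with `K`.
#' @return An object of class `episcan_eigen` with fields `U`, `delta`,
#'   `Wdiag`, `y_star`, `lambda_a`, `lambda_aa`.
#' @export
build_eigen_context <- function(K, vc, y) {
  n <- K$n
  if (length(y$values) != n) stop("trait and kinship dimensions differ",
                                  call. = FALSE)
  Hmat <- vc$lambda_a * K$K_a + vc$lambda_aa * K$K_aa
  es <- eigen(Hmat, symmetric = TRUE)
  delta <- es$values
  if (length(delta) && min(delta) < -1e-8 * max(abs(delta), 1)) {
    stop("combined kinship is not positive semidefinite", call. = FALSE)
  }
  delta <- pmax(delta, 0)
  structure(list(
    U = es$vectors, delta = delta, Wdiag = 1 / (delta + 1),
    y_star = drop(crossprod(es$vectors, y$values)),
    lambda_a = vc$lambda_a, lambda_aa = vc$lambda_aa,
    individual_ids = K$individual_ids,
    trait_name = y$trait_name
  ), class = "episcan_eigen")
}

#' @export
print.episcan_eigen <- function(x, ...) {
  cat(sprintf("<episcan_eigen> n = %d; lambda_a = %.4g, lambda_aa = %.4g\n",
              length(x$delta), x$lambda_a, x$lambda_aa))
  invisible(x)
}

#' Generalized least squares fit through the eigen context
#'
#' Fits \eqn{y = Pb + \epsilon} with \eqn{var(\epsilon) = (H+I)\sigma^2} using
#' the rotated problem: \eqn{P^* = U^TP},
#' \eqn{\hat b = (P^{*T}WP^*)^{-1}P^{*T}Wy^*},
#' \eqn{\hat\sigma^2 = (y^*-P^*\hat b)^TW(y^*-P^*\hat b)/(n-r(P))} and
#' \eqn{var(\hat b) = (P^{*T}WP^*)^{-1}\hat\sigma^2}. The design's first
#' column is the intercept; rank-deficient designs (condition number above
#' 1e12) return `status = "singular"` rather than an error.
#'
#' @param P Design matrix, `n x 2` (intercept + marker) or `n x 4`
#'   (intercept, two markers, their element-wise product).
#' @param ec An `episcan_eigen` context from [build_eigen_context()].
#' @return A list with `b_hat`, `var_b`, `sigma2_hat` and `status`
#'   (`"ok"`/`"singular"`).
#' @export
fit_gls <- function(P, ec) {
  stopifnot(ncol(P) %in% c(2L, 4L))
  Ps <- crossprod(ec$U, P)
  .fit_gls_star(Ps, ec$Wdiag, ec$y_star)
}

# core WLS on rotated coordinates; shared by fit_gls and the scans
.fit_gls_star <- function(Ps, w, ys) {
  n <- nrow(Ps)
  r <- ncol(Ps)
  M <- crossprod(Ps, Ps * w)
  if (!all(is.finite(M)) || kappa(M, exact = FALSE) > 1e12) {
    return(list(b_hat = NULL, var_b = NULL, sigma2_hat = NA_real_,
                status = "singular"))
  }
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) {
    return(list(b_hat = NULL, var_b = NULL, sigma2_hat = NA_real_,
                status = "singular"))
  }
  b <- drop(Minv %*% crossprod(Ps, w * ys))
  res <- ys - drop(Ps %*% b)
  sigma2 <- sum(w * res^2) / (n - r)
  list(b_hat = b, var_b = Minv * sigma2, sigma2_hat = sigma2, status = "ok")
}

.p_from_wald <- function(wald) {
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  pmax(p, 1e-300)  # floor so -log10(p) stays finite
}

new_scan1d <- function(df, trait_name = NULL) {
  structure(df, class = c("episcan_scan1d", class(tibble::as_tibble(df))),
            trait_name = trait_name)
}

new_scan2d <- function(df, trait_name = NULL, marker_ids = NULL) {
  structure(df, class = c("episcan_scan2d", class(tibble::as_tibble(df))),
            trait_name = trait_name, scan_marker_ids = marker_ids)
}

#' 1D association scan: per-marker additive effects
#'
#' For each marker `i`, fits model I \eqn{y = X\beta + Z_ia_i + e} by GLS
#' under the fixed-ratio covariance, and tests \eqn{H_0: a_i = 0} with the
#' 1-df Wald statistic \eqn{\hat a_i^2/var(\hat a_i)},
#' \eqn{p = 1 - \Pr(\chi^2_1 < Wald)}. p-values are floored at 1e-300 so
#' \eqn{-\log_{10}(p)} is always finite. Constant (zero-variance) markers get
#' `status = "singular"` and the scan continues.
#'
#' @param Z A [marker_matrix()] aligned with the eigen context's individuals.
#' @param ec An `episcan_eigen` context.
#' @return An `episcan_scan1d` tibble with columns `marker_id`, `effect`,
#'   `var_effect`, `wald`, `p`, `neglog10p`, `status`, in input marker order.
#' @examples
#' Z <- simulate_ril_genotypes(n = 60, m = 30, seed = 3)
#' sim <- simulate_trait(Z, sigma2_a = 1, sigma2_aa = 0, sigma2_e = 0.3,
#'                       n_causal_add = 3, seed = 3)
#' K <- compute_kinships(Z)
#' vc <- estimate_variance_components(sim$y, K)
#' res <- scan_1d(Z, build_eigen_context(K, vc, sim$y))
#' head(dplyr::arrange(res, p))
#' @export
scan_1d <- function(Z, ec) {
  n <- length(ec$y_star)
  if (n_individuals(Z) != n) stop("marker matrix not aligned with eigen context",
                                  call. = FALSE)
  m <- n_markers(Z)
  w <- ec$Wdiag
  ys <- ec$y_star
  xs <- drop(crossprod(ec$U, rep(1, n)))          # rotated intercept
  Zs <- crossprod(ec$U, t(Z$values))              # n x m rotated markers
  # closed-form 2x2 weighted LS, vectorized across markers
  s00 <- sum(w * xs * xs)
  s0y <- sum(w * xs * ys)
  syy <- sum(w * ys * ys)
  s0z <- drop(crossprod(Zs, w * xs))              # per-marker sum w x z
  szz <- drop(crossprod(Zs * Zs, w))
  szy <- drop(crossprod(Zs, w * ys))
  det <- s00 * szz - s0z^2
  # relative condition of the 2x2 normal matrix via its eigenvalues
  tr <- s00 + szz
  disc <- sqrt(pmax(tr^2 - 4 * det, 0))
  cond <- (tr + disc) / pmax(tr - disc, .Machine$double.xmin)
  singular <- !is.finite(det) | det <= 0 | cond > 1e12
  a_hat <- (s00 * szy - s0z * s0y) / det
  b0 <- (szz * s0y - s0z * szy) / det
  rss <- syy - 2 * (b0 * s0y + a_hat * szy) +
    b0^2 * s00 + 2 * b0 * a_hat * s0z + a_hat^2 * szz
  sigma2 <- pmax(rss, 0) / (n - 2)
  var_a <- s00 / det * sigma2
  wald <- a_hat^2 / var_a
  p <- .p_from_wald(wald)
  out <- tibble::tibble(
    marker_id = marker_ids(Z),
    effect = unname(ifelse(singular, NA_real_, a_hat)),
    var_effect = unname(ifelse(singular, NA_real_, var_a)),
    wald = unname(ifelse(singular, NA_real_, wald)),
    p = unname(ifelse(singular, NA_real_, p)),
    neglog10p = unname(ifelse(singular, NA_real_, -log10(p))),
    status = unname(ifelse(singular, "singular", "ok"))
  )
  new_scan1d(out, trait_name = ec$trait_name)
}

# row-major enumeration of pairs i < j; chunking never changes results
.pair_index <- function(m) {
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) seq.int(k + 1L, m)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' 2D association scan: per-pair interaction effects
#'
#' For each pair `i < j`, fits model II
#' \eqn{y = X\beta + Z_ia_i + Z_ja_j + W_{ij}\gamma_{ij} + e} with
#' \eqn{W_{ij} = Z_i * Z_j} (element-wise product) and tests
#' \eqn{H_0: \gamma_{ij} = 0} with the 1-df Wald statistic. Pairs are
#' enumerated row-major with `i < j` and processed in chunks; the output is
#' identical for any `chunk_size`. For panels above `dense_limit` markers a
#' `store_threshold` is required and only pairs with
#' \eqn{-\log_{10}(p) \ge} `store_threshold` are materialized.
#'
#' @param Z A [marker_matrix()] aligned with the eigen context.
#' @param ec An `episcan_eigen` context.
#' @param chunk_size Number of pairs assembled per output block (default
#'   512); a memory/batching knob only — every pair is fitted identically,
#'   so results are bit-identical across chunk sizes.
#' @param store_threshold Optional `-log10(p)` cutoff for sparse storage.
#' @param pair_subset Optional 2-column matrix/data frame of (i, j) marker
#'   indices restricting the scan to those pairs.
#' @param dense_limit Largest `m` for which full dense output is allowed
#'   without a `store_threshold` (default 2000).
#' @return An `episcan_scan2d` tibble with columns `marker_i`, `marker_j`,
#'   `gamma`, `var_gamma`, `wald`, `p`, `neglog10p`, `status`.
#' @export
scan_2d <- function(Z, ec, chunk_size = 512L, store_threshold = NULL,
                    pair_subset = NULL, dense_limit = 2000L) {
  m <- n_markers(Z)
  if (m < 2L) stop("no marker pairs: need at least 2 markers", call. = FALSE)
  n <- length(ec$y_star)
  if (n_individuals(Z) != n) stop("marker matrix not aligned with eigen context",
                                  call. = FALSE)
  if (is.null(pair_subset) && m > dense_limit && is.null(store_threshold)) {
    stop(sprintf("m = %d exceeds the dense storage cap (%d); set store_threshold",
                 m, dense_limit), call. = FALSE)
  }
  if (is.null(pair_subset)) {
    pairs <- .pair_index(m)
  } else {
    pairs <- as.matrix(pair_subset)[, 1:2, drop = FALSE]
    storage.mode(pairs) <- "integer"
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1L] == pairs[, 2L])) stop("pair_subset contains self-pairs",
                                              call. = FALSE)
  }
  w <- ec$Wdiag
  ys <- ec$y_star
  xs <- drop(crossprod(ec$U, rep(1, n)))
  Zc <- t(Z$values)                      # n x m, individuals x markers
  Zs <- crossprod(ec$U, Zc)              # rotated markers
  # weighted cross products that do not involve the pair product
  wZs <- Zs * w
  Gw <- crossprod(Zs, wZs)               # m x m: z_i' W z_j
  a0 <- drop(crossprod(Zs, w * xs))      # x' W z_i
  ay <- drop(crossprod(Zs, w * ys))      # y*' W z_i
  s00 <- sum(w * xs^2)
  s0y <- sum(w * xs * ys)
  syy <- sum(w * ys^2)
  np <- nrow(pairs)
  chunk_size <- max(1L, as.integer(chunk_size))
  res_list <- vector("list", ceiling(np / chunk_size))
  ids <- marker_ids(Z)
  wxs <- w * xs
  wys <- w * ys
  for (ck in seq_along(res_list)) {
    from <- (ck - 1L) * chunk_size + 1L
    to <- min(ck * chunk_size, np)
    ii <- pairs[from:to, 1L]
    jj <- pairs[from:to, 2L]
    nn <- length(ii)
    gamma <- var_g <- wald <- rep(NA_real_, nn)
    status <- rep("ok", nn)
    for (k in seq_len(nn)) {
      i <- ii[k]; j <- jj[k]
      # each pair product is rotated on its own so results are bit-identical
      # for every chunk size (chunking only batches the output)
      bs <- drop(crossprod(ec$U, Zc[, i] * Zc[, j]))
      wbs <- w * bs
      q0 <- sum(bs * wxs)
      qy <- sum(bs * wys)
      qq <- sum(bs * wbs)
      qi <- sum(wbs * Zs[, i])
      qj <- sum(wbs * Zs[, j])
      M <- matrix(c(s00,      a0[i],     a0[j],     q0,
                    a0[i],    Gw[i, i],  Gw[i, j],  qi,
                    a0[j],    Gw[i, j],  Gw[j, j],  qj,
                    q0,       qi,        qj,        qq), 4L, 4L)
      rhs <- c(s0y, ay[i], ay[j], qy)
      if (!all(is.finite(M)) || kappa(M, exact = FALSE) > 1e12) {
        status[k] <- "singular"
        next
      }
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv)) {
        status[k] <- "singular"
        next
      }
      b <- drop(Minv %*% rhs)
      rss <- syy - 2 * sum(b * rhs) + drop(crossprod(b, M %*% b))
      sigma2 <- max(rss, 0) / (n - 4)
      gamma[k] <- b[4L]
      var_g[k] <- Minv[4L, 4L] * sigma2
      wald[k] <- b[4L]^2 / (Minv[4L, 4L] * sigma2)
    }
    p <- ifelse(status == "ok", .p_from_wald(wald), NA_real_)
    df <- tibble::tibble(
      marker_i = ids[ii], marker_j = ids[jj],
      gamma = ifelse(status == "ok", gamma, NA_real_),
      var_gamma = ifelse(status == "ok", var_g, NA_real_),
      wald = ifelse(status == "ok", wald, NA_real_),
      p = p, neglog10p = -log10(p), status = status
    )
    if (!is.null(store_threshold)) {
      df <- df[!is.na(df$neglog10p) & df$neglog10p >= store_threshold, ,
               drop = FALSE]
    }
    res_list[[ck]] <- df
  }
  out <- dplyr::bind_rows(res_list)
  new_scan2d(out, trait_name = ec$trait_name, marker_ids = ids)
}

#' Conditional 1D slice of a 2D scan
#'
#' Extracts, for one focal marker, the significance of every pair it
#' participates in — the row/column of the 2D association matrix at that
#' marker, read as a conditional 1D association profile.
#'
#' @param res An `episcan_scan2d` result.
#' @param marker_id The focal marker.
#' @return A tibble with columns `marker_id` (the partner), `gamma`,
#'   `var_gamma`, `wald`, `p`, `neglog10p`, `status`, ordered by partner
#'   marker index.
#' @export
conditional_slice <- function(res, marker_id) {
  ids <- attr(res, "scan_marker_ids")
  if (is.null(ids)) ids <- sort(unique(c(res$marker_i, res$marker_j)))
  if (!marker_id %in% c(res$marker_i, res$marker_j)) {
    stop(sprintf("marker '%s' not present in 2D result", marker_id),
         call. = FALSE)
  }
  hit <- res$marker_i == marker_id | res$marker_j == marker_id
  sl <- res[hit, , drop = FALSE]
  partner <- ifelse(sl$marker_i == marker_id, sl$marker_j, sl$marker_i)
  out <- tibble::tibble(
    marker_id = partner,
    gamma = sl$gamma, var_gamma = sl$var_gamma, wald = sl$wald,
    p = sl$p, neglog10p = sl$neglog10p, status = sl$status
  )
  out[order(match(out$marker_id, ids)), , drop = FALSE]
}

#' Threshold the 2D scan into a sparse significant-pair list
#'
#' @param res An `episcan_scan2d` result.
#' @param th Significance threshold on `-log10(p)` (default 3.0, i.e.
#'   p = 0.001).
#' @return The qualifying `ok`-status pairs sorted by descending
#'   `neglog10p`, ties broken by (marker_i, marker_j) index order.
#' @export
threshold_pairs <- function(res, th = 3.0) {
  stopifnot(th >= 0)
  ids <- attr(res, "scan_marker_ids")
  keep <- res$status == "ok" & !is.na(res$neglog10p) & res$neglog10p >= th
  out <- res[keep, , drop = FALSE]
  if (is.null(ids)) {
    oi <- out$marker_i
    oj <- out$marker_j
  } else {
    oi <- match(out$marker_i, ids)
    oj <- match(out$marker_j, ids)
  }
  out[order(-out$neglog10p, oi, oj), , drop = FALSE]
}
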