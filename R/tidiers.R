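#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a variance-component fit
#'
#' @param x An `episcan_vc` object.
#' @param ... Unused.
#' @return A tibble with one row per variance component: `component`,
#'   `variance`, `ratio`, `lambda`.
#' @export
tidy.episcan_vc <- function(x, ...) {
  tibble::tibble(
    component = c("additive", "interaction", "residual"),
    variance = c(x$sigma2_a, x$sigma2_aa, x$sigma2_e),
    ratio = c(x$ratio_a, x$ratio_aa, x$ratio_e),
    lambda = c(x$lambda_a, x$lambda_aa, NA_real_)
  )
}

#' Summarize a variance-component fit in one row
#'
#' @param x An `episcan_vc` object.
#' @param ... Unused.
#' @return A one-row tibble: `trait`, `n`, `H`, `loglik`, `converged`,
#'   `n_restarts_used`.
#' @export
glance.episcan_vc <- function(x, ...) {
  tibble::tibble(trait = x$trait_name, n = x$n, H = x$H, loglik = x$loglik,
                 converged = x$converged, n_restarts_used = x$n_restarts_used)
}

#' Summarize a 1D scan in one row
#'
#' @param x An `episcan_scan1d` tibble.
#' @param ... Unused.
#' @return A one-row tibble: marker counts, the top marker and its
#'   significance.
#' @export
glance.episcan_scan1d <- function(x, ...) {
  ok <- x$status == "ok"
  top <- which.max(replace(x$neglog10p, !ok, -Inf))
  tibble::tibble(n_markers = nrow(x), n_ok = sum(ok),
                 top_marker = x$marker_id[top],
                 top_neglog10p = x$neglog10p[top])
}

#' Summarize a 2D scan in one row
#'
#' @param x An `episcan_scan2d` tibble.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, the top pair and its significance.
#' @export
glance.episcan_scan2d <- function(x, ...) {
  ok <- x$status == "ok"
  top <- which.max(replace(x$neglog10p, !ok, -Inf))
  tibble::tibble(n_pairs = nrow(x), n_ok = sum(ok),
                 top_pair = paste(x$marker_i[top], x$marker_j[top], sep = ":"),
                 top_neglog10p = x$neglog10p[top])
}
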