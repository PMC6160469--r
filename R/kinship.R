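#' Kinship matrices generated from omic markers
#'
#' The model's covariance structure uses two marker-generated relationship
#' matrices over individuals: the additive kinship
#' \deqn{K_a = \frac{1}{d_a} \sum_i Z_i Z_i^T, \qquad d_a = \mathrm{tr}\Big(\sum_i Z_i Z_i^T\Big)/n}
#' and the epistatic (additive-by-additive) kinship built from all element-wise
#' marker pair products \eqn{W_{ij} = Z_i * Z_j}:
#' \deqn{K_{aa} = \frac{1}{d_{aa}} \sum_{i<j} W_{ij} W_{ij}^T.}
#' The trace normalizers \eqn{d_a, d_{aa}} scale the diagonals to average 1,
#' so `trace(K) == n` for both matrices.
#'
#' `kinship_epistatic()` avoids the O(m^2) pair loop through the identity
#' \deqn{\Big[\sum_{i<j} W_{ij}W_{ij}^T\Big]_{kl} = \frac{G_{kl}^2 - S_{kl}}{2}}
#' with \eqn{G = \sum_i Z_i Z_i^T} and \eqn{S_{kl} = \sum_i Z_{ik}^2 Z_{il}^2},
#' which costs O(m n^2) — essential for transcriptome-scale panels where the
#' pair count reaches hundreds of millions. `kinship_epistatic_bruteforce()`
#' performs the literal double sum and serves as the correctness oracle for
#' small panels.
#'
#' @param Z A [marker_matrix()] (markers in rows, individuals in columns);
#'   `Z_i` denotes marker `i`'s values across individuals.
#'
#' @return `kinship_additive()` and the epistatic variants return a list with
#'   the `n x n` matrix (`K`) and its normalizer (`d`). `compute_kinships()`
#'   returns a [kinship_set()].
#' @name kinship
NULL

#' @rdname kinship
#' @export
kinship_additive <- function(Z) {
  M <- Z$values
  n <- ncol(M)
  G <- crossprod(M)              # sum_i Z_i Z_i^T
  d_a <- sum(diag(G)) / n
  if (d_a <= 0) stop("degenerate marker matrix: additive normalizer is zero",
                     call. = FALSE)
  list(K = G / d_a, d = d_a)
}

#' @rdname kinship
#' @export
kinship_epistatic <- function(Z) {
  M <- Z$values
  if (nrow(M) < 2L) stop("no marker pairs: need at least 2 markers", call. = FALSE)
  n <- ncol(M)
  G <- crossprod(M)
  S <- crossprod(M * M)
  P <- (G * G - S) / 2           # sum_{i<j} W_ij W_ij^T, closed form
  d_aa <- sum(diag(P)) / n
  if (d_aa <= 0) stop("degenerate marker matrix: epistatic normalizer is zero",
                      call. = FALSE)
  list(K = P / d_aa, d = d_aa)
}

#' @rdname kinship
#' @export
kinship_epistatic_bruteforce <- function(Z) {
  M <- Z$values
  m <- nrow(M)
  if (m < 2L) stop("no marker pairs: need at least 2 markers", call. = FALSE)
  n <- ncol(M)
  P <- matrix(0, n, n)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      w <- M[i, ] * M[j, ]
      P <- P + tcrossprod(w)
    }
  }
  d_aa <- sum(diag(P)) / n
  if (d_aa <= 0) stop("degenerate marker matrix: epistatic normalizer is zero",
                      call. = FALSE)
  list(K = P / d_aa, d = d_aa)
}

#' Bundle additive and epistatic kinships
#'
#' @param K_a,K_aa Normalized `n x n` kinship matrices.
#' @param d_a,d_aa Their positive trace normalizers.
#' @param individual_ids Individual identifiers (defaults to `K_a` rownames).
#' @param check Validate symmetry, positive semidefiniteness and trace
#'   normalization (`TRUE` by default).
#' @return An object of class `kinship_set`.
#' @export
kinship_set <- function(K_a, K_aa, d_a, d_aa,
                        individual_ids = rownames(K_a), check = TRUE) {
  n <- nrow(K_a)
  if (is.null(individual_ids)) individual_ids <- paste0("s", seq_len(n))
  if (check) {
    .check_kinship(K_a, n, "K_a")
    .check_kinship(K_aa, n, "K_aa")
    if (d_a <= 0 || d_aa <= 0) stop("normalizers must be positive", call. = FALSE)
  }
  dimnames(K_a) <- dimnames(K_aa) <- list(individual_ids, individual_ids)
  structure(list(K_a = K_a, K_aa = K_aa, d_a = d_a, d_aa = d_aa, n = n,
                 individual_ids = as.character(individual_ids)),
            class = "kinship_set")
}

.check_kinship <- function(K, n, name) {
  if (nrow(K) != n || ncol(K) != n) stop(name, " is not n x n", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-10) stop(name, " is not symmetric", call. = FALSE)
  if (abs(sum(diag(K)) - n) > 1e-8 * n) {
    stop(name, " trace is not normalized to n", call. = FALSE)
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop(name, " is not positive semidefinite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute both kinship matrices from a marker panel
#'
#' @inheritParams kinship
#' @return A [kinship_set()].
#' @examples
#' Z <- simulate_ril_genotypes(n = 30, m = 40, seed = 1)
#' K <- compute_kinships(Z)
#' round(sum(diag(K$K_a)) / K$n, 10)  # trace-normalized to 1 per individual
#' @export
compute_kinships <- function(Z) {
  a <- kinship_additive(Z)
  e <- kinship_epistatic(Z)
  kinship_set(a$K, e$K, a$d, e$d, individual_ids = individual_ids(Z))
}

#' @export
print.kinship_set <- function(x, ...) {
  cat(sprintf("<kinship_set> n = %d individuals; d_a = %.6g, d_aa = %.6g\n",
              x$n, x$d_a, x$d_aa))
  invisible(x)
}
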