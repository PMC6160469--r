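#' Construct a marker matrix
#'
#' The central data container of the package: an `m x n` numeric matrix of
#' omic markers (genotype bins coded numerically, log2 expression, log2
#' metabolite abundance, ...) with markers in rows and individuals in columns,
#' plus optional per-marker metadata.
#'
#' @param values Numeric matrix, markers in rows and individuals in columns.
#' @param marker_ids Character vector of unique marker identifiers (defaults
#'   to the rownames of `values`).
#' @param individual_ids Character vector of unique individual identifiers
#'   (defaults to the colnames of `values`).
#' @param meta Optional data frame of per-marker metadata with a `marker_id`
#'   column; recognised columns are `chromosome`, `position_index`, `bin_id`
#'   and `tissue`.
#'
#' @return An object of class `marker_matrix`.
#' @examples
#' z <- marker_matrix(matrix(c(1, -1, 1, -1, -1, 1), nrow = 3),
#'                    marker_ids = c("m1", "m2", "m3"),
#'                    individual_ids = c("s1", "s2"))
#' n_markers(z)
#' @export
marker_matrix <- function(values, marker_ids = rownames(values),
                          individual_ids = colnames(values), meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L) stop("marker matrix needs at least one marker", call. = FALSE)
  if (n < 2L) stop("marker matrix needs at least two individuals", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in marker matrix at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(m))
  if (is.null(individual_ids)) individual_ids <- paste0("s", seq_len(n))
  marker_ids <- as.character(marker_ids)
  individual_ids <- as.character(individual_ids)
  if (length(marker_ids) != m) stop("marker_ids length != nrow(values)", call. = FALSE)
  if (length(individual_ids) != n) stop("individual_ids length != ncol(values)", call. = FALSE)
  if (anyDuplicated(marker_ids)) {
    stop(sprintf("duplicated marker id: %s",
                 marker_ids[anyDuplicated(marker_ids)]), call. = FALSE)
  }
  if (anyDuplicated(individual_ids)) {
    stop(sprintf("duplicated individual id: %s",
                 individual_ids[anyDuplicated(individual_ids)]), call. = FALSE)
  }
  dimnames(values) <- list(marker_ids, individual_ids)
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    if (!"marker_id" %in% names(meta)) {
      stop("`meta` must contain a marker_id column", call. = FALSE)
    }
    meta <- meta[match(marker_ids, meta$marker_id), , drop = FALSE]
    meta$marker_id <- marker_ids
  }
  structure(list(values = values, meta = meta), class = "marker_matrix")
}

#' @rdname marker_matrix
#' @param x A `marker_matrix`.
#' @export
n_markers <- function(x) nrow(x$values)

#' @rdname marker_matrix
#' @export
n_individuals <- function(x) ncol(x$values)

#' @rdname marker_matrix
#' @export
marker_ids <- function(x) rownames(x$values)

#' @rdname marker_matrix
#' @export
individual_ids <- function(x) UseMethod("individual_ids")

#' @export
individual_ids.marker_matrix <- function(x) colnames(x$values)

#' @export
individual_ids.trait_vector <- function(x) names(x$values)

#' @export
individual_ids.kinship_set <- function(x) x$individual_ids

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d markers x %d individuals\n",
              n_markers(x), n_individuals(x)))
  if (!is.null(x$meta)) {
    cat("  metadata columns:", paste(setdiff(names(x$meta), "marker_id"),
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a trait vector
#'
#' A quantitative phenotype over `n` individuals. Values must be complete and
#' non-constant (a trait with zero variance cannot be mapped).
#'
#' @param values Numeric vector of phenotype values.
#' @param individual_ids Character identifiers, one per value.
#' @param trait_name Name of the trait (e.g., `"YIELD"`).
#'
#' @return An object of class `trait_vector`.
#' @export
trait_vector <- function(values, individual_ids = names(values),
                         trait_name = "trait") {
  values <- as.numeric(values)
  if (anyNA(values)) stop("trait has missing values", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("trait needs at least two individuals", call. = FALSE)
  if (is.null(individual_ids)) individual_ids <- paste0("s", seq_len(n))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != n) {
    stop("individual_ids length != length(values)", call. = FALSE)
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicated individual id in trait", call. = FALSE)
  }
  if (stats::var(values) <= 0) {
    stop("trait has zero variance", call. = FALSE)
  }
  names(values) <- individual_ids
  structure(list(values = values, trait_name = trait_name),
            class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat(sprintf("<trait_vector> '%s', %d individuals\n", x$trait_name,
              length(x$values)))
  invisible(x)
}

#' Construct a transcript-to-bin map
#'
#' Maps transcript (or other omic marker) identifiers into ordered genotype
#' bins along chromosomes, for bin-level reduction of scan results.
#'
#' @param entries Data frame with columns `marker_id` and `bin_id`; each
#'   marker maps to at most one bin.
#' @param bin_order Character vector giving the positional order of bins; must
#'   be unique. Defaults to the order of first appearance in `entries`.
#'
#' @return An object of class `bin_map`.
#' @export
bin_map <- function(entries, bin_order = NULL) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("marker_id", "bin_id") %in% names(entries))) {
    stop("`entries` needs marker_id and bin_id columns", call. = FALSE)
  }
  entries <- entries[, c("marker_id", "bin_id")]
  entries$marker_id <- as.character(entries$marker_id)
  entries$bin_id <- as.character(entries$bin_id)
  if (anyDuplicated(entries$marker_id)) {
    stop("a marker maps to more than one bin", call. = FALSE)
  }
  if (is.null(bin_order)) bin_order <- unique(entries$bin_id)
  bin_order <- as.character(bin_order)
  if (anyDuplicated(bin_order)) stop("bin_order has duplicates", call. = FALSE)
  structure(list(entries = entries, bin_order = bin_order), class = "bin_map")
}
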