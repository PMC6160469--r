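# CSV dialect used throughout: comma separator, '.' decimal, UTF-8, header
# row mandatory on matrix files, no quoting of numeric fields.

#' Read a marker matrix from CSV
#'
#' The expected layout is `marker_id,<ind1>,...,<indN>` with one header row of
#' individual identifiers and numeric rows. Missing or non-numeric cells are
#' rejected (the model assumes complete data; imputation is out of scope).
#'
#' @param path Path to the marker CSV.
#' @param meta_path Optional path to a per-marker metadata CSV with columns
#'   `marker_id,chromosome,position_index,bin_id,tissue` (any subset beyond
#'   `marker_id`).
#'
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, meta_path = NULL) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 3L) stop("marker CSV needs an id column and >= 2 individuals",
                           call. = FALSE)
  ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  .check_numeric_cells(body, ids, colnames(body), what = "marker CSV")
  values <- matrix(as.numeric(body), nrow = nrow(body),
                   dimnames = list(ids, colnames(body)))
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, header = TRUE, check.names = FALSE,
                            fileEncoding = "UTF-8",
                            colClasses = "character")
    if ("position_index" %in% names(meta)) {
      meta$position_index <- as.integer(meta$position_index)
    }
  }
  marker_matrix(values, meta = meta)
}

.check_numeric_cells <- function(chr_mat, row_ids, col_ids, what) {
  empty <- !nzchar(trimws(chr_mat)) | is.na(chr_mat)
  if (any(empty)) {
    bad <- which(empty, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: missing value for marker '%s', individual '%s'",
                 what, row_ids[bad[1L]], col_ids[bad[2L]]), call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(chr_mat))
  if (anyNA(num)) {
    bad <- which(matrix(is.na(num), nrow = nrow(chr_mat)), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric cell '%s' for marker '%s', individual '%s'",
                 what, chr_mat[bad[1L], bad[2L]], row_ids[bad[1L]],
                 col_ids[bad[2L]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a marker matrix to CSV
#'
#' @param x A [marker_matrix()].
#' @param path Output path.
#' @param meta_path Optional path for the metadata CSV.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(x, path, meta_path = NULL) {
  df <- data.frame(marker_id = marker_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path) && !is.null(x$meta)) {
    utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a trait vector from CSV
#'
#' Accepts a two-column `individual_id,value` file (with or without a header
#' line) or a single column of values headed by the trait name, in which case
#' individual identifiers `s1..sN` are generated.
#'
#' @param path Path to the trait CSV.
#' @param trait_name Trait name; defaults to the file's header (if any) or
#'   the file name.
#' @return A [trait_vector()].
#' @export
read_trait <- function(path, trait_name = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trait file", call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  width <- unique(lengths(fields))
  if (length(width) != 1L || !width %in% c(1L, 2L)) {
    stop("trait CSV must have one or two columns", call. = FALSE)
  }
  if (width == 2L) {
    second <- vapply(fields, `[`, "", 2L)
    has_header <- is.na(suppressWarnings(as.numeric(second[1L])))
    if (has_header) {
      if (is.null(trait_name)) trait_name <- second[1L]
      fields <- fields[-1L]
      second <- second[-1L]
    }
    vals <- suppressWarnings(as.numeric(second))
    ids <- vapply(fields, `[`, "", 1L)
  } else {
    first <- vapply(fields, `[`, "", 1L)
    if (is.na(suppressWarnings(as.numeric(first[1L])))) {
      if (is.null(trait_name)) trait_name <- first[1L]
      first <- first[-1L]
    }
    vals <- suppressWarnings(as.numeric(first))
    ids <- paste0("s", seq_along(vals))
  }
  if (anyNA(vals)) {
    stop(sprintf("trait CSV: non-numeric or missing value at data row %d",
                 which(is.na(vals))[1L]), call. = FALSE)
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  trait_vector(vals, ids, trait_name)
}

#' Write a trait vector to CSV
#'
#' @param y A [trait_vector()].
#' @param path Output path.
#' @param header Write an `individual_id,<trait_name>` header line?
#' @return `path`, invisibly.
#' @export
write_trait <- function(y, path, header = FALSE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines(paste0("individual_id,", y$trait_name), con)
  writeLines(paste0(names(y$values), ",",
                    formatC(y$values, digits = 17, format = "g")), con)
  invisible(path)
}

#' Align a marker matrix and a trait to a common individual order
#'
#' Both objects are restricted to the intersection of their individual
#' identifiers and reordered to the trait's order; dropped individuals are
#' reported with a message. The operation is idempotent.
#'
#' @param Z A [marker_matrix()].
#' @param y A [trait_vector()].
#' @return A list with elements `Z` and `y`, aligned.
#' @export
align_samples <- function(Z, y) {
  zid <- individual_ids(Z)
  yid <- individual_ids(y)
  common <- yid[yid %in% zid]
  if (length(common) < 3L) {
    stop(sprintf("only %d individuals shared between markers and trait (>= 3 required)",
                 length(common)), call. = FALSE)
  }
  drop_z <- length(zid) - length(common)
  drop_y <- length(yid) - length(common)
  if (drop_z > 0L || drop_y > 0L) {
    message(sprintf("align_samples: dropped %d marker-side and %d trait-side individuals",
                    drop_z, drop_y))
  }
  Z2 <- marker_matrix(Z$values[, common, drop = FALSE], meta = Z$meta)
  y2 <- trait_vector(y$values[common], common, y$trait_name)
  list(Z = Z2, y = y2)
}

#' Write pipeline result objects to disk
#'
#' Dispatches on the result type: kinship sets are written as square CSV
#' matrices with individual identifiers on the first row/column (plus a
#' `*_normalizers.csv` companion), variance components as `key,value` lines,
#' and 1D/2D scan tables as CSV with a fixed column order. Output is
#' byte-stable across runs on identical input.
#'
#' @param obj A `kinship_set`, `episcan_vc`, `episcan_scan1d` or
#'   `episcan_scan2d` object.
#' @param path Output path (for kinship sets, a stem: `<stem>_Ka.csv`,
#'   `<stem>_Kaa.csv`, `<stem>_normalizers.csv`).
#' @return The path(s) written, invisibly.
#' @export
write_results <- function(obj, path) UseMethod("write_results")

.write_square <- function(M, ids, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", ids), collapse = ","), con)
  body <- apply(M, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = ",")
  })
  writeLines(paste0(ids, ",", body), con)
  invisible(path)
}

#' @export
write_results.kinship_set <- function(obj, path) {
  p1 <- paste0(path, "_Ka.csv")
  p2 <- paste0(path, "_Kaa.csv")
  p3 <- paste0(path, "_normalizers.csv")
  .write_square(obj$K_a, obj$individual_ids, p1)
  .write_square(obj$K_aa, obj$individual_ids, p2)
  writeLines(c(sprintf("d_a,%s", formatC(obj$d_a, digits = 17, format = "g")),
               sprintf("d_aa,%s", formatC(obj$d_aa, digits = 17, format = "g"))),
             p3)
  invisible(c(p1, p2, p3))
}

#' @export
write_results.episcan_vc <- function(obj, path) {
  keys <- c("sigma2_a", "sigma2_aa", "sigma2_e", "lambda_a", "lambda_aa",
            "ratio_a", "ratio_aa", "ratio_e", "H")
  vals <- c(obj$sigma2_a, obj$sigma2_aa, obj$sigma2_e, obj$lambda_a,
            obj$lambda_aa, obj$ratio_a, obj$ratio_aa, obj$ratio_e, obj$H)
  writeLines(paste0(keys, ",", formatC(vals, digits = 17, format = "g")), path)
  invisible(path)
}

.write_scan_csv <- function(df, cols, path) {
  out <- df[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  for (j in which(num)) out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.episcan_scan1d <- function(obj, path) {
  .write_scan_csv(obj, c("marker_id", "effect", "var_effect", "wald", "p",
                         "neglog10p", "status"), path)
}

#' @export
write_results.episcan_scan2d <- function(obj, path) {
  .write_scan_csv(obj, c("marker_i", "marker_j", "gamma", "var_gamma", "wald",
                         "p", "neglog10p", "status"), path)
}

#' Read back a written kinship set
#'
#' @param path The stem used in [write_results()].
#' @return A `kinship_set`.
#' @export
read_kinship <- function(path) {
  rd <- function(p) {
    df <- utils::read.csv(p, header = TRUE, check.names = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- df[[1L]]
    M
  }
  Ka <- rd(paste0(path, "_Ka.csv"))
  Kaa <- rd(paste0(path, "_Kaa.csv"))
  nm <- utils::read.csv(paste0(path, "_normalizers.csv"), header = FALSE)
  kinship_set(Ka, Kaa, d_a = nm$V2[nm$V1 == "d_a"],
              d_aa = nm$V2[nm$V1 == "d_aa"],
              individual_ids = rownames(Ka))
}

#' Read back a written 1D scan table
#'
#' @param path Path written by [write_results()].
#' @return An `episcan_scan1d` tibble.
#' @export
read_scan1d <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, header = TRUE,
                                          check.names = FALSE,
                                          colClasses = c(marker_id = "character",
                                                         status = "character")))
  new_scan1d(df)
}

#' Read back a written variance-component file
#'
#' @param path Path written by [write_results()].
#' @return A named list of the nine stored values.
#' @export
read_varcomp <- function(path) {
  kv <- utils::read.csv(path, header = FALSE,
                        colClasses = c("character", "numeric"))
  stats::setNames(as.list(kv$V2), kv$V1)
}
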