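#' Pipeline runner configuration
#'
#' A flat key-value configuration shared by the pipeline wrappers and the
#' command-line entry point. Recognised keys: `marker_csv`, `meta_csv`,
#' `trait_csv`, `out_dir`, `chunk_size`, `store_threshold`,
#' `network_threshold`, `seed`, `standardize`, `additive_only_pred`,
#' `run_2d`. Unknown keys are rejected. Every key can be overridden by a
#' `key=value` command-line flag.
#'
#' @param path Optional path of a config file with one `key=value` per line
#'   (`#` comments allowed).
#' @param overrides Named character vector/list of overrides.
#' @return A named list with parsed, typed values.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(marker_csv = NULL, meta_csv = NULL, trait_csv = NULL,
                   out_dir = ".", chunk_size = 512L, store_threshold = NULL,
                   network_threshold = 3.0, seed = 1L, standardize = FALSE,
                   additive_only_pred = FALSE, run_2d = TRUE)
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop("bad config line: ", ln, call. = FALSE)
      kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
    }
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, kv)
  cfg$chunk_size <- as.integer(cfg$chunk_size)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$store_threshold)) {
    cfg$store_threshold <- as.numeric(cfg$store_threshold)
  }
  cfg$network_threshold <- as.numeric(cfg$network_threshold)
  for (k in c("standardize", "additive_only_pred", "run_2d")) {
    cfg[[k]] <- as.logical(cfg[[k]])
  }
  cfg
}

.write_config <- function(cfg, out_dir) {
  keep <- !vapply(cfg, is.null, TRUE)
  writeLines(paste0(names(cfg)[keep], "=",
                    vapply(cfg[keep], function(v) paste(v, collapse = ","), "")),
             file.path(out_dir, "run_config.txt"))
}

.load_markers <- function(cfg) {
  if (is.null(cfg$marker_csv)) stop("config is missing marker_csv", call. = FALSE)
  if (!file.exists(cfg$marker_csv)) {
    stop(sprintf("expected marker file not found: %s", cfg$marker_csv),
         call. = FALSE)
  }
  Z <- read_marker_matrix(cfg$marker_csv, meta_path = cfg$meta_csv)
  if (isTRUE(cfg$standardize)) {
    ctr <- Z$values - rowMeans(Z$values)
    sdv <- sqrt(rowSums(ctr^2) / (ncol(ctr) - 1))
    sdv[sdv == 0] <- 1
    Z <- marker_matrix(ctr / sdv, meta = Z$meta)
  }
  Z
}

#' Compute and write kinship matrices for a marker panel
#'
#' @param cfg A [run_config()] list with at least `marker_csv` and `out_dir`.
#' @return The [kinship_set()], invisibly; writes `kinship_Ka.csv`,
#'   `kinship_Kaa.csv` and `kinship_normalizers.csv` to `out_dir`.
#' @export
run_kinship <- function(cfg) {
  Z <- .load_markers(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # write the additive kinship even when the panel has no pairs, so a
  # single-marker panel still yields its K_a before the epistatic error
  a <- kinship_additive(Z)
  .write_square(a$K, individual_ids(Z), file.path(cfg$out_dir, "kinship_Ka.csv"))
  e <- kinship_epistatic(Z)
  K <- kinship_set(a$K, e$K, a$d, e$d, individual_ids = individual_ids(Z))
  write_results(K, file.path(cfg$out_dir, "kinship"))
  message(sprintf("kinship: m = %d markers, n = %d individuals",
                  n_markers(Z), n_individuals(Z)))
  invisible(K)
}

#' Estimate and write the variance components for a trait
#'
#' @param cfg A [run_config()] list with `marker_csv`, `trait_csv`, `out_dir`.
#' @return The `episcan_vc` fit, invisibly; writes `varcomp.csv`.
#' @export
run_varcomp <- function(cfg) {
  Z <- .load_markers(cfg)
  if (is.null(cfg$trait_csv) || !file.exists(cfg$trait_csv %||% "")) {
    stop(sprintf("expected trait file not found: %s",
                 cfg$trait_csv %||% "<unset>"), call. = FALSE)
  }
  al <- align_samples(Z, read_trait(cfg$trait_csv))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  vc <- estimate_variance_components(al$y, compute_kinships(al$Z))
  write_results(vc, file.path(cfg$out_dir, "varcomp.csv"))
  invisible(vc)
}

.scan_inputs <- function(cfg) {
  Z <- .load_markers(cfg)
  if (is.null(cfg$trait_csv) || !file.exists(cfg$trait_csv %||% "")) {
    stop(sprintf("expected trait file not found: %s",
                 cfg$trait_csv %||% "<unset>"), call. = FALSE)
  }
  al <- align_samples(Z, read_trait(cfg$trait_csv))
  K <- compute_kinships(al$Z)
  vc <- estimate_variance_components(al$y, K)
  list(Z = al$Z, y = al$y, K = K, vc = vc,
       ec = build_eigen_context(K, vc, al$y))
}

#' Run the 1D scan and write its CSV
#'
#' @param cfg A [run_config()] list.
#' @return The `episcan_scan1d` result, invisibly; writes `scan1d.csv`.
#' @export
run_scan1d <- function(cfg) {
  inp <- .scan_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- scan_1d(inp$Z, inp$ec)
  write_results(res, file.path(cfg$out_dir, "scan1d.csv"))
  invisible(res)
}

#' Run the 2D scan and write its CSV
#'
#' @param cfg A [run_config()] list; honors `chunk_size` and
#'   `store_threshold` (output is identical for any chunk size).
#' @return The `episcan_scan2d` result, invisibly; writes `scan2d.csv`.
#' @export
run_scan2d <- function(cfg) {
  inp <- .scan_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- scan_2d(inp$Z, inp$ec, chunk_size = cfg$chunk_size,
                 store_threshold = cfg$store_threshold)
  write_results(res, file.path(cfg$out_dir, "scan2d.csv"))
  invisible(res)
}

#' One-shot pipeline: kinships, variance components, 1D and 2D scans
#'
#' Runs the full analysis chain on one marker panel and one trait, writing
#' every artifact (kinship CSVs, variance-component file, scan CSVs, the
#' serialized configuration) into `out_dir`.
#'
#' @param cfg A [run_config()] list.
#' @return A list with `K`, `vc`, `scan1`, and (when `run_2d`) `scan2`,
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  Z <- .load_markers(cfg)
  if (is.null(cfg$trait_csv) || !file.exists(cfg$trait_csv %||% "")) {
    stop(sprintf("expected trait file not found: %s",
                 cfg$trait_csv %||% "<unset>"), call. = FALSE)
  }
  al <- align_samples(Z, read_trait(cfg$trait_csv))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_config(cfg, cfg$out_dir)
  K <- compute_kinships(al$Z)
  write_results(K, file.path(cfg$out_dir, "kinship"))
  vc <- estimate_variance_components(al$y, K)
  write_results(vc, file.path(cfg$out_dir, "varcomp.csv"))
  ec <- build_eigen_context(K, vc, al$y)
  s1 <- scan_1d(al$Z, ec)
  write_results(s1, file.path(cfg$out_dir, "scan1d.csv"))
  out <- list(K = K, vc = vc, scan1 = s1)
  if (isTRUE(cfg$run_2d)) {
    s2 <- scan_2d(al$Z, ec, chunk_size = cfg$chunk_size,
                  store_threshold = cfg$store_threshold)
    write_results(s2, file.path(cfg$out_dir, "scan2d.csv"))
    out$scan2 <- s2
  }
  invisible(out)
}

#' Write a synthetic dataset (genotypes, trait, truth) to disk
#'
#' @param out_dir Output directory.
#' @param n,m,n_chrom,switch_prob Passed to [simulate_ril_genotypes()].
#' @param sigma2_a,sigma2_aa,sigma2_e Passed to [simulate_trait()].
#' @param seed Integer seed.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(out_dir, n = 210, m = 200, n_chrom = 12,
                         switch_prob = 0.1, sigma2_a = 0.4, sigma2_aa = 0.3,
                         sigma2_e = 0.3, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Z <- simulate_ril_genotypes(n, m, n_chrom = n_chrom,
                              switch_prob = switch_prob, seed = seed)
  sim <- simulate_trait(Z, sigma2_a, sigma2_aa, sigma2_e, seed = seed)
  p1 <- file.path(out_dir, "markers.csv")
  p2 <- file.path(out_dir, "markers_meta.csv")
  p3 <- file.path(out_dir, "trait.csv")
  p4 <- file.path(out_dir, "truth.csv")
  write_marker_matrix(Z, p1, meta_path = p2)
  write_trait(sim$y, p3)
  rr <- sim$truth$realized_ratios
  writeLines(c(sprintf("beta,%g", sim$truth$beta),
               sprintf("realized_ratio_additive,%.17g", rr[1L]),
               sprintf("realized_ratio_interaction,%.17g", rr[2L]),
               sprintf("realized_ratio_residual,%.17g", rr[3L])), p4)
  invisible(c(p1, p2, p3, p4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exit codes for the command-line wrapper:
#   2 validation/degenerate input, 3 non-convergence, 4 I/O
.classify_error <- function(msg) {
  if (grepl("not found|cannot open|unwritable|No such file", msg)) return(4L)
  if (grepl("converge", msg)) return(3L)
  2L
}

#' Command-line dispatcher
#'
#' Backs the `exec/episcan` script. Usage:
#' `episcan <subcommand> [config=FILE] [key=value ...]` with subcommands
#' `km-cal` (kinships), `vc-anal` (variance components), `ps-main` (1D scan),
#' `ps-inter` (2D scan), `pipeline`, and `simulate`. All [run_config()] keys
#' are accepted as `key=value` flags; `config=FILE` loads a flat key-value
#' file first, flags override it.
#'
#' @param args Character vector of command-line arguments.
#' @return An integer exit status (0 on success; 2 validation, 3
#'   convergence, 4 I/O failure).
#' @export
episcan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: episcan <km-cal|vc-anal|ps-main|ps-inter|pipeline|simulate>",
        "[config=FILE] [key=value ...]\n")
    return(invisible(1L))
  }
  sub <- args[1L]
  flags <- args[-1L]
  kv <- list()
  for (f in flags) {
    parts <- strsplit(f, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      message("ignoring malformed flag: ", f)
      next
    }
    kv[[parts[1L]]] <- paste(parts[-1L], collapse = "=")
  }
  cfg_path <- kv$config
  kv$config <- NULL
  status <- tryCatch({
    if (sub == "simulate") {
      sim_kv <- kv
      out_dir <- sim_kv$out_dir %||% "."
      sim_kv$out_dir <- NULL
      num <- lapply(sim_kv, as.numeric)
      do.call(run_simulate, c(list(out_dir = out_dir), num))
      0L
    } else {
      cfg <- run_config(cfg_path, overrides = kv)
      switch(sub,
             "km-cal" = run_kinship(cfg),
             "vc-anal" = run_varcomp(cfg),
             "ps-main" = run_scan1d(cfg),
             "ps-inter" = run_scan2d(cfg),
             "pipeline" = run_pipeline(cfg),
             stop("unknown subcommand: ", sub, call. = FALSE))
      0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    .classify_error(conditionMessage(e))
  })
  invisible(status)
}
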