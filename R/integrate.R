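#' Reduce a transcript panel to one representative per genotype bin
#'
#' Transcript panels are an order of magnitude larger than genotype-bin
#' panels; to compare variance decompositions on an equal footing, each bin
#' keeps only its most trait-associated transcript: the one with the highest
#' \eqn{-\log_{10}(p)} in the 1D scan (ties broken by lowest marker index).
#' Scanned markers absent from the bin map are dropped with a message.
#'
#' @param scan An `episcan_scan1d` result over the transcript panel.
#' @param binmap A [bin_map()] assigning transcripts to ordered bins.
#' @param Z The transcript [marker_matrix()] the scan was run on.
#' @return A list with `reduced` (a [marker_matrix()] of representative rows,
#'   ordered by `bin_order`) and `representative` (tibble `bin_id,marker_id`).
#' @export
reduce_to_bins <- function(scan, binmap, Z) {
  entries <- binmap$entries
  hit <- scan$marker_id %in% entries$marker_id
  if (!any(hit)) stop("no scanned marker appears in the bin map", call. = FALSE)
  if (any(!hit)) {
    message(sprintf("reduce_to_bins: dropped %d markers absent from the bin map",
                    sum(!hit)))
  }
  df <- tibble::tibble(marker_id = scan$marker_id,
                       neglog10p = scan$neglog10p,
                       idx = seq_len(nrow(scan)))[hit, ]
  df$bin_id <- entries$bin_id[match(df$marker_id, entries$marker_id)]
  rep_tab <- df |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::arrange(dplyr::desc(.data$neglog10p), .data$idx,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  ord <- binmap$bin_order[binmap$bin_order %in% rep_tab$bin_id]
  rep_tab <- rep_tab[match(ord, rep_tab$bin_id), ]
  reduced <- marker_matrix(Z$values[rep_tab$marker_id, , drop = FALSE],
                           marker_ids = rep_tab$marker_id)
  list(reduced = reduced,
       representative = tibble::tibble(bin_id = rep_tab$bin_id,
                                       marker_id = rep_tab$marker_id))
}

#' Bin-level summary of a 1D scan
#'
#' Collapses per-transcript significances to one value per genotype bin — the
#' maximum \eqn{-\log_{10}(p)} (equivalently the minimum p) among the bin's
#' transcripts — so genotype- and transcript-level Manhattan profiles can be
#' positionally aligned. Bins with no mapped transcript emit an `NA` row.
#'
#' @inheritParams reduce_to_bins
#' @return A tibble `bin_id,neglog10p` with one row per bin in `bin_order`.
#' @export
bin_level_minp <- function(scan, binmap) {
  entries <- binmap$entries
  df <- tibble::tibble(marker_id = scan$marker_id,
                       neglog10p = scan$neglog10p)
  df$bin_id <- entries$bin_id[match(df$marker_id, entries$marker_id)]
  df <- df[!is.na(df$bin_id), ]
  agg <- df |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(neglog10p = if (all(is.na(.data$neglog10p))) NA_real_
                     else max(.data$neglog10p, na.rm = TRUE),
                     .groups = "drop")
  tibble::tibble(
    bin_id = binmap$bin_order,
    neglog10p = agg$neglog10p[match(binmap$bin_order, agg$bin_id)]
  )
}

#' Tissue-stratified top-n table of a 1D scan
#'
#' Ranks markers by ascending p-value (ties broken by marker index order) and,
#' for each requested `top_n`, reports the significance threshold attained by
#' the `top_n`-th marker and the tissue composition of the selection —
#' e.g., how many of the top metabolites come from leaf versus seed.
#'
#' @param scan An `episcan_scan1d` result.
#' @param tissue Character vector of tissue labels (`"leaf"`, `"seed"`, or
#'   other), one per scanned marker (or named by marker_id).
#' @param top_ns Integer vector of selection sizes, each at most the number
#'   of `ok`-status markers.
#' @return A tibble `top_n,significance_th,n_leaf,n_seed` (plus `n_other`
#'   when other labels occur). `n_leaf + n_seed (+ n_other) = top_n` and
#'   `significance_th` is non-increasing in `top_n`.
#' @export
tissue_topn_table <- function(scan, tissue, top_ns) {
  m <- nrow(scan)
  if (!is.null(names(tissue))) tissue <- tissue[scan$marker_id]
  if (length(tissue) != m) stop("`tissue` must label every scanned marker",
                                call. = FALSE)
  ok <- scan$status == "ok"
  ordx <- order(scan$p[ok], which(ok))
  ranked_sig <- scan$neglog10p[ok][ordx]
  ranked_tissue <- as.character(tissue)[ok][ordx]
  if (any(top_ns > length(ranked_sig))) {
    stop("a top_n exceeds the number of usable markers", call. = FALSE)
  }
  has_other <- any(!ranked_tissue %in% c("leaf", "seed"))
  rows <- lapply(sort(as.integer(top_ns)), function(k) {
    sel <- ranked_tissue[seq_len(k)]
    out <- tibble::tibble(top_n = k,
                          significance_th = ranked_sig[k],
                          n_leaf = sum(sel == "leaf"),
                          n_seed = sum(sel == "seed"))
    if (has_other) out$n_other <- sum(!sel %in% c("leaf", "seed"))
    out
  })
  dplyr::bind_rows(rows)
}

#' Build a weighted association network from significant pairs
#'
#' Nodes are markers and each edge is a significant marker pair weighted by
#' its \eqn{-\log_{10}(p)}; optionally restricted to edges incident to one
#' focal (hub) marker.
#'
#' @param pairs A thresholded pair tibble (from [threshold_pairs()]) sorted
#'   by significance, with columns `marker_i`, `marker_j`, `neglog10p`.
#' @param mode `"top_k"` keeps the `k` most significant pairs; `"threshold"`
#'   keeps pairs with `neglog10p >= th`.
#' @param k Number of pairs in `top_k` mode (default 10).
#' @param th Weight threshold in `threshold` mode (default 3.0).
#' @param focal Optional focal marker id; only its incident edges are kept.
#' @return An `episcan_network` object: list with `nodes`, `edges` (tibble
#'   `marker_i,marker_j,weight`), and `focal`. An empty selection gives an
#'   empty network.
#' @export
build_network <- function(pairs, mode = c("top_k", "threshold"), k = 10L,
                          th = 3.0, focal = NULL) {
  mode <- match.arg(mode)
  ed <- tibble::tibble(marker_i = pairs$marker_i, marker_j = pairs$marker_j,
                       weight = pairs$neglog10p)
  ed <- ed[order(-ed$weight), ]
  if (mode == "top_k") {
    ed <- utils::head(ed, k)
  } else {
    ed <- ed[ed$weight >= th, ]
  }
  if (!is.null(focal)) {
    ed <- ed[ed$marker_i == focal | ed$marker_j == focal, ]
  }
  structure(list(nodes = unique(c(ed$marker_i, ed$marker_j)),
                 edges = ed, focal = focal),
            class = "episcan_network")
}

#' @export
print.episcan_network <- function(x, ...) {
  cat(sprintf("<episcan_network> %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges),
              if (!is.null(x$focal)) paste0("; focal = ", x$focal) else ""))
  invisible(x)
}

#' Degree of every node in an association network
#'
#' @param net An `episcan_network`.
#' @return A tibble `marker_id,degree` sorted by decreasing degree.
#' @export
network_degrees <- function(net) {
  cnt <- table(c(net$edges$marker_i, net$edges$marker_j))
  out <- tibble::tibble(marker_id = names(cnt), degree = as.integer(cnt))
  out[order(-out$degree, out$marker_id), ]
}

#' Export an association network as an edge-list TSV
#'
#' Format: `marker_i<TAB>marker_j<TAB>neglog10p`, one edge per line.
#'
#' @param net An `episcan_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$edges$marker_i, net$edges$marker_j,
                   formatC(net$edges$weight, digits = 17, format = "g"))
  writeLines(c("marker_i\tmarker_j\tneglog10p", lines), path)
  invisible(path)
}

#' Convert an association network to igraph
#'
#' @param net An `episcan_network`.
#' @return An `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  }
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$marker_i, to = net$edges$marker_j,
               weight = net$edges$weight),
    directed = FALSE,
    vertices = net$nodes)
}
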