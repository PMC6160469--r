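# a tiny deterministic 1D scan table used across integration tests
fake_scan1d <- function(p, ids = paste0("t", seq_along(p)),
                        status = rep("ok", length(p))) {
  episcan:::new_scan1d(tibble::tibble(
    marker_id = ids, effect = 0, var_effect = 1, wald = 0, p = p,
    neglog10p = -log10(p), status = status))
}

test_that("bin reduction keeps the most significant transcript per bin", {
  Z <- rand_panel(6, 5, seed = 1)
  Z <- marker_matrix(Z$values, marker_ids = paste0("t", 1:6))
  bm <- bin_map(data.frame(marker_id = paste0("t", 1:6),
                           bin_id = c("b1", "b1", "b1", "b2", "b3", "b3")),
                bin_order = c("b1", "b2", "b3"))
  # b1 significances 1.2, 3.4, 0.5 -> t2 represents b1
  sc <- fake_scan1d(10^(-c(1.2, 3.4, 0.5, 2.0, 1.0, 1.0)))
  red <- reduce_to_bins(sc, bm, Z)
  expect_equal(red$representative$bin_id, c("b1", "b2", "b3"))
  expect_equal(red$representative$marker_id[1], "t2")
  expect_equal(red$representative$marker_id[2], "t4")
  expect_equal(red$representative$marker_id[3], "t5")  # tie in b3 -> lower index
  expect_equal(marker_ids(red$reduced), red$representative$marker_id)
  expect_equal(red$reduced$values["t2", ], Z$values["t2", ])
})

test_that("one-transcript-per-bin reduction is a reorder of the input", {
  Z <- rand_panel(4, 5, seed = 2)
  Z <- marker_matrix(Z$values, marker_ids = paste0("t", 1:4))
  bm <- bin_map(data.frame(marker_id = paste0("t", 1:4),
                           bin_id = paste0("b", c(3, 1, 4, 2))),
                bin_order = paste0("b", 1:4))
  sc <- fake_scan1d(c(0.5, 0.01, 0.2, 0.3))
  red <- reduce_to_bins(sc, bm, Z)
  expect_equal(marker_ids(red$reduced), c("t2", "t4", "t1", "t3"))
  expect_equal(red$reduced$values, Z$values[c("t2", "t4", "t1", "t3"), ],
               ignore_attr = TRUE)

  # unmapped markers are dropped with a message; empty intersection errors
  sc2 <- fake_scan1d(c(0.5, 0.01), ids = c("t1", "zz"))
  expect_message(reduce_to_bins(sc2, bm, Z), "dropped 1")
  expect_error(reduce_to_bins(fake_scan1d(0.1, ids = "nope"), bm, Z),
               "no scanned marker")
})

test_that("bin-level summary takes the per-bin maximum significance", {
  bm <- bin_map(data.frame(marker_id = paste0("t", 1:4),
                           bin_id = c("b1", "b2", "b2", "b2")),
                bin_order = c("b1", "b2", "bEmpty"))
  sc <- fake_scan1d(10^(-c(7, 2, 5, 3)))
  out <- bin_level_minp(sc, bm)
  expect_equal(out$bin_id, c("b1", "b2", "bEmpty"))
  expect_equal(out$neglog10p, c(7, 5, NA), tolerance = 1e-12)
  expect_equal(nrow(out), 3L)  # one row per bin in bin_order
})

test_that("tissue top-n table counts and thresholds behave like a sort", {
  p <- withr::with_seed(3, runif(30))
  tissue <- rep(c("leaf", "seed"), 15)
  sc <- fake_scan1d(p, ids = paste0("M", 1:30))
  tab <- tissue_topn_table(sc, tissue, top_ns = c(5, 10, 20))
  # naive oracle: sort by p, count labels
  ord <- order(p, seq_along(p))
  for (r in seq_len(nrow(tab))) {
    k <- tab$top_n[r]
    sel <- tissue[ord][1:k]
    expect_equal(tab$n_leaf[r], sum(sel == "leaf"))
    expect_equal(tab$n_seed[r], sum(sel == "seed"))
    expect_equal(tab$n_leaf[r] + tab$n_seed[r], k)
    expect_equal(tab$significance_th[r], -log10(p[ord][k]), tolerance = 1e-12)
  }
  expect_true(all(diff(tab$significance_th) <= 0))

  # all-leaf panel
  tab2 <- tissue_topn_table(sc, rep("leaf", 30), top_ns = 7)
  expect_equal(unlist(tab2[1, c("n_leaf", "n_seed")], use.names = FALSE),
               c(7L, 0L))
  expect_error(tissue_topn_table(sc, tissue, top_ns = 31), "exceeds")
})

test_that("association networks filter, weight and hub-restrict correctly", {
  pairs <- tibble::tibble(
    marker_i = c("hub", "hub", "hub", "a", "hub", "b", "c", "hub", "d", "e"),
    marker_j = c(paste0("p", 1:3), "b", "p4", "c", "d", "p5", "e", "f"),
    neglog10p = seq(9, 0.9, length.out = 10))
  net <- build_network(pairs, mode = "top_k", k = 10)
  deg <- network_degrees(net)
  expect_equal(deg$degree[deg$marker_id == "hub"], 5L)
  netf <- build_network(pairs, mode = "top_k", k = 10, focal = "hub")
  expect_equal(nrow(netf$edges), 5L)
  expect_true(all(netf$edges$marker_i == "hub" | netf$edges$marker_j == "hub"))

  nett <- build_network(pairs, mode = "threshold", th = 3.0)
  expect_true(all(nett$edges$weight >= 3.0))
  expect_equal(nrow(nett$edges), sum(pairs$neglog10p >= 3.0))

  empty <- build_network(pairs[0, ], mode = "threshold", th = 1)
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  # edge-list TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(nett, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(nett$edges))
  expect_equal(back$neglog10p, nett$edges$weight, tolerance = 1e-14)
})

test_that("network conversion to igraph preserves weights", {
  skip_if_not_installed("igraph")
  pairs <- tibble::tibble(marker_i = c("a", "b"), marker_j = c("b", "c"),
                          neglog10p = c(4, 5))
  g <- as_igraph(build_network(pairs, mode = "threshold", th = 0))
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$weight, c(4, 5))
})

test_that("a planted hub's conditional slice holds the top pairs", {
  # build a trait driven by interactions of marker 1 with several partners
  n <- 80
  Z <- simulate_ril_genotypes(n = n, m = 12, switch_prob = 0.5, seed = 5)
  W <- Z$values[1, ] * t(Z$values[c(4, 7, 10), , drop = FALSE])
  yv <- rowSums(W) + withr::with_seed(6, rnorm(n, sd = 0.4))
  y <- trait_vector(yv, individual_ids(Z), "y")
  ec <- build_eigen_context(compute_kinships(Z),
                            list(lambda_a = 0, lambda_aa = 0), y)
  res <- scan_2d(Z, ec)
  top3 <- utils::head(threshold_pairs(res, 0), 3)
  expect_true(all(top3$marker_i == "m1" | top3$marker_j == "m1"))
  sl <- conditional_slice(res, "m1")
  expect_setequal(sl$marker_id[order(-sl$neglog10p)][1:3], c("m4", "m7", "m10"))
})
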