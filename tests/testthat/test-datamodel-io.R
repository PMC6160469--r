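test_that("marker CSV parsing handles the documented layout and errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2", "m1,1,-1", "m2,-1,1", "m3,1,1"), p)
  Z <- read_marker_matrix(p)
  expect_equal(n_markers(Z), 3L)
  expect_equal(n_individuals(Z), 2L)
  expect_equal(Z$values["m2", "s1"], -1)

  writeLines(c("id,s1,s2", "m1,1,-1", "m1,0,1"), p)
  expect_error(read_marker_matrix(p), "duplicated marker id")

  writeLines(c("id,s1,s2", "m1,1,x", "m2,0,1"), p)
  expect_error(read_marker_matrix(p), "non-numeric cell 'x'.*'m1'.*'s2'")

  writeLines(c("id,s1,s2", "m1,1,", "m2,0,1"), p)
  expect_error(read_marker_matrix(p), "missing value.*'m1'.*'s2'")
})

test_that("marker matrix round-trips through CSV with metadata", {
  Z <- rand_panel(20, 10, seed = 11)
  Z <- marker_matrix(Z$values,
                     meta = tibble::tibble(marker_id = marker_ids(Z),
                                           chromosome = rep(c("c1", "c2"), 10)))
  p <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_marker_matrix(Z, p, meta_path = mp)
  Z2 <- read_marker_matrix(p, meta_path = mp)
  expect_equal(Z2$values, Z$values, tolerance = 1e-14)
  expect_equal(marker_ids(Z2), marker_ids(Z))
  expect_equal(Z2$meta$chromosome, Z$meta$chromosome)
})

test_that("trait CSV parsing, validation and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("s1,10.2", "s2,9.8"), p)
  y <- read_trait(p)
  expect_equal(length(y$values), 2L)
  expect_equal(unname(y$values), c(10.2, 9.8))
  expect_equal(names(y$values), c("s1", "s2"))

  writeLines(c("individual_id,YIELD", "s1,10.2", "s2,9.8"), p)
  y <- read_trait(p)
  expect_equal(y$trait_name, "YIELD")

  writeLines(c("s1,5", "s2,5", "s3,5"), p)
  expect_error(read_trait(p), "zero variance")

  writeLines(c("s1,5", "s2,abc"), p)
  expect_error(read_trait(p), "non-numeric or missing")

  y0 <- rand_trait(15, seed = 3)
  write_trait(y0, p, header = TRUE)
  y1 <- read_trait(p)
  expect_equal(y1$values, y0$values, tolerance = 1e-15)
  expect_equal(y1$trait_name, "y")
})

test_that("align_samples matches by id, drops extras, and is idempotent", {
  Z <- rand_panel(5, 8, seed = 4)
  ids <- individual_ids(Z)
  y <- withr::with_seed(5, trait_vector(rnorm(8), sample(ids), "y"))
  al <- align_samples(Z, y)
  expect_equal(individual_ids(al$Z), individual_ids(al$y))
  expect_equal(n_individuals(al$Z), 8L)

  # extra trait-side individual is dropped
  y2 <- trait_vector(c(y$values, extra = 1.5), c(names(y$values), "extra"), "y")
  expect_message(al2 <- align_samples(Z, y2), "dropped 0 marker-side and 1")
  expect_equal(length(al2$y$values), 8L)

  # idempotence
  al3 <- align_samples(al$Z, al$y)
  expect_identical(al3$Z$values, al$Z$values)
  expect_identical(al3$y$values, al$y$values)

  expect_error(align_samples(Z, trait_vector(c(1, 2), c("a", "b"), "y")),
               ">= 3 required")
})

test_that("alignment property: columns always match trait entries by id", {
  for (seed in 1:10) {
    Z <- rand_panel(4, 12, seed = seed)
    perm <- withr::with_seed(seed, sample(individual_ids(Z)))
    y <- trait_vector(seq_len(12) + 0.5, perm, "y")
    al <- align_samples(Z, y)
    expect_identical(colnames(al$Z$values), names(al$y$values))
    # values follow their ids through the permutation
    expect_equal(al$Z$values[, perm[1]], Z$values[, perm[1]])
  }
})

test_that("written results read back at full precision", {
  pr <- make_problem(n = 30, m = 8, seed = 21)
  vc <- estimate_variance_components(pr$y, pr$K)
  ec <- build_eigen_context(pr$K, vc, pr$y)
  s1 <- scan_1d(pr$Z, ec)

  d <- withr::local_tempdir()
  f1 <- file.path(d, "scan1d.csv")
  write_results(s1, f1)
  s1b <- read_scan1d(f1)
  expect_equal(s1b$p, s1$p, tolerance = 1e-15)
  expect_equal(s1b$neglog10p, s1$neglog10p, tolerance = 1e-15)
  expect_equal(s1b$marker_id, s1$marker_id)

  stem <- file.path(d, "kin")
  write_results(pr$K, stem)
  Kb <- read_kinship(stem)
  expect_equal(Kb$K_a, pr$K$K_a, tolerance = 1e-14)
  expect_equal(Kb$K_aa, pr$K$K_aa, tolerance = 1e-14)
  expect_equal(Kb$d_aa, pr$K$d_aa, tolerance = 1e-14)

  fv <- file.path(d, "vc.csv")
  write_results(vc, fv)
  v2 <- read_varcomp(fv)
  expect_equal(v2$sigma2_a, vc$sigma2_a, tolerance = 1e-14)
  expect_equal(v2$H, vc$H, tolerance = 1e-14)
  expect_equal(v2$ratio_a + v2$ratio_aa + v2$ratio_e, 1, tolerance = 1e-12)

  # 1D scan CSV has the documented column order
  expect_equal(readLines(f1, n = 1L),
               "marker_id,effect,var_effect,wald,p,neglog10p,status")
})

test_that("container invariants reject bad inputs", {
  expect_error(marker_matrix(matrix(1, 1, 1)), "two individuals")
  expect_error(marker_matrix(matrix(c(1, NA, 2, 3), 2, 2)), "missing value")
  expect_error(trait_vector(c(1, 1, 1), c("a", "b", "c")), "zero variance")
  expect_error(trait_vector(c(1, 2), c("a", "a")), "duplicated")
  expect_error(bin_map(data.frame(marker_id = c("t1", "t1"),
                                  bin_id = c("b1", "b2"))),
               "more than one bin")
})
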