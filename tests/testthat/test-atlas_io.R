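test_that("bundled AAL-116 atlas has 54 pairs, 8 midline regions, valid subsets", {
  a <- aal116_atlas()
  expect_equal(a$n_regions, 116)
  expect_equal(nrow(homotopic_pairs(a)), 54)
  expect_equal(sum(a$hemisphere == "midline"), 8)
  # odd = left, even = right for ids 1..108
  expect_true(all(a$hemisphere[seq(1, 107, 2)] == "left"))
  expect_true(all(a$hemisphere[seq(2, 108, 2)] == "right"))
  ins <- atlas_subset(a, "insula_module_pairs")
  expect_length(ins, 16)
  expect_equal(nrow(homotopic_pairs(a, "insula_module_pairs")), 8)
  # the shipped fixture file matches the in-code constructor
  f <- system.file("extdata", "aal116.tsv", package = "brainmod")
  a2 <- read_atlas(f)
  expect_identical(a2$homotopic_partner, a$homotopic_partner)
  expect_identical(a2$name, a$name)
})

test_that("atlas validation rejects broken pairings and duplicates", {
  expect_error(
    region_atlas(1:3, c("a", "b", "c"), c("left", "right", "right"),
                 c(2, 3, NA)),
    "asymmetric")
  expect_error(
    region_atlas(c(1, 1, 2), c("a", "b", "c"),
                 c("left", "right", "midline"), c(2, 1, NA)),
    "duplicate")
  # pairs must be one left + one right
  expect_error(
    region_atlas(1:2, c("a", "b"), c("left", "left"), c(2, 1)),
    "one left and one right")
  # midline region with a partner
  expect_error(
    region_atlas(1:3, c("a", "b", "c"), c("left", "right", "midline"),
                 c(2, 1, 1)),
    "midline")
  # subset naming a missing region
  expect_error(
    region_atlas(1:2, c("a", "b"), c("left", "right"), c(2, 1),
                 named_subsets = list(s = c(1, 7))),
    "unknown regions")
})

test_that("toy atlas round-trips through TSV", {
  a <- toy_atlas()
  expect_equal(nrow(homotopic_pairs(a)), 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(a, f)
  a2 <- read_atlas(f, named_subsets = a$named_subsets)
  expect_identical(a2$homotopic_partner, a$homotopic_partner)
  expect_identical(a2$hemisphere, a$hemisphere)
  expect_identical(a2$named_subsets, a$named_subsets)
})

test_that("read_timeseries validates shape and reorders shuffled columns", {
  a <- toy_atlas()
  set.seed(1)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, 1:6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- read_timeseries(f, a, subject_id = "s", group = "g")
  expect_equal(dim(ts$data), c(10, 6))

  # shuffled columns: correlations identical to unshuffled input
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  xs <- x[, perm]
  write.table(xs, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  ts2 <- read_timeseries(f2, a, subject_id = "s")
  expect_equal(ts2$data, ts$data, ignore_attr = TRUE)
  expect_equal(subject_connectivity(ts2)$cc, subject_connectivity(ts)$cc)

  # missing a region column
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(x[, 1:5], f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_timeseries(f3, a), "missing region")

  # too few time points
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(x[1:2, ], f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_timeseries(f4, a), "3 time points")
})

test_that("matrix TSV round-trip is lossless and write_results makes a manifest", {
  set.seed(2)
  m <- matrix(rnorm(16), 4, 4, dimnames = list(NULL, 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_identical(read_matrix_tsv(f), m)

  d <- withr::local_tempdir()
  cfg <- analysis_config(seed = 99L)
  p <- module_partition(c(1, 1, 2, 2), Q = 0.5, source = "toy")
  man <- write_results(list(cc = m, partition = p,
                            summary = list(alpha = 0.05)),
                       d, config = cfg)
  expect_setequal(man$files, c("cc.tsv", "partition.tsv", "summary.json"))
  expect_equal(man$seed, 99L)
  expect_true(file.exists(file.path(d, "manifest.json")))
  j <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(j$seed, 99L)
  # partition round-trip
  p2 <- read_partition(file.path(d, "partition.tsv"))
  expect_identical(p2$assignment, p$assignment)
})

test_that("config files parse and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "seed=7", "ne_grid=100:300:100",
               "refine=FALSE", "sd_type=sample"), f)
  cfg <- read_config(f)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$ne_grid, c(100L, 200L, 300L))
  expect_false(cfg$refine)
  expect_equal(cfg$sd_type, "sample")
  writeLines("nonsense=1", f)
  expect_error(read_config(f), "unknown config key")
})
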