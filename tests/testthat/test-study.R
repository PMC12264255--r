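test_that("the default factorial crossing has 24 labelled cells", {
  g <- study_cells()
  expect_equal(nrow(g), 24L)
  expect_setequal(unique(g$n), c(100, 250, 500))
  expect_setequal(unique(g$os), c(0, 0.10, 0.25, 0.40))
  expect_setequal(unique(g$model), c("si", "mi"))
  expect_equal(anyDuplicated(g$cell), 0L)
})

test_that("a cell run is deterministic and summarises both bias tables", {
  cell <- run_cell(n = 100, os = 0.10, model = "mi", n_replications = 50,
                   base_seed = 42)
  cell2 <- run_cell(n = 100, os = 0.10, model = "mi", n_replications = 50,
                    base_seed = 42)
  expect_identical(cell, cell2)
  expect_equal(cell$truth_reliability, 0.8)
  expect_equal(nrow(cell$growth_bias), 6L)
  expect_equal(nrow(cell$reliability_bias), 7L)
  expect_lte(cell$n_converged, cell$n_replications)
  expect_true(all(cell$growth_bias$metric == "relative"))
  expect_true(all(is.finite(cell$growth_bias$mc_se)))
  # SI cells are scored against the Spearman-Brown composite truth
  si <- run_cell(n = 100, os = 0.10, model = "si", n_replications = 50,
                 base_seed = 42)
  expect_equal(si$truth_reliability, spearman_brown(0.8, 2))
  expect_error(run_cell(100, 0.1, "mi", n_replications = 10), "50")
})

test_that("a small study assembles long tables and reruns identically", {
  st <- run_study(n = 100, os_levels = c(0, 0.25), models = c("si", "mi"),
                  n_replications = 50, base_seed = 11)
  expect_s3_class(st, "pgm_study")
  expect_length(st$cells, 4L)
  expect_equal(nrow(st$growth_table), 4L * 6L)
  expect_equal(nrow(st$reliability_table), 4L * 7L)
  st2 <- run_study(n = 100, os_levels = c(0, 0.25), models = c("si", "mi"),
                   n_replications = 50, base_seed = 11)
  expect_identical(st$growth_table, st2$growth_table)

  tmp <- withr::local_tempdir()
  files <- write_results(st, tmp)
  expect_true(all(file.exists(file.path(
    tmp, c("table1_growth_bias.csv", "table2_reliability_bias.csv",
           "study_log.json")))))
  t1 <- utils::read.csv(file.path(tmp, "table1_growth_bias.csv"))
  expect_equal(nrow(t1), 6L)
  expect_equal(ncol(t1), 1L + 4L)
  # display convention: sub-0.001 magnitudes render as "<0.001", while the
  # JSON log keeps raw values
  log <- jsonlite::read_json(file.path(tmp, "study_log.json"),
                             simplifyVector = TRUE)
  raw <- log$growth_bias$bias
  expect_true(any(abs(raw) < 0.001) == any(t1[, -1] == "<0.001"))
  expect_equal(sort(log$convergence$cell), sort(names(st$cells)))
  # byte-identical on rewrite
  before <- readBin(file.path(tmp, "table1_growth_bias.csv"), "raw", 1e6)
  write_results(st, tmp)
  after <- readBin(file.path(tmp, "table1_growth_bias.csv"), "raw", 1e6)
  expect_identical(before, after)
})

test_that("SI and MI cells of one generating cell share datasets", {
  # the replication seed depends on (base_seed, n, os, rep) but not on the
  # analysis model, so both models see the same generated data
  s_mi <- lstpgm:::replication_seed(7, 250, 0.25, c(0, .1, .25, .4),
                                    c(100, 250, 500), 3)
  s_si <- lstpgm:::replication_seed(7, 250, 0.25, c(0, .1, .25, .4),
                                    c(100, 250, 500), 3)
  expect_identical(s_mi, s_si)
  # distinct across reps and cells
  expect_false(s_mi == lstpgm:::replication_seed(7, 250, 0.25,
                                                 c(0, .1, .25, .4),
                                                 c(100, 250, 500), 4))
  expect_false(s_mi == lstpgm:::replication_seed(7, 500, 0.25,
                                                 c(0, .1, .25, .4),
                                                 c(100, 250, 500), 3))
})
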