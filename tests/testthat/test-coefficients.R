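test_that("reliability is the sum of consistency and occasion specificity", {
  set.seed(7)
  for (rep in 1:10) {
    cf <- lst_coefficients(general_mi_model())
    expect_equal(cf$reliability, cf$consistency + cf$occasion_specificity)
    expect_true(all(cf$consistency >= 0 & cf$consistency <= 1))
    expect_true(all(cf$occasion_specificity >= 0 &
                      cf$occasion_specificity <= 1))
    expect_true(all(cf$reliability >= 0 & cf$reliability <= 1))
  }
})

test_that("coefficient numerators match the term-by-term formula oracle", {
  set.seed(13)
  mod <- general_mi_model()
  cf <- lst_coefficients(mod)
  im <- implied_moments(mod)
  for (r in seq_len(nrow(cf))) {
    i <- cf$indicator[r]; j <- cf$occasion[r]
    lam <- mod$measurement$loadings[i, j]
    tv <- oracle_indicator_variance(
      mod$design$time_codes[j], mod$design$knot, lam, mod$growth$cov,
      mod$measurement$state_var[j], mod$measurement$error_var[i, j])
    expect_equal(cf$total_variance[r], tv)
    # two-route check: total variance also equals the implied-moments diagonal
    expect_equal(tv, unname(im$cov[(j - 1) * 2 + i, (j - 1) * 2 + i]))
    expect_equal(cf$consistency[r],
                 oracle_trait_part(mod$design$time_codes[j], mod$design$knot,
                                   lam, mod$growth$cov) / tv)
    expect_equal(cf$occasion_specificity[r],
                 unname(lam^2 * mod$measurement$state_var[j]) / tv)
  }
})

test_that("SI reliability reduces to the trait share", {
  d <- pgm_design()
  # only level variance: at t = 0, rel = 1 / (1 + 0.25) = 0.8
  g <- growth_parameters(c(0, 0, 0), c(1, 0, 0))
  m <- measurement_parameters(1, 7, error_var = rep(0.25, 7))
  cf <- lst_coefficients(pgm_model(d, g, m))
  expect_equal(cf$reliability[1], 0.8)
  expect_equal(cf$occasion_specificity, rep(0, 7))
  expect_equal(cf$reliability, cf$consistency)
  # error-free limit
  m0 <- measurement_parameters(1, 7, error_var = rep(0, 7))
  g2 <- growth_parameters(c(0, 0, 0), c(1, 0.2, 0.2))
  cf0 <- lst_coefficients(pgm_model(d, g2, m0))
  expect_equal(cf0$reliability, rep(1, 7))
})

test_that("the design-cell arithmetic gives con .4, os .4, rel .8", {
  g <- growth_parameters(c(0, 0, 0), c(1, 0, 0))  # trait part 1 everywhere
  m <- measurement_parameters(2, 7, state_var = 1.0, error_var = 0.5)
  cf <- lst_coefficients(pgm_model(pgm_design(), g, m))
  expect_equal(cf$consistency, rep(0.4, 14))
  expect_equal(cf$occasion_specificity, rep(0.4, 14))
  expect_equal(cf$reliability, rep(0.8, 14))
})

test_that("growing state variance raises os and rel, lowers con", {
  g <- growth_parameters(c(10, 2, 1), c(1, 0.25, 0.25))
  d <- pgm_design()
  grid <- c(0, 0.3, 0.8, 1.5)
  cfs <- lapply(grid, function(z) {
    m <- measurement_parameters(2, 7, state_var = z, error_var = 0.4)
    lst_coefficients(pgm_model(d, g, m))
  })
  os <- sapply(cfs, function(cf) cf$occasion_specificity[1])
  rel <- sapply(cfs, function(cf) cf$reliability[1])
  con <- sapply(cfs, function(cf) cf$consistency[1])
  expect_true(all(diff(os) > 0))
  expect_true(all(diff(rel) > 0))
  expect_true(all(diff(con) < 0))
  # zero state variance: trait-only model, rel = con
  expect_equal(cfs[[1]]$reliability, cfs[[1]]$consistency)
})

test_that("tau-parallel indicators share identical coefficients", {
  gd <- generating_design(target_os = 0.25)
  cf <- lst_coefficients(gd)
  for (j in 1:7) {
    sub <- cf[cf$occasion == j, ]
    expect_equal(sub$reliability[1], sub$reliability[2])
    expect_equal(sub$consistency[1], sub$consistency[2])
  }
})

test_that("Spearman-Brown formula and domain checks", {
  expect_equal(spearman_brown(0.8, 2), 2 * 0.8 / 1.8)
  expect_equal(round(spearman_brown(0.8, 2), 3), 0.889)
  expect_equal(spearman_brown(0.37, 1), 0.37)
  expect_equal(spearman_brown(0.5, 3), 0.75)
  expect_error(spearman_brown(0, 2), "between 0 and 1")
  expect_error(spearman_brown(1, 2), "between 0 and 1")
  expect_error(spearman_brown(0.5, 0), "positive integer")
})
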