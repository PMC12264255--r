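test_that("ml discrepancy matches the scalar closed form and saturation", {
  # p = 1, S = 2, Sigma = 1, equal means: F = log(1/2) + 2 - 1
  expect_equal(ml_discrepancy(0, matrix(1), 0, matrix(2)),
               log(1 / 2) + 2 - 1)
  # saturation
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(c(1, 2), S, c(1, 2), S), 0)
  # nonnegative over random moment pairs
  set.seed(42)
  for (rep in 1:20) {
    A <- matrix(rnorm(9), 3); S1 <- crossprod(A) + diag(3)
    B <- matrix(rnorm(9), 3); S2 <- crossprod(B) + diag(3)
    expect_gte(ml_discrepancy(rnorm(3), S1, rnorm(3), S2), 0)
  }
})

test_that("discrepancy equals -2/n times the log-likelihood ratio", {
  gd <- generating_design(target_os = 0.25)
  y <- simulate_pgm(gd, n = 60, seed = 9)
  n <- nrow(y)
  m <- colMeans(y)
  S <- stats::cov(y) * (n - 1) / n
  im <- implied_moments(gd$model)
  F_val <- ml_discrepancy(im$mean, im$cov, m, S)
  ll_model <- oracle_mvn_loglik(y, im$mean, im$cov)
  ll_sat <- oracle_mvn_loglik(y, m, S)
  expect_equal(F_val, -2 / n * (ll_model - ll_sat), tolerance = 1e-8)
})

test_that("fit recovers the generator exactly from exact moments", {
  gd <- generating_design(target_os = 0.25, target_rel = 0.8)
  im <- implied_moments(gd$model)
  y <- exact_moment_data(300, im$mean, im$cov, seed = 4)
  fit <- fit_pgm(y, design = gd$design)
  expect_true(fit$converged)
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(unname(fit$model$growth$means), unname(gd$growth$means),
               tolerance = 1e-4)
  expect_equal(unname(diag(fit$model$growth$cov)),
               unname(diag(gd$growth$cov)), tolerance = 1e-3)
  expect_equal(unname(fit$model$measurement$state_var),
               unname(gd$calibration$state_var), tolerance = 1e-3)
  expect_equal(unname(fit$model$measurement$error_var[1, ]),
               unname(gd$calibration$error_var), tolerance = 1e-3)
  # and the reported log-likelihood matches a direct density-sum oracle
  im_hat <- implied_moments(fit$model)
  expect_equal(fit$loglik, oracle_mvn_loglik(y, im_hat$mean, im_hat$cov),
               tolerance = 1e-6)
})

test_that("large-sample MI estimates are consistent for the truth", {
  gd <- generating_design(target_os = 0.40, target_rel = 0.8)
  # at n = 5e5 the Monte Carlo error of every estimate sits well inside
  # the 2% band, so a single draw is an adequate consistency oracle
  y <- simulate_pgm(gd, n = 500000, seed = 12)
  fit <- fit_pgm(y, design = gd$design)
  expect_true(fit$converged)
  truth <- c(gd$growth$means, diag(gd$growth$cov))
  est <- coef(fit)
  expect_true(all(abs(est - truth) / abs(truth) < 0.02))
  expect_lt(max(abs(fit$model$measurement$state_var -
                      gd$calibration$state_var) /
                  gd$calibration$state_var), 0.03)
})

test_that("SI fit on no-state data recovers the generating error variances", {
  gd <- generating_design(target_os = 0, target_rel = 0.8)
  y <- aggregate_indicators(simulate_pgm(gd, n = 50000, seed = 21))
  fit <- fit_pgm(y, design = gd$design)
  expect_true(fit$converged)
  expect_identical(fit$family, "si")
  # composite error variance is half the per-indicator error variance
  truth_eps <- gd$calibration$error_var / 2
  expect_lt(max(abs(fit$model$measurement$error_var[1, ] - truth_eps) /
                  truth_eps), 0.05)
})

test_that("fits are invariant to row order and indicator relabeling", {
  gd <- generating_design(target_os = 0.25)
  y <- simulate_pgm(gd, n = 400, seed = 31)
  f1 <- fit_pgm(y, design = gd$design)
  # shuffle subjects
  yr <- y[sample(nrow(y)), ]
  f2 <- fit_pgm(yr, design = gd$design)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  # swap the two indicators within every occasion, then restore names
  swap <- as.vector(rbind(seq(2, 14, 2), seq(1, 13, 2)))
  ys <- y[, swap]
  colnames(ys) <- colnames(y)
  f3 <- fit_pgm(ys, design = gd$design)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-6)
})

test_that("growth means are recovered without bias over replications", {
  gd <- generating_design(target_os = 0.10, target_rel = 0.8)
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    y <- simulate_pgm(gd, n = 500, seed = 5000 + r)
    fit <- fit_pgm(y, design = gd$design)
    if (fit$converged) est[r, ] <- fit$model$growth$means
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  expect_gt(nrow(est), 190)
  bias <- (colMeans(est) - gd$growth$means) / gd$growth$means
  expect_true(all(abs(bias) < 0.05))
})

test_that("free growth covariances reproduce zero-constrained estimates
           when the truth has zero covariances", {
  gd <- generating_design(target_os = 0.25)
  im <- implied_moments(gd$model)
  y <- exact_moment_data(300, im$mean, im$cov, seed = 8)
  f_fix <- fit_pgm(y, design = gd$design, free_growth_cov = FALSE)
  f_free <- fit_pgm(y, design = gd$design, free_growth_cov = TRUE)
  expect_true(f_free$converged)
  expect_lt(max(abs(f_free$model$growth$cov[upper.tri(diag(3))])), 1e-3)
  expect_equal(coef(f_fix)[1:6], coef(f_free)[1:6], tolerance = 1e-3)
})

test_that("degenerate inputs fail gracefully", {
  gd <- generating_design()
  y <- simulate_pgm(gd, n = 10, seed = 1)
  expect_error(fit_pgm(y, design = gd$design), "free parameters")
  y2 <- simulate_pgm(gd, n = 100, seed = 1)
  expect_error(fit_pgm(y2, design = gd$design, family = "si"), "aggregate")
  y3 <- y2; y3[1, 1] <- NA
  expect_error(fit_pgm(y3, design = gd$design), "complete")
})
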