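test_that("AR(1) covariance is exact and graph covariances are valid", {
  nc <- network_covariance("ar1", p = 3, rho = 0.5)
  expect_equal(nc$covariance,
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3))
  expect_equal(nrow(nc$edges), 2)

  band <- network_covariance("band", p = 10, bandwidth = 1)
  expect_equal(nrow(band$edges), 9)

  hub <- network_covariance("hub", p = 100, group_size = 20)
  expect_equal(nrow(hub$edges), 95)  # 5 groups x 19 spokes

  for (s in c("band", "hub", "cluster", "scale_free")) {
    nc <- network_covariance(s, p = 40, seed = 4)
    expect_equal(diag(nc$covariance), rep(1, 40))
    expect_silent(chol(nc$covariance))
    # precision sparsity pattern = adjacency + diagonal
    omega <- solve(nc$covariance)
    A <- matrix(0, 40, 40)
    A[nc$edges] <- 1
    A <- A + t(A)
    off_pattern <- abs(omega[A == 0 & row(omega) != col(omega)])
    expect_lt(max(off_pattern), 1e-8)
  }
  # scale-free preferential attachment with m = 1 yields a tree
  sf <- network_covariance("scale_free", p = 30, attach_m = 1, seed = 5)
  expect_equal(nrow(sf$edges), 29)
})

test_that("drawn covariates reproduce the target correlations", {
  nc <- network_covariance("ar1", p = 3, rho = 0.5)
  x <- draw_covariates(50000, nc, seed = 6)
  expect_equal(cor(x[, 1], x[, 2]), 0.5, tolerance = 0.02 / 0.5)
  expect_equal(cor(x[, 1], x[, 3]), 0.25, tolerance = 0.02 / 0.25)
  expect_true(all(abs(apply(x, 2, var) - 1) < 0.03))
})

test_that("contamination replaces entries at the nominal rate", {
  set.seed(7)
  x <- matrix(rnorm(200 * 500), 200, 500)
  none <- contaminate(x, prob = 0)
  expect_identical(none$x, x)
  expect_false(any(none$mask))

  all_in <- contaminate(x, prob = 1, df = 2, seed = 8)
  expect_true(all(all_in$mask))
  kurt <- mean((all_in$x - mean(all_in$x))^4) / var(as.vector(all_in$x))^2
  expect_gt(kurt, 9)  # t(2) tails far exceed the Gaussian value 3

  some <- contaminate(x, prob = 0.1, seed = 9)
  p_hat <- mean(some$mask)
  tol4 <- 4 * sqrt(0.1 * 0.9 / length(x))
  expect_lt(abs(p_hat - 0.1), tol4)
  expect_identical(some$x[!some$mask], x[!some$mask])

  subj <- contaminate(x, prob = 0.2, unit = "subject", seed = 10)
  row_any <- rowSums(subj$mask) > 0
  expect_true(all(rowSums(subj$mask)[row_any] == ncol(x)))
})

test_that("baseline survival matches the closed-form transformation law", {
  # eta = 0: S(t) = exp(-0.5(e^{2t}-1)) (PH), (1 + 0.5(e^{2t}-1))^-1 (PO)
  n <- 100000
  t_ph <- draw_survival(rep(0, n), "ph", seed = 11)
  expect_equal(median(t_ph), 0.5 * log(1 + 2 * log(2)), tolerance = 0.005 / 0.43)
  t_po <- draw_survival(rep(0, n), "po", seed = 12)
  expect_equal(median(t_po), 0.5 * log(3), tolerance = 0.005 / 0.55)

  dec <- quantile(t_ph, probs = seq(0.1, 0.9, 0.1))
  s_theory <- exp(-0.5 * expm1(2 * dec))
  expect_true(all(abs(s_theory - seq(0.9, 0.1, -0.1)) < 3 / sqrt(n)))
  dec_po <- quantile(t_po, probs = seq(0.1, 0.9, 0.1))
  s_po <- 1 / (1 + 0.5 * expm1(2 * dec_po))
  expect_true(all(abs(s_po - seq(0.9, 0.1, -0.1)) < 3 / sqrt(n)))

  # shifting eta by +c shifts the H(T) distribution by -c
  t0 <- draw_survival(rep(0, n), "ph", seed = 13)
  t1 <- draw_survival(rep(1, n), "ph", seed = 13)
  expect_equal(median(tm_transform(t0)) - median(tm_transform(t1)), 1,
               tolerance = 0.03)
})

test_that("censoring calibration reproduces target rates", {
  sc <- sim_scenario("sim1", n = 400, p = 200)
  for (target in c(0.3, 0.5)) {
    sc$censoring <- censoring_spec(target_rate = target)
    sc_r <- resolve_censoring(sc, mc_draws = 50000, seed = 14)
    oo <- draw_outcomes(sc_r, n = 50000, seed = 15)
    expect_equal(mean(oo$status == 0), target, tolerance = 0.015 / target)
  }
  expect_error(censoring_spec(target_rate = 0), "strictly|proportion")
  expect_error(
    calibrate_censoring(0, function(m) rexp(m)), "proportion")
})

test_that("simulated cohorts satisfy the observed-data identities", {
  sc <- sim_scenario("sim1", n = 150, p = 60, censoring = 0.3,
                     contamination = 0.1)
  coh <- simulate_cohort(sc, seed = 16, calibration_draws = 20000)
  expect_equal(dim(coh$x), c(150, 60))
  expect_length(coh$truth, 14)
  expect_equal(coh$time, pmin(coh$t_true, coh$c_true))
  expect_equal(coh$status, as.integer(coh$t_true <= coh$c_true))
  expect_true(all(coh$time > 0))

  coh2 <- simulate_cohort(sc, seed = 16, calibration_draws = 20000)
  expect_identical(coh$x, coh2$x)
  expect_identical(coh$time, coh2$time)

  no_cens <- sim_scenario("sim1", n = 80, p = 30, censoring = NULL)
  coh3 <- simulate_cohort(no_cens, seed = 17)
  expect_true(all(coh3$status == 1))

  # contamination is measurement corruption: eta comes from the clean
  # covariates by default, from the contaminated ones only behind the flag.
  # Under one seed the two modes share X, mask and error draws, so the
  # implied errors eps = H(T) + eta must agree across modes.
  sc_a <- sim_scenario("sim1", n = 100, p = 30, censoring = NULL,
                       contamination = 0.5)
  sc_b <- sc_a
  sc_b$contaminate_before_eta <- TRUE
  ca <- simulate_cohort(sc_a, seed = 18, keep_clean = TRUE)
  cb <- simulate_cohort(sc_b, seed = 18, keep_clean = TRUE)
  expect_identical(ca$x, cb$x)
  eff <- sc_a$effects
  eps_a <- tm_transform(ca$t_true) + linear_predictor(ca$x_clean, eff)
  eps_b <- tm_transform(cb$t_true) + linear_predictor(cb$x, eff)
  expect_equal(eps_a, eps_b, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(ca$t_true, cb$t_true)))
})
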