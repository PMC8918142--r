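test_that("minimum model size is the largest rank of any true feature", {
  expect_equal(mms(c(3L, 2L, 1L), truth = 2), 2)
  rk <- survscreen:::new_feature_ranking(c(9, 8, 7, 1, 2), "test")
  expect_equal(mms(rk, truth = c(1, 2, 3)), 3)
  expect_equal(mms(rk, truth = 4), 5)  # worst case: last rank
  expect_error(mms(rk, truth = 99), "not in the ranking")
  set.seed(50)
  ord <- sample(100)
  truth <- sample(100, 10)
  expect_gte(mms(ord, truth), 10)
  expect_equal(mms(ord, ord[1:10]), 10)
})

test_that("overlap and Jaccard follow their set formulas", {
  expect_equal(overlap_coefficient(1:5, 1:5), 1)
  expect_equal(overlap_coefficient(c(1, 2), c(2, 3)), 0.5)
  expect_equal(overlap_coefficient(1:3, 7:9), 0)
  expect_error(overlap_coefficient(integer(0), 1:3), "non-empty")
  expect_equal(jaccard_index(1:4, 1:4), 1)
  expect_equal(jaccard_index(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccard_index(1:3, 7:9), 0)
  expect_error(jaccard_index(integer(0), integer(0)), "non-empty")
})

test_that("method-similarity matrix is a symmetric unit-diagonal Jaccard table", {
  r1 <- survscreen:::new_feature_ranking(10:1, "a")
  r2 <- survscreen:::new_feature_ranking(10:1, "b")
  r3 <- survscreen:::new_feature_ranking(1:10, "c")
  m <- method_similarity(list(a = r1, b = r2, c = r3), model_size = 5)
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], 0)  # disjoint top halves of reversed rankings
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_warning(method_similarity(list(a = r1, b = r2), model_size = 50),
                 "clipped")
})

test_that("Harrell concordance matches brute-force pair counting", {
  expect_equal(harrell_c(-(1:8), 1:8, rep(1, 8)), 1)
  expect_equal(harrell_c(rep(1, 20), rexp(20), rep(1, 20)), 0.5)
  set.seed(51)
  expect_equal(harrell_c(rnorm(5000), rexp(5000), rbinom(5000, 1, 0.7)), 0.5,
               tolerance = 0.02 / 0.5)
  for (r in 1:20) {
    d <- random_surv_data(30, cens_rate = 0.3)
    sc <- rnorm(30)
    expect_equal(harrell_c(sc, d$time, d$status),
                 oracle_concordance(sc, d$time, d$status), tolerance = 1e-12)
  }
  # tie-free complement identity
  d <- random_surv_data(40, cens_rate = 0.2)
  sc <- rnorm(40)
  expect_equal(harrell_c(sc, d$time, d$status) +
                 harrell_c(-sc, d$time, d$status), 1, tolerance = 1e-12)
})

test_that("fixed-beta Cox partial likelihood matches closed forms and coxph", {
  expect_equal(cox_pll(0, matrix(c(1, 0)), c(1, 2), c(1, 1)), -log(2),
               tolerance = 1e-12)
  set.seed(52)
  for (r in 1:50) {
    d <- random_surv_data(10, cens_rate = 0.3,
                          tie_grid = if (r %% 2) NULL else 1:4)
    expect_equal(cox_pll(0, d$x, d$time, d$status),
                 oracle_pll0(d$time, d$status), tolerance = 1e-10)
  }
  # at the fitted optimum, matches survival::coxph's reported loglik
  d <- random_surv_data(100, p = 2, cens_rate = 0.3)
  fit <- survival::coxph(survival::Surv(d$time, d$status) ~ d$x,
                         ties = "breslow")
  expect_equal(cox_pll(coef(fit), d$x, d$time, d$status), fit$loglik[2],
               tolerance = 1e-6)
  expect_error(cox_pll(1e400, matrix(1:3), 1:3, c(1, 1, 1)), "finite")
})

test_that("test-set deviance is anchored at the null model", {
  set.seed(53)
  d <- random_surv_data(50, p = 3, cens_rate = 0.3)
  expect_equal(cox_deviance(rep(0, 3), d$x, d$time, d$status), 0)
  # feature reordering applied consistently changes nothing
  beta <- c(0.5, -1, 0.2)
  perm <- c(3, 1, 2)
  expect_equal(cox_deviance(beta, d$x, d$time, d$status),
               cox_deviance(beta[perm], d$x[, perm], d$time, d$status),
               tolerance = 1e-12)
  # a strongly informative feature fitted on training data improves on the
  # null for a large independent test set
  n <- 600
  x_all <- matrix(rnorm(2 * n), 2 * n, 1)
  t_all <- draw_survival(drop(x_all * 1.5), "ph", seed = 54)
  tr <- 1:n
  te <- (n + 1):(2 * n)
  fit <- survival::coxph(survival::Surv(t_all[tr], rep(1, n)) ~ x_all[tr, ],
                         ties = "breslow")
  expect_lt(cox_deviance(coef(fit), x_all[te, , drop = FALSE],
                         t_all[te], rep(1, n)), 0)
})

test_that("benchmark bookkeeping: sizes, curves, determinism", {
  sc <- sim_scenario("sim1", n = 120, p = 50, censoring = 0.3,
                     contamination = 0.1)
  sc <- resolve_censoring(sc, mc_draws = 20000, seed = 55)
  bm <- run_benchmark(sc, methods = c("sis", "fast"), replications = 2,
                      size_grid = c(14, 20, 30, 50), seed = 56,
                      cindex = TRUE, similarity_size = 20)
  expect_equal(dim(bm$mms), c(2, 2))
  expect_true(all(bm$mms >= 14))
  # nested top-k sets: overlap curves are non-decreasing past |truth|
  expect_true(all(apply(bm$overlap, 2, function(v) all(diff(v) >= -1e-12))))
  expect_equal(unname(bm$overlap[4, ]), c(1, 1))  # top-p covers the truth
  expect_true(all(bm$cindex >= 0 & bm$cindex <= 1))
  expect_equal(dim(bm$similarity), c(2, 2))
  bm2 <- run_benchmark(sc, methods = c("sis", "fast"), replications = 2,
                       size_grid = c(14, 20, 30, 50), seed = 56,
                       cindex = TRUE, similarity_size = 20)
  expect_identical(bm$mms, bm2$mms)
  expect_identical(bm$overlap, bm2$overlap)
})
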