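test_that("latent correlation matrices are unit-diagonal and PSD", {
  for (p in c(1, 5, 40)) {
    s <- make_correlation(p, seed = p)
    expect_equal(diag(s), rep(1, p))
    expect_equal(s, t(s))
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  expect_identical(make_correlation(6, seed = 3), make_correlation(6, seed = 3))
  expect_equal(make_correlation(1, seed = 1), matrix(1, 1, 1))
})

test_that("probit binary design reproduces its marginal frequencies", {
  s <- make_correlation(5, seed = 2)
  bd <- sample_binary_design(2e5, s, c(0.2, 0.8), seed = 7)
  expect_true(all(bd$pi >= 0.2 & bd$pi <= 0.8))
  expect_lt(max(abs(colMeans(bd$x) - bd$pi)), 0.01)

  # degenerate pi range + identity correlation: independent fair coins
  bd2 <- sample_binary_design(2e5, diag(5), c(0.5, 0.5), seed = 8)
  expect_lt(max(abs(colMeans(bd2$x) - 0.5)), 0.01)
  cc <- cor(bd2$x)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.01)
})

test_that("coefficient law gives the advertised hazard-ratio range and sparsity", {
  b <- sample_coefficients(1e5, seed = 5)
  expect_true(all(exp(b) >= exp(-0.25) & exp(b) <= exp(0.25)))
  expect_lt(abs(mean(b != 0) - 0.5), 0.005)
  expect_identical(sample_coefficients(50, coef_nonzero_prob = 0, seed = 1),
                   rep(0, 50))
})

test_that("Weibull survival sampler hits analytic quantiles and centers", {
  # beta = 0, a = 1, alpha = log log 2: median survival is exactly 1
  sv <- sample_survival(matrix(0, 1e6, 1), 0, 1, log(log(2)), seed = 4)
  expect_lt(abs(median(sv$t) - 1), 0.005)
  # a = 1 reduces to an exponential with mean 1/m
  expect_lt(abs(mean(sv$t) - 1 / log(2)) / (1 / log(2)), 0.01)

  # centering forces mean log m = alpha regardless of beta
  x <- matrix(rnorm(500 * 3), 500)
  sv2 <- sample_survival(x, c(1, -2, 0.5), 1.4, -0.2, seed = 9)
  expect_lt(abs(mean(sv2$log_m) - (-0.2)), 1e-12)
})

test_that("censoring sampler is calibrated and independent of predictors", {
  u <- sample_censoring(1e6, 1, log(2) / 2, seed = 11)
  expect_lt(abs(median(u) - 2) / 2, 0.005)
  expect_identical(u, sample_censoring(1e6, 1, log(2) / 2, seed = 11))
  x <- matrix(rnorm(1e5), 1e5, 1)
  u2 <- sample_censoring(1e5, 1, log(2) / 2, seed = 12)
  expect_lt(abs(cor(u2, x[, 1])), 0.01)
})

test_that("two-part entry model matches its defining moments", {
  # analytic identity behind the default sigma: exp(mu + sigma^2/2) = 1.6
  expect_equal(exp(0 + (sqrt(2 * log(1.6)))^2 / 2), 1.6, tolerance = 1e-12)

  v <- sample_entry(1e6, seed = 21)
  expect_lt(abs(mean(v > 0) - 0.2), 0.005)
  pos <- v[v > 0]
  expect_lt(abs(median(pos) - 1), 0.01)
  expect_lt(abs(mean(pos) - 1.6) / 1.6, 0.01)
  expect_identical(sample_entry(100, entry_positive_prob = 0, seed = 1),
                   rep(0, 100))
})

test_that("cohort assembly applies the truncation and censoring definitions", {
  x1 <- matrix(0, 3, 1)
  co <- assemble_cohort(c(2, 2, 5), c(3, 3, 4), c(1, 2.5, 0), x1, 0)
  expect_equal(co$observed_Y, c(2, 2, 4))
  expect_equal(co$event, c(1L, 1L, 0L))
  expect_equal(co$truncated, c(0L, 1L, 0L))

  # truncated subjects have systematically shorter observed times
  cohort <- simulate_cohort(sim_config(n = 4000, p_binary = 5, seed = 31))
  expect_gt(sum(cohort$truncated), 50)
  expect_lt(mean(cohort$observed_Y[cohort$truncated == 1]),
            mean(cohort$observed_Y[cohort$truncated == 0]))

  expect_identical(simulate_cohort(sim_config(n = 200, p_binary = 3, seed = 6)),
                   simulate_cohort(sim_config(n = 200, p_binary = 3, seed = 6)))
})

test_that("LTRC Weibull likelihood recovers generating parameters", {
  a_true <- 1; alpha_true <- log(log(2))
  cfg <- sim_config(n = 20000, p_binary = 1, seed = 52,
                    standin_covariates = FALSE, coef_nonzero_prob = 0,
                    entry_positive_prob = 0.3)  # ~20% truncation
  cohort <- simulate_cohort(cfg)
  expect_gt(mean(cohort$truncated), 0.15)
  d <- observed_data(cohort)
  wf <- fit_weibull_ltrc(d)
  expect_true(wf$converged)
  expect_lt(abs(wf$shape - a_true), 0.03)
  expect_lt(abs(wf$log_scale - alpha_true), 0.03)

  # reversed indicator recovers the censoring distribution
  wr <- fit_weibull_ltrc(d, reverse_indicator = TRUE)
  expect_lt(abs(wr$shape - cfg$cens_shape), 0.03)
  expect_lt(abs(wr$log_scale - log(cfg$cens_scale)), 0.04)

  # without truncation the fit matches the survreg oracle
  d0 <- ltrc_data(rep(0, 5000), cohort$observed_Y[1:5000],
                  cohort$event[1:5000])
  w0 <- fit_weibull_ltrc(d0)
  sr <- survival::survreg(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(d0), dist = "weibull")
  expect_lt(abs(w0$shape - 1 / sr$scale), 1e-5)
  expect_lt(abs(w0$log_scale - (-coef(sr) / sr$scale)), 1e-5)

  expect_error(fit_weibull_ltrc(ltrc_data(0, 1, 0)), "at least 2 events")
})

test_that("entry-correlated predictors bias unadjusted hazard ratios downward", {
  set.seed(61)
  n <- 5000
  v <- sample_entry(n, seed = 62)
  # predictor positively associated with entry time, null true effect
  x2 <- drop(scale(rank(v) + rnorm(n, sd = n / 10)))
  x1 <- rnorm(n)
  x <- cbind(x1 = x1, x2 = x2)
  tt <- (-log(runif(n)) / exp(log(log(2)) + 0.4 * x1))^(1)
  u <- sample_censoring(n, seed = 63)
  cohort <- assemble_cohort(tt, u, v, x, c(0.4, 0))
  d <- observed_data(cohort)
  f_adj <- ltrcnet(d, lambda = c(1, 0), adjust = TRUE)
  f_un <- ltrcnet(d, lambda = c(1, 0), adjust = FALSE)
  expect_lt(coef(f_un, 0)["x2", ], coef(f_adj, 0)["x2", ])
  # the adjusted estimate of the null effect stays near zero
  expect_lt(abs(coef(f_adj, 0)["x2", ]), 0.1)
})

test_that("scenario designs have the advertised dimensions", {
  co_small <- simulate_cohort(sim_config(n = 100, p_binary = 10, seed = 3))
  expect_equal(ncol(co_small$x), 21L)
  expect_equal(length(co_small$true_beta), 21L)
  # the replicate engine smoke test: small cohort, both models, 4 cells
  rr <- run_replicate(sim_config(n = 400, p_binary = 10, seed = 8),
                      scenario = "small_p", nfolds = 4)
  expect_equal(nrow(rr$cindex), 4L)
  expect_setequal(rr$cindex$sample, c("observed", "complete"))
  expect_true(all(rr$cindex$cindex > 0 & rr$cindex$cindex < 1))
  rr2 <- run_replicate(sim_config(n = 400, p_binary = 10, seed = 8),
                       scenario = "small_p", nfolds = 4)
  expect_identical(rr$cindex, rr2$cindex)
})
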