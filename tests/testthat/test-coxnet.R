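## Hand-checkable dataset used throughout: y = (2, 4, 6), v = (0, 3, 1),
## all events. Subject 2 enters only at time 3, so it is absent from the
## risk set at t = 2.
hand_data <- function(p = 1) {
  ltrc_data(entry = c(0, 3, 1), time = c(2, 4, 6), event = c(1, 1, 1),
            x = matrix(0, 3, p))
}

test_that("entry-adjusted risk sets match the set definitions", {
  d <- hand_data()
  rs <- risk_sets(d, adjust = TRUE)
  expect_equal(risk_set_members(rs, 1), c(1L, 3L))  # v2 = 3 >= t = 2
  expect_equal(risk_set_members(rs, 2), c(2L, 3L))
  expect_equal(risk_set_members(rs, 3), 3L)
  expect_equal(rs$size, c(2L, 2L, 1L))

  rs0 <- risk_sets(d, adjust = FALSE)
  expect_equal(risk_set_members(rs0, 1), 1:3)

  # subject entering exactly at an event time is excluded (strict t > v)
  db <- ltrc_data(entry = c(0, 2), time = c(2, 5), event = c(1, 1))
  expect_equal(risk_set_members(risk_sets(db), 1), 1L)
  expect_equal(risk_set_members(risk_sets(db, adjust = FALSE), 1), 1:2)

  # adjusted sets are always subsets of the unadjusted ones
  for (s in 1:20) {
    dr <- rand_ltrc(s)
    rsa <- risk_sets(dr, TRUE); rsu <- risk_sets(dr, FALSE)
    for (k in seq_along(rsa$times))
      expect_true(all(risk_set_members(rsa, k) %in% risk_set_members(rsu, k)))
  }
})

test_that("partial log-likelihood matches hand values and enumeration", {
  d <- hand_data()
  expect_equal(partial_loglik(d, 0), -(log(2) + log(2) + log(1)),
               tolerance = 1e-12)

  # with all entries zero the LTRC value reduces to the standard Cox one
  for (s in 1:25) {
    dr <- rand_ltrc(s, p = 2)
    d0 <- ltrc_data(rep(0, nobs(dr)), dr$time, dr$event, dr$x)
    beta <- round(rnorm(2, sd = 0.5), 2)
    expect_equal(partial_loglik(d0, beta, adjust = TRUE),
                 partial_loglik(d0, beta, adjust = FALSE), tolerance = 1e-12)
    # and agrees with explicit risk-set enumeration, both adjust flags
    for (adj in c(TRUE, FALSE))
      expect_equal(partial_loglik(dr, beta, adjust = adj),
                   bf_partial_loglik(dr$entry, dr$time, dr$event, dr$x,
                                     beta, adjust = adj),
                   tolerance = 1e-10)
  }
  expect_error(partial_loglik(d, c(0, 0)), "length 1")
  expect_error(partial_loglik(d, NaN), "finite")
  dnoev <- ltrc_data(0, 1, 0)
  expect_error(partial_loglik(dnoev, numeric(0)), "no events")
})

test_that("penalized objective combines loglik and elastic-net penalty", {
  set.seed(3)
  d <- rand_ltrc(7, p = 2)
  n <- nobs(d)
  expect_equal(penalized_objective(d, c(0, 0), lambda = 0.3),
               (2 / n) * partial_loglik(d, c(0, 0)))
  b <- c(0.5, -0.5)
  expect_equal(penalized_objective(d, b, lambda = 0),
               (2 / n) * partial_loglik(d, b))
  expect_equal(penalized_objective(d, b, lambda = 0.1, alpha = 1) -
                 (2 / n) * partial_loglik(d, b), -0.1 * 1)
  expect_error(penalized_objective(d, b, lambda = -1), "nonnegative")
})

test_that("lambda_max is the exact all-zero boundary and paths are log-spaced", {
  set.seed(21)
  n <- 150
  x <- matrix(rnorm(n * 4), n)
  tt <- rexp(n, exp(0.6 * x[, 1] - 0.4 * x[, 3]))
  u <- rexp(n, 0.3)
  v <- ifelse(rbinom(n, 1, 0.3) == 1, rlnorm(n, -1, 0.7), 0)
  keep <- v < pmin(tt, u)
  d <- ltrc_data(v[keep], pmin(tt, u)[keep], as.integer(tt <= u)[keep],
                 x[keep, ])
  lmax <- lambda_max(d)
  fit <- ltrcnet(d, lambda = c(1.0001 * lmax, lmax, 0.99 * lmax))
  expect_equal(fit$df[1:2], c(0L, 0L))
  expect_identical(unname(fit$beta[, 2]), rep(0, 4))
  expect_gte(fit$df[3], 1L)

  pth <- lambda_path(d, nlambda = 100, lambda_min_ratio = 0.01)
  expect_length(pth, 100)
  expect_equal(pth[1] / pth[100], 100, tolerance = 1e-10)
  expect_true(all(diff(pth) < 0))
})

test_that("the unpenalized fit matches a Newton-Raphson LTRC Cox oracle", {
  set.seed(9)
  n <- 200
  x <- matrix(rnorm(n * 3), n)
  tt <- rexp(n, exp(0.5 * x[, 1] - 0.3 * x[, 2]))
  u <- rexp(n, 0.3)
  v <- ifelse(rbinom(n, 1, 0.3) == 1, rlnorm(n, -1, 0.8), 0)
  y <- pmin(tt, u); e <- as.integer(tt <= u); keep <- v < y
  d <- ltrc_data(v[keep], y[keep], e[keep], x[keep, ])
  fit <- ltrcnet(d, lambda = c(0.05, 0))
  oracle <- survival::coxph(survival::Surv(entry, time, event) ~ .,
                            data = as.data.frame(d), ties = "breslow")
  expect_lt(max(abs(drop(coef(fit, 0)) - coef(oracle))), 1e-4)
})

test_that("truncation-free fits reduce to the standard elastic-net Cox", {
  set.seed(13)
  n <- 120
  x <- matrix(rnorm(n * 5), n)
  tt <- rexp(n, exp(0.4 * x[, 1] - 0.4 * x[, 2]))
  u <- rexp(n, 0.4)
  d0 <- ltrc_data(rep(0, n), pmin(tt, u), as.integer(tt <= u), x)
  f_adj <- ltrcnet(d0, nlambda = 25, adjust = TRUE)
  f_un <- ltrcnet(d0, lambda = f_adj$lambda, adjust = FALSE)
  expect_lt(max(abs(f_adj$beta - f_un$beta)), 1e-10)
})

test_that("KKT optimality holds at convergence on the standardized scale", {
  set.seed(31)
  d <- simulate_cohort(sim_config(n = 400, p_binary = 8, seed = 31,
                                  standin_covariates = FALSE))
  d <- observed_data(d)
  for (alpha in c(1, 0.5)) {
    fit <- ltrcnet(d, alpha = alpha, nlambda = 20)
    std <- ltrcnet:::standardize_x(d$x)
    enc <- ltrcnet:::risk_encoding(d, TRUE)
    for (l in c(5L, 12L, length(fit$lambda))) {
      beta_std <- fit$beta[, l] * std$scale
      eta <- drop(std$x %*% beta_std)
      u <- ltrcnet:::cox_irls_quants(eta, d$event, enc$cy, enc$cv, enc$d)$u
      g <- drop(crossprod(std$x, u)) * (2 / nobs(d))
      lam <- fit$lambda[l]
      nz <- beta_std != 0
      if (any(nz))
        expect_lt(max(abs(g[nz] - lam * (1 - alpha) * beta_std[nz]) -
                        lam * alpha), 1e-4)
      if (any(!nz))
        expect_lt(max(abs(g[!nz])), lam * alpha + 1e-4)
    }
  }
})

test_that("warm starts never decrease the penalized objective", {
  set.seed(17)
  d <- observed_data(simulate_cohort(sim_config(n = 300, p_binary = 5,
                                                seed = 17)))
  fit <- ltrcnet(d, nlambda = 30)
  # the solver ascends the objective with the penalty on the internally
  # standardized coefficient scale; evaluate exactly that quantity
  obj <- function(beta, lam) {
    (2 / nobs(d)) * partial_loglik(d, beta) - lam * sum(abs(beta * fit$scale))
  }
  for (l in 2:length(fit$lambda)) {
    expect_gte(obj(fit$beta[, l], fit$lambda[l]),
               obj(fit$beta[, l - 1], fit$lambda[l]) - 1e-8)
  }
})

test_that("parameter recovery: the adjusted fit is consistent for true beta", {
  # per-coefficient sampling error at n = 2000 is ~0.065, so the fit is
  # checked on the per-replicate mean absolute error and on the absence of
  # systematic bias across replicates, the signature left truncation would
  # otherwise leave
  errs <- sapply(1:3, function(s) {
    cfg <- sim_config(n = 2000, p_binary = 5, seed = s,
                      standin_covariates = FALSE,
                      entry_positive_prob = 0.45)  # ~30% truncated
    cohort <- simulate_cohort(cfg)
    if (s == 1) expect_gt(mean(cohort$truncated), 0.2)
    d <- observed_data(cohort)
    fit <- ltrcnet(d, lambda = c(lambda_max(d), 0))
    drop(coef(fit, 0)) - cohort$true_beta
  })
  expect_true(all(colMeans(abs(errs)) < 0.1))
  expect_lt(max(abs(rowMeans(errs))), 0.1)
})

test_that("cross-validation is seeded, coherent, and null under pure noise", {
  set.seed(5)
  d <- observed_data(simulate_cohort(sim_config(n = 500, p_binary = 6,
                                                seed = 5)))
  cv1 <- cv_ltrcnet(d, nfolds = 5, seed = 42, nlambda = 30)
  cv2 <- cv_ltrcnet(d, nfolds = 5, seed = 42, nlambda = 30)
  expect_identical(cv1$foldid, cv2$foldid)
  expect_identical(cv1$lambda.min, cv2$lambda.min)
  # argmin definition and the one-standard-error rule
  expect_equal(cv1$cvm[cv1$index.min], min(cv1$cvm))
  expect_gte(cv1$lambda.1se, cv1$lambda.min)

  # pure noise: the null model (lambda near lambda_max) wins most runs
  null_wins <- 0L
  for (s in 1:20) {
    set.seed(s + 300)
    n <- 500
    x <- matrix(rnorm(n * 10), n)
    tt <- rexp(n, 1); u <- rexp(n, 0.35)
    dn <- ltrc_data(rep(0, n), pmin(tt, u), as.integer(tt <= u), x)
    cvn <- cv_ltrcnet(dn, nfolds = 5, seed = s, nlambda = 30)
    if (cvn$nzero[cvn$index.min] == 0L) null_wins <- null_wins + 1L
  }
  expect_gt(null_wins, 10L)
})

test_that("cross-validation refuses folds that empty the event set", {
  d <- ltrc_data(entry = rep(0, 6), time = 1:6,
                 event = c(1, 0, 0, 0, 0, 0), x = matrix(rnorm(6), 6))
  # some fold must contain the single event row, leaving none for training
  expect_error(cv_ltrcnet(d, nfolds = 6, seed = 1), "fewer folds")
})

test_that("model JSON serialization round-trips coefficients and metadata", {
  d <- observed_data(simulate_cohort(sim_config(n = 250, p_binary = 4,
                                                seed = 2)))
  cv <- cv_ltrcnet(d, nfolds = 4, seed = 9, nlambda = 15)
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(cv, f)
  back <- model_from_json(f)
  expect_equal(back$lambda.min, cv$lambda.min)
  expect_equal(coef(back), coef(cv), tolerance = 1e-12)
  expect_equal(drop(predict(back, d$x[1:5, ])),
               drop(predict(cv, d$x[1:5, ])), tolerance = 1e-12)
})
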