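test_that("a single visit at day zero has zero predictive probability", {
  p <- predict_visit(patient_record("one", 0, -3, 0L))
  expect_identical(p$p_hcc, 0)
  expect_error(predict_visit(patient_record("d", c(0, 10), c(-3, -2), c(0L, 1L))),
               "positive diagnosis")
})

test_that("predictions are deterministic given the seed and never look ahead", {
  times <- seq(0, 1200, by = 150)
  set.seed(30)
  sc <- rnorm(length(times), -3.2, 0.46)
  rec <- patient_record("p", times, sc, rep(0L, length(times)))
  cfg <- predict_config(seed = 11, n_iter = 1200, n_burnin = 300)
  p1 <- predict_visit(rec, config = cfg)
  p2 <- predict_visit(rec, config = cfg)
  expect_identical(p1$p_hcc, p2$p_hcc)
  # cohort-level: editing visits after j never changes the prediction at j
  coh <- galad_cohort(list(rec))
  preds <- predict_cohort(coh, config = cfg, window_days = Inf)
  sc2 <- sc; sc2[7:9] <- sc2[7:9] + 5
  rec2 <- patient_record("p", times, sc2, rep(0L, length(times)))
  preds2 <- predict_cohort(galad_cohort(list(rec2)), config = cfg,
                           window_days = Inf)
  expect_identical(preds$p_hcc[preds$visit <= 6], preds2$p_hcc[preds2$visit <= 6])
  expect_equal(nrow(preds), length(times))  # infinite window: every visit
})

test_that("a sustained score rise raises the predictive probability", {
  cfg <- predict_config(seed = 13, n_iter = 1200, n_burnin = 300)
  times <- seq(0, 1500, by = 125)
  n <- length(times)
  set.seed(31)
  wins <- logical(20)
  for (r in 1:20) {
    base <- rnorm(1, -3.2, 1.5)
    flat <- patient_record("flat", times, rnorm(n, base, 0.46), rep(0L, n))
    rise_mu <- base + pmax(times - (1500 - 365), 0) * (3 / 365)
    rise <- patient_record("rise", times, rnorm(n, rise_mu, 0.46), rep(0L, n))
    pf <- predict_visit(flat, config = cfg)$p_hcc
    pr <- predict_visit(rise, config = cfg)$p_hcc
    wins[r] <- pr > pf
  }
  expect_true(all(wins))
})

test_that("the sampler agrees with the exact enumeration/quadrature oracle", {
  rec <- patient_record("y", c(0, 150, 300, 450),
                        c(-3.2, -3.1, -2.4, -1.8), rep(0L, 4))
  p_mcmc <- predict_visit(rec, config = predict_config(seed = 1, n_iter = 6000,
                                                       n_burnin = 600))$p_hcc
  p_exact <- predict_visit_exact(rec, n_theta = 2000, seed = 1)
  expect_equal(p_mcmc, p_exact, tolerance = 0.3)  # relative; p ~ 0.15
  expect_lt(abs(p_mcmc - p_exact), 0.04)
})

test_that("raising every post-onset score never lowers the prediction", {
  cfg <- predict_config(seed = 17, n_iter = 1500, n_burnin = 300)
  times <- seq(0, 1200, by = 150)
  n <- length(times)
  set.seed(33)
  for (r in 1:8) {
    base <- rnorm(1, -3.2, 1)
    mu <- base + pmax(times - 800, 0) * 0.004
    sc <- rnorm(n, mu, 0.46)
    rec <- patient_record("p", times, sc, rep(0L, n))
    sc_up <- sc + 0.75 * (times > 800)
    rec_up <- patient_record("p", times, sc_up, rep(0L, n))
    p0 <- predict_visit(rec, config = cfg)
    p1 <- predict_visit(rec_up, config = cfg)
    se <- sqrt(p0$p_hcc * (1 - p0$p_hcc) / max(p0$n_eff, 1)) +
      sqrt(p1$p_hcc * (1 - p1$p_hcc) / max(p1$n_eff, 1))
    expect_gte(p1$p_hcc, p0$p_hcc - 2 * se)
  }
})

test_that("with a point-mass flat-slope prior the prediction reverts to the onset prior", {
  pr <- predictive_prior_spec(
    beta_mean = 1e-8, beta_sd = 1e-9,
    sigma_shape = 47309, sigma_rate = 102754,
    sigma_b_shape = 3320, sigma_b_rate = 1839,
    nzx_mean = c(-3.218, -7, 0), nzx_cov = diag(c(1e-6, 1e-6, 1e-6)))
  times <- seq(0, 1000, by = 100)
  set.seed(2)
  rec <- patient_record("x", times, rnorm(11, -3.2, 0.46), rep(0L, 11))
  p <- predict_visit(rec, pr, predict_config(seed = 5, n_iter = 8000,
                                             n_burnin = 1000))
  expect_lt(abs(p$p_hcc - (-expm1(-exp(-7) * 1000))), 0.04)
})

test_that("cohort prediction honours the trailing window and skips post-diagnosis visits", {
  cfg <- predict_config(seed = 19, n_iter = 400, n_burnin = 100)
  times <- seq(0, 2000, by = 250)
  set.seed(34)
  rec_n <- patient_record("n", times, rnorm(9, -3, 0.5), rep(0L, 9))
  rec_d <- patient_record("d", times[1:5], rnorm(5, -3, 0.5),
                          c(0L, 0L, 0L, 0L, 1L))
  rec_1 <- patient_record("s", 0, -3, 0L)
  coh <- galad_cohort(list(rec_n, rec_d, rec_1))
  preds <- predict_cohort(coh, config = cfg, window_days = 1500)
  # never-diagnosed: visits within 1500 days of the last (times >= 500)
  expect_identical(preds$time_days[preds$patient_id == "n"],
                   times[times >= 500])
  # diagnosed at day 1000: every visit up to and including diagnosis
  expect_identical(preds$time_days[preds$patient_id == "d"], times[1:5])
  # single-visit patient: one (zero) result
  expect_identical(preds$p_hcc[preds$patient_id == "s"], 0)
  expect_true(all(preds$p_hcc >= 0 & preds$p_hcc <= 1))
})

test_that("predictions are calibrated against the reduced model's own world", {
  # patients generated from the prediction model itself: every patient a
  # responder, diagnosis hazard negligible, parameters drawn from the same
  # priors the predictor uses -- binned predictive probabilities must then
  # match empirical onset frequencies
  pr <- predictive_prior_spec(
    beta_mean = 0.00604, beta_sd = 0.000207,
    sigma_shape = 47309, sigma_rate = 102754,
    sigma_b_shape = 3320, sigma_b_rate = 1839,
    nzx_mean = c(-3.218, -8.6, 0.445),
    nzx_cov = diag(c(0.002, 0.013, 0.0016)))
  set.seed(41)
  n <- 30
  times_grid <- seq(0, 1200, by = 150)
  recs <- vector("list", n); taus <- numeric(n)
  for (i in seq_len(n)) {
    nzx <- as.vector(pr$nzx_mean + pr$nzx_chol %*% rnorm(3))
    th <- model_parameters(
      beta = max(rnorm(1, pr$beta_mean, pr$beta_sd), 1e-6),
      sigma = rgamma(1, pr$sigma_shape, pr$sigma_rate),
      sigma_b = rgamma(1, pr$sigma_b_shape, pr$sigma_b_rate),
      nu = nzx[1], zeta = nzx[2], xi = nzx[3], delta = 1e-8, p_s = 1)
    sim <- simulate_patient(th, schedule_spec(n_patients = 1,
                                              followup_days = 1200,
                                              mean_intervisit = 150,
                                              p_missing_score = 0.1),
                            times = times_grid)
    sim$record$patient_id <- sprintf("C%02d", i)
    recs[[i]] <- sim$record
    taus[i] <- sim$truth$tau
  }
  coh <- galad_cohort(recs)
  preds <- predict_cohort(coh, pr,
                          predict_config(seed = 3, n_adapt = 150,
                                         n_iter = 1000, n_burnin = 250),
                          window_days = 900)
  names(taus) <- vapply(recs, `[[`, character(1), "patient_id")
  lab <- preds$time_days > taus[preds$patient_id]
  bins <- cut(preds$p_hcc, breaks = c(-0.01, 0.1, 0.5, 1.01))
  for (lv in levels(bins)) {
    i <- bins == lv
    if (sum(i) < 10) next
    p_hat <- mean(preds$p_hcc[i])
    se <- sqrt(max(p_hat * (1 - p_hat), 1e-3) / sum(i))
    expect_true(abs(mean(lab[i]) - p_hat) <= 3 * se)
  }
})

test_that("predictive prior specifications validate their matrix input", {
  expect_error(predictive_prior_spec(0.006, 2e-4, 1, 1, 1, 1,
                                     c(0, 0, 0), matrix(1:9, 3)),
               "symmetric")
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(predictive_prior_spec(0.006, 2e-4, 1, 1, 1, 1,
                                     c(0, 0, 0), bad),
               "positive definite")
  expect_error(predictive_prior_spec(0.006, -1, 1, 1, 1, 1,
                                     c(0, 0, 0), diag(3)),
               "positive")
  # precision form inverts to the covariance
  pr <- predictive_prior_spec(0.006, 2e-4, 1, 1, 1, 1, c(0, 0, 0),
                              diag(c(4, 5, 10)), cov_is_precision = TRUE)
  expect_equal(pr$nzx_cov, diag(c(0.25, 0.2, 0.1)))
})
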