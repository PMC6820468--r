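# Enumeration oracle for the onset-interval posterior of one undiagnosed
# patient at fixed parameters: b integrated by adaptive Gauss-Hermite, the
# responder flag enumerated, the onset day by Gauss-Legendre.  Includes the
# diagnosis-survival factor (an undiagnosed visit after onset is a false
# negative with probability exp(-delta * elapsed)).
enumerate_onset_posterior <- function(th, rec) {
  times <- rec$times
  J <- length(times)
  gh <- pracma::gaussHermite(40)
  obs <- !is.na(rec$scores)
  ag <- galadhmm:::agq_grid(gh, th$sigma_b, th$sigma,
                            sum(rec$scores[obs] - th$nu), sum(obs))
  logw_cfg <- function(kcfg) {
    terms <- numeric(0)
    for (g in seq_along(ag$b)) {
      bb <- ag$b[g]
      lam <- hazard_rate(th$zeta, th$xi, bb)
      for (s in 0:1) {
        lp_s <- if (s == 1) log(th$p_s) else log1p(-th$p_s)
        if (is.na(kcfg)) {
          ll <- -lam * times[J] +
            score_loglik(rec$scores,
                         mean_trajectory(th$nu, bb, s, Inf, th$beta, times),
                         th$sigma) +
            diagnosis_loglik(rec$diag, rep(0L, J), Inf, th$delta, times)
          terms <- c(terms, ag$logw[g] + lp_s + ll)
        } else {
          t0 <- times[kcfg]; t1 <- times[kcfg + 1]
          gl <- pracma::gaussLegendre(30, t0, t1)
          cp <- c(rep(0L, kcfg), rep(1L, J - kcfg))
          lpath <- -lam * t0 + log1p(-exp(-lam * (t1 - t0)))
          lltau <- vapply(gl$x, function(tt)
            score_loglik(rec$scores,
                         mean_trajectory(th$nu, bb, s, tt, th$beta, times),
                         th$sigma) +
              diagnosis_loglik(rec$diag, cp, tt, th$delta, times), numeric(1))
          terms <- c(terms, ag$logw[g] + lp_s + lpath +
                       galadhmm:::logsumexp(log(gl$w) + lltau) - log(t1 - t0))
        }
      }
    }
    galadhmm:::logsumexp(terms)
  }
  lw <- vapply(c(seq_len(J - 1), NA), logw_cfg, numeric(1))
  exp(lw - galadhmm:::logsumexp(lw))
}

test_that("the chain's onset-interval marginal matches the enumerated posterior", {
  th <- hot_parameters()
  rec <- patient_record("p", c(0, 200, 420), c(-3.1, -2.2, -0.9), c(0L, 0L, 0L))
  coh <- galad_cohort(list(rec))
  cfg <- mcmc_config(n_chains = 1, n_adapt = 300, n_iter = 20000,
                     n_burnin = 1000, seed = 3, store_latents = TRUE)
  fit <- fit_mcmc(coh, default_prior_spec(), cfg, fixed = unclass(th))
  k <- fit$latents[[1]]$k[-(1:1000), 1]
  post <- enumerate_onset_posterior(th, rec)
  lev <- c("1", "2", "none")
  kf <- ifelse(is.na(k), "none", as.character(k))
  for (j in seq_along(lev)) {
    x <- as.numeric(kf == lev[j])
    se <- batch_se(x)
    expect_true(abs(mean(x) - post[j]) <= 3 * se)
  }
})

test_that("the responder-flag frequency matches its Bernoulli full conditional", {
  # b pinned by a tiny sigma_b and a single forced onset interval, so only
  # tau varies; the marginal P(S = 1 | data) is a one-dimensional quadrature
  th <- model_parameters(beta = 0.008, sigma = 0.5, sigma_b = 1e-5, nu = -3,
                         zeta = -7, xi = 0.3, delta = 0.002, p_s = 0.6)
  rec <- patient_record("p", c(0, 400), c(-3.0, -1.2), c(0L, 1L))
  coh <- galad_cohort(list(rec))
  cfg <- mcmc_config(n_chains = 1, n_adapt = 200, n_iter = 20000,
                     n_burnin = 1000, seed = 4, store_latents = TRUE)
  fit <- fit_mcmc(coh, default_prior_spec(), cfg, fixed = unclass(th))
  S <- fit$latents[[1]]$S[-(1:1000), 1]
  gl <- pracma::gaussLegendre(60, 0, 400)
  num_s <- vapply(0:1, function(s) {
    lltau <- vapply(gl$x, function(tt) {
      cp <- as.integer(tt < rec$times)
      score_loglik(rec$scores,
                   mean_trajectory(th$nu, 0, s, tt, th$beta, rec$times),
                   th$sigma) +
        diagnosis_loglik(rec$diag, cp, tt, th$delta, rec$times)
    }, numeric(1))
    galadhmm:::logsumexp(log(gl$w) + lltau)
  }, numeric(1))
  p1 <- 1 / (1 + exp(log1p(-th$p_s) - log(th$p_s) + num_s[1] - num_s[2]))
  expect_true(abs(mean(S) - p1) <= 3 * batch_se(S))
})

test_that("with no information the posterior reproduces the prior", {
  # one visit per patient, every score missing, no diagnoses
  recs <- lapply(1:30, function(i)
    patient_record(sprintf("u%02d", i), 0, NA_real_, 0L))
  coh <- galad_cohort(recs)
  ps <- default_prior_spec()
  cfg <- mcmc_config(n_chains = 1, n_adapt = 500, n_iter = 8000,
                     n_burnin = 1000, seed = 6)
  fit <- fit_mcmc(coh, ps, cfg)
  x <- pooled_draws(fit)
  # p_s: Beta(0.5, 0.5) prior mean 0.5
  expect_true(abs(mean(x[, "p_s"]) - 0.5) <= 3 * batch_se(x[, "p_s"]))
  # sigma: U(0, 100) prior mean 50
  expect_true(abs(mean(x[, "sigma"]) - 50) <= 4 * batch_se(x[, "sigma"]))
})

test_that("stored draws always have a finite joint log-posterior", {
  coh <- simulate_cohort(hot_parameters(), schedule_spec(n_patients = 25),
                         seed = 14)
  ps <- default_prior_spec()
  cfg <- mcmc_config(n_chains = 1, n_adapt = 300, n_iter = 600, n_burnin = 100,
                     seed = 7, store_latents = TRUE)
  fit <- fit_mcmc(coh, ps, cfg)
  lat <- fit$latents[[1]]
  x <- fit$chains[[1]]
  set.seed(8)
  for (row in sample(nrow(x), 20)) {
    th <- do.call(model_parameters, as.list(x[row, ]))
    lats <- lapply(seq_along(coh$records), function(i)
      latent_state(lat$k[row, i], lat$tau[row, i], lat$S[row, i],
                   lat$b[row, i], coh$records[[i]]$times))
    expect_true(is.finite(joint_log_posterior(th, lats, coh, ps)))
  }
})

test_that("onset draws never contradict an observed diagnosis", {
  coh <- simulate_cohort(hot_parameters(), schedule_spec(n_patients = 40),
                         seed = 15)
  cfg <- mcmc_config(n_chains = 1, n_adapt = 200, n_iter = 400, n_burnin = 100,
                     seed = 9, store_latents = TRUE)
  fit <- fit_mcmc(coh, default_prior_spec(), cfg)
  lat <- fit$latents[[1]]
  for (i in seq_along(coh$records)) {
    d1 <- galadhmm:::first_diag_index(coh$records[[i]])
    if (is.na(d1)) next
    t_diag <- coh$records[[i]]$times[d1]
    expect_true(all(lat$tau[, i] < t_diag))
    expect_true(all(lat$k[, i] <= d1 - 1L))
  }
})

test_that("a first-visit diagnosis is rejected with the patient named", {
  recs <- list(patient_record("ok", c(0, 100), c(-3, -2), c(0L, 0L)),
               patient_record("bad", c(0, 100), c(-3, -2), c(1L, 1L)))
  coh <- galad_cohort(recs)
  expect_error(fit_mcmc(coh, config = mcmc_config_fast(n_iter = 10, n_burnin = 1)),
               "bad")
})

test_that("Gelman-Rubin diagnostics behave on identical, shifted and single chains", {
  set.seed(10)
  base <- matrix(rnorm(4000), 500, 8, dimnames = list(NULL, galadhmm:::PARAM_NAMES))
  mk <- function(chains) structure(
    list(chains = chains, config = mcmc_config(n_chains = length(chains),
                                               n_iter = 500, n_burnin = 100,
                                               thin = 1L)),
    class = "posterior_draws")
  expect_equal(unname(gelman_rubin(mk(list(base, base)))), rep(1, 8))
  shifted <- base + 10
  expect_true(all(gelman_rubin(mk(list(base, shifted))) > 1.1))
  expect_error(gelman_rubin(mk(list(base))), "2 chains")
})

test_that("posterior summaries use the Table-style layout and known quantiles", {
  const <- matrix(rep(c(0.006, 0.46, 1.8, -3.2, -10, 0.44, 3e-4, 0.66),
                      each = 200), 200, 8,
                  dimnames = list(NULL, galadhmm:::PARAM_NAMES))
  fake <- structure(list(chains = list(const),
                         config = mcmc_config(n_chains = 1, n_iter = 200,
                                              n_burnin = 10, thin = 1L)),
                    class = "posterior_draws")
  s <- summarize_posterior(fake)
  expect_identical(s$parameter,
                   c("beta", "sigma", "sigma_b", "nu", "zeta", "xi", "delta", "p_s"))
  expect_equal(s$mean, s$q05)
  expect_equal(s$mean, s$q95)
  set.seed(11)
  norm <- matrix(rnorm(8e5), 1e5, 8, dimnames = list(NULL, galadhmm:::PARAM_NAMES))
  fake2 <- structure(list(chains = list(norm),
                          config = mcmc_config(n_chains = 1, n_iter = 1e5,
                                               n_burnin = 10, thin = 1L)),
                     class = "posterior_draws")
  s2 <- summarize_posterior(fake2)
  expect_equal(s2$q05, rep(-1.645, 8), tolerance = 0.02)
})

test_that("moment-matched predictive priors recover known generating laws", {
  set.seed(12)
  n <- 1e5
  x <- cbind(beta = rnorm(n, 0.006, 2e-4),
             sigma = rgamma(n, 47309, 102754),
             sigma_b = rgamma(n, 3320, 1839),
             nu = rnorm(n, -3.2, 0.05),
             zeta = rnorm(n, -10.1, 0.1),
             xi = rnorm(n, 0.44, 0.05),
             delta = rgamma(n, 20, 6e4),
             p_s = rbeta(n, 20, 10))[, galadhmm:::PARAM_NAMES]
  fake <- structure(list(chains = list(x),
                         config = mcmc_config(n_chains = 1, n_iter = n,
                                              n_burnin = 10, thin = 1L)),
                    class = "posterior_draws")
  pr <- approximate_posterior_as_priors(fake)
  expect_equal(pr$sigma_shape, 47309, tolerance = 0.05)
  expect_equal(pr$sigma_rate, 102754, tolerance = 0.05)
  expect_equal(pr$sigma_b_shape, 3320, tolerance = 0.05)
  expect_equal(pr$beta_mean, 0.006, tolerance = 0.01)
  expect_equal(pr$nzx_mean, c(-3.2, -10.1, 0.44), tolerance = 0.01)
  # independent margins: near-diagonal fitted covariance
  cv <- pr$nzx_cov
  expect_lt(max(abs(cv[upper.tri(cv)])) / min(diag(cv)), 0.05)
  expect_true(all(attr(pr, "qq") < 0.01))
  # constant draws are degenerate
  x2 <- x; x2[, "beta"] <- 0.006
  fake2 <- fake; fake2$chains <- list(x2)
  expect_error(approximate_posterior_as_priors(fake2), "degenerate")
})

test_that("simulation-based calibration ranks are uniform at toy scale", {
  ps <- prior_spec(h_beta = 0.02, h_sigma = 2, h_sigma_b = 4, h_nu = 9,
                   h_zeta = c(-9, -5), h_xi = c(-0.5, 0.5), h_delta = 0.02,
                   h_s = c(1, 1))
  spec <- schedule_spec(n_patients = 12, followup_days = 900,
                        mean_intervisit = 150, intervisit_dispersion = 0.3,
                        p_missing_score = 0.1)
  cfg <- mcmc_config(n_chains = 1, n_adapt = 300, n_iter = 1200,
                     n_burnin = 200, thin = 20, seed = 1)
  set.seed(77)
  R <- 50
  ranks <- matrix(NA_integer_, R, 2)
  for (r in seq_len(R)) {
    # parameter draws from the prior (scale parameters kept off the origin
    # to avoid degenerate cohorts)
    th <- model_parameters(beta = runif(1, 1e-6, ps$h_beta),
                           sigma = runif(1, 0.05, ps$h_sigma),
                           sigma_b = runif(1, 0.05, ps$h_sigma_b),
                           nu = rnorm(1, 0, sqrt(ps$h_nu)),
                           zeta = runif(1, ps$h_zeta[1], ps$h_zeta[2]),
                           xi = runif(1, ps$h_xi[1], ps$h_xi[2]),
                           delta = runif(1, 1e-7, ps$h_delta),
                           p_s = rbeta(1, ps$h_s[1], ps$h_s[2]))
    coh <- simulate_cohort(th, spec)
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    fit <- fit_mcmc(coh, ps, cfg_r)
    x <- pooled_draws(fit)   # 50 thinned post-burn-in draws
    ranks[r, 1] <- sum(x[, "nu"] < th$nu)
    ranks[r, 2] <- sum(x[, "sigma"] < th$sigma)
  }
  for (j in 1:2) {
    bins <- table(cut(ranks[, j], breaks = c(-0.5, 16.5, 33.5, 50.5)))
    expect_gt(suppressWarnings(stats::chisq.test(bins)$p.value), 0.01)
  }
})
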