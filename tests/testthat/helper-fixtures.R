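# Shared fixture builders.  Everything is generated in code; tests that need
# randomness set their own seed.

# A short record with optional missing scores and a final-visit diagnosis.
make_record <- function(id = "P1", times = c(0, 100, 250),
                        scores = c(-3.0, -2.8, -2.5),
                        diag = rep(0L, length(times))) {
  patient_record(id, times, scores, diag)
}

# Random small patient drawn from the generative model at given parameters.
random_small_patient <- function(theta, n_visits = 3L, span = 500) {
  times <- sort(c(0, runif(n_visits - 1L, 1, span)))
  sim <- simulate_patient(theta, schedule_spec(n_patients = 1L,
                                               followup_days = span,
                                               mean_intervisit = span / n_visits,
                                               p_missing_score = 0.1),
                          times = times)
  sim
}

# Parameters with a hazard high enough that onset actually happens in short
# windows; used where tests need informative latent structure.
hot_parameters <- function() {
  model_parameters(beta = 0.01, sigma = 0.5, sigma_b = 1.5, nu = -3,
                   zeta = -6.5, xi = 0.4, delta = 0.002, p_s = 0.6)
}

# Monte-Carlo marginal likelihood from the model's latent prior (vectorized);
# returns the log estimate and the (delta-method) SE of the log.
mc_marginal_loglik <- function(theta, record, n_mc = 40000L) {
  times <- record$times
  J <- length(times)
  b <- rnorm(n_mc, 0, theta$sigma_b)
  S <- rbinom(n_mc, 1L, theta$p_s)
  lam <- exp(theta$zeta + theta$xi * b)
  # interval probabilities under the absorbing chain at the visit grid
  pk <- matrix(0, n_mc, J)
  for (k in seq_len(J - 1L))
    pk[, k] <- exp(-lam * times[k]) * (-expm1(-lam * (times[k + 1L] - times[k])))
  pk[, J] <- exp(-lam * times[J])  # no onset
  u <- runif(n_mc) * rowSums(pk)
  kdraw <- max.col((u <= t(apply(pk, 1L, cumsum))), ties.method = "first")
  tau <- rep(Inf, n_mc)
  ii <- which(kdraw < J)
  tau[ii] <- times[kdraw[ii]] +
    runif(length(ii)) * (times[kdraw[ii] + 1L] - times[kdraw[ii]])
  Tm <- matrix(times, n_mc, J, byrow = TRUE)
  MU <- theta$nu + b + (S * theta$beta) * pmax(Tm - tau, 0)
  SLL <- rowSums(dnorm(matrix(record$scores, n_mc, J, byrow = TRUE), MU,
                       theta$sigma, log = TRUE), na.rm = TRUE)
  q <- -expm1(-theta$delta * pmax(Tm - tau, 0))
  D <- matrix(record$diag, n_mc, J, byrow = TRUE)
  L <- log1p(-q)
  L[D == 1L] <- log(q[D == 1L])
  w <- exp(SLL + rowSums(L))
  list(log_est = log(mean(w)), se_log = sd(w) / sqrt(n_mc) / mean(w))
}

# Batch-means Monte-Carlo SE for the mean of a (possibly autocorrelated)
# chain of values.
batch_se <- function(x, n_batch = 40L) {
  m <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1L) * m + 1L):(i * m)]),
               numeric(1L))
  sd(bm) / sqrt(n_batch)
}
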