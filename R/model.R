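#' Onset hazard under the log-linear link
#'
#' The per-day hazard of tumour onset is `lambda = exp(zeta + xi * b)`:
#' patients with a higher baseline biomarker level (larger random effect `b`)
#' carry a larger onset hazard when `xi > 0`.
#'
#' @param zeta log-hazard intercept (per-day log scale).
#' @param xi coefficient on the baseline deviation (per score unit).
#' @param b baseline deviation(s); vectorized.
#' @return per-day hazard(s), strictly positive.
#' @export
#' @examples
#' hazard_rate(-10.123, 0.445, b = c(-2, 0, 2))
hazard_rate <- function(zeta, xi, b) {
  if (!all(is.finite(c(zeta, xi, b))))
    stop("hazard_rate: all inputs must be finite", call. = FALSE)
  exp(zeta + xi * b)
}

#' Continuous-time transition matrix over an interval
#'
#' Two states: 0 = tumour free, 1 = tumour present (absorbing).  Over an
#' interval of length `dt` days with onset hazard `lam`, the transition
#' matrix is the matrix exponential of the absorbing generator, i.e. row 0 is
#' `(exp(-lam*dt), 1 - exp(-lam*dt))` and row 1 is `(0, 1)`.
#'
#' @param lam per-day onset hazard (> 0).
#' @param dt elapsed time in days (>= 0).
#' @return a 2x2 row-stochastic matrix.
#' @export
transition_matrix <- function(lam, dt) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be a positive finite scalar", call. = FALSE)
  if (!is.finite(dt) || dt < 0) stop("dt must be non-negative", call. = FALSE)
  p01 <- -expm1(-lam * dt)
  matrix(c(1 - p01, 0, p01, 1), nrow = 2L,
         dimnames = list(c("free", "tumour"), c("free", "tumour")))
}

#' Mean biomarker trajectory
#'
#' Flat at `nu + b` before onset (and always, for non-responders); rising
#' linearly with slope `beta` from the onset day `tau` for responders.  The
#' per-visit tumour indicator follows the convention `C_j = I(tau < t_j)`.
#'
#' @param nu population mean baseline.
#' @param b patient baseline deviation.
#' @param s_flag responder indicator (0/1).
#' @param tau onset day (`Inf` for no onset).
#' @param beta post-onset slope (> 0).
#' @param times visit times (ordered).
#' @return vector of per-visit mean scores.
#' @export
mean_trajectory <- function(nu, b, s_flag, tau, beta, times) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing", call. = FALSE)
  on <- tau < times
  nu + b + ifelse(on, s_flag * beta * (times - tau), 0)
}

#' Gaussian score log-likelihood
#'
#' Sum of Gaussian log-densities over visits with an observed score; visits
#' with a missing score contribute exactly 0 (likelihood omission, never
#' imputation).
#'
#' @param scores observed scores (`NA` = missing).
#' @param means per-visit means (same length).
#' @param sigma within-patient SD (> 0).
#' @return scalar log-likelihood.
#' @export
score_loglik <- function(scores, means, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(scores) != length(means)) stop("scores/means length mismatch", call. = FALSE)
  obs <- !is.na(scores)
  if (!any(obs)) return(0)
  sum(dnorm(scores[obs], means[obs], sigma, log = TRUE))
}

#' Log-probability of a latent tumour-state path
#'
#' The path is evaluated under the absorbing continuous-time chain observed
#' at the visit grid: an all-zero path over total span `T` has log-probability
#' `-lam * T`; onset in interval `k` contributes `-lam * t_k +
#' log(1 - exp(-lam * dt_{k+1}))`; continuation in the absorbed state is free.
#' Any 1 -> 0 transition is impossible (`-Inf`).  A path already positive at
#' the first visit follows the point-mass convention (onset fixed at day 0)
#' and contributes no density.
#'
#' @param c_path 0/1 per-visit path.
#' @param lam per-day onset hazard (> 0).
#' @param times visit times.
#' @return scalar log-probability (possibly `-Inf`).
#' @export
path_loglik <- function(c_path, lam, times) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0", call. = FALSE)
  J <- length(c_path)
  if (length(times) != J) stop("c_path/times length mismatch", call. = FALSE)
  if (J > 1L && any(diff(c_path) < 0)) return(-Inf)
  if (c_path[1L] == 1L) return(0)   # AT_FIRST convention: no density contribution
  if (c_path[J] == 0L) return(-lam * times[J])
  k <- which(c_path == 1L)[1L] - 1L  # onset in (t_k, t_{k+1}]
  -lam * times[k] + log1p(-exp(-lam * (times[k + 1L] - times[k])))
}

#' Uniform onset-time log-prior within the transition interval
#'
#' Given that onset happened between consecutive visits at `t0 < t1`, the
#' onset day is uniform on that interval.  The degenerate tumour-at-first-visit
#' case is a point mass at 0 and returns 0 (pass `at_first = TRUE`).
#'
#' @param tau onset day.
#' @param t0,t1 interval endpoints, `t0 < t1`.
#' @param at_first logical; use the point-mass convention.
#' @return scalar log-density.
#' @export
onset_logprior <- function(tau, t0, t1, at_first = FALSE) {
  if (at_first) return(0)
  if (!is.finite(t0) || !is.finite(t1) || t0 >= t1)
    stop("onset interval must satisfy t0 < t1", call. = FALSE)
  if (tau > t0 && tau < t1) -log(t1 - t0) else -Inf
}

#' Diagnosis log-likelihood
#'
#' Clinical diagnosis at visit `j` is Bernoulli with success probability
#' `1 - exp(-delta * (t_j - tau))` when the tumour is present and 0 when it
#' is absent (no false positives).  Contributions are counted at each visit
#' up to and including the first positive one; later visits are censored.
#'
#' @param diag per-visit 0/1 diagnosis indicators (monotone).
#' @param c_path per-visit 0/1 tumour path.
#' @param tau onset day (`Inf` if no onset).
#' @param delta per-day diagnosis hazard (> 0).
#' @param times visit times.
#' @return scalar log-likelihood (`-Inf` for a diagnosis without a tumour).
#' @export
diagnosis_loglik <- function(diag, c_path, tau, delta, times) {
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0", call. = FALSE)
  J <- length(times)
  upto <- if (any(diag == 1L)) which(diag == 1L)[1L] else J
  ll <- 0
  for (j in seq_len(upto)) {
    q <- if (c_path[j] == 1L) -expm1(-delta * max(times[j] - tau, 0)) else 0
    ll <- ll + if (diag[j] == 1L) log(q) else log1p(-q)
    if (is.infinite(ll)) return(-Inf)
  }
  ll
}

#' Responder-mixture and random-effect log-priors
#'
#' `mixture_logprior` is the Bernoulli log-mass of the responder indicator;
#' `random_effect_logprior` the zero-mean Gaussian log-density of the
#' baseline deviation.
#'
#' @param s_flag responder indicator (0/1).
#' @param p_s responder probability.
#' @return scalar log-density.
#' @export
mixture_logprior <- function(s_flag, p_s) {
  if (p_s < 0 || p_s > 1) stop("p_s must lie in [0, 1]", call. = FALSE)
  if (s_flag == 1L) log(p_s) else log1p(-p_s)
}

#' @param b baseline deviation.
#' @param sigma_b between-patient SD (> 0).
#' @rdname mixture_logprior
#' @export
random_effect_logprior <- function(b, sigma_b) {
  if (sigma_b <= 0) stop("sigma_b must be > 0", call. = FALSE)
  dnorm(b, 0, sigma_b, log = TRUE)
}

#' Hyperprior log-density of the model parameters
#'
#' Evaluates the product of the prior families in [prior_spec()] at a
#' parameter vector; `-Inf` outside any uniform bound (including the
#' structural constraint `beta > 0`).
#'
#' @param theta [model_parameters()] (or a compatible named list).
#' @param priors [prior_spec()].
#' @return scalar log-density.
#' @export
hyperprior_logdensity <- function(theta, priors = default_prior_spec()) {
  if (!inherits(priors, "prior_spec")) stop("priors must be a prior_spec", call. = FALSE)
  th <- theta
  if (th$beta <= 0 || th$beta >= priors$h_beta) return(-Inf)
  if (th$sigma <= 0 || th$sigma >= priors$h_sigma) return(-Inf)
  if (th$sigma_b <= 0 || th$sigma_b >= priors$h_sigma_b) return(-Inf)
  if (th$zeta <= priors$h_zeta[1L] || th$zeta >= priors$h_zeta[2L]) return(-Inf)
  if (th$xi <= priors$h_xi[1L] || th$xi >= priors$h_xi[2L]) return(-Inf)
  if (th$delta <= 0 || th$delta >= priors$h_delta) return(-Inf)
  if (th$p_s < 0 || th$p_s > 1) return(-Inf)
  -log(priors$h_beta) - log(priors$h_sigma) - log(priors$h_sigma_b) -
    log(diff(priors$h_zeta)) - log(diff(priors$h_xi)) - log(priors$h_delta) +
    dnorm(th$nu, 0, sqrt(priors$h_nu), log = TRUE) +
    dbeta(th$p_s, priors$h_s[1L], priors$h_s[2L], log = TRUE)
}

# Log-posterior factors for one patient at given latents; returns -Inf for
# inconsistent configurations instead of raising.
patient_log_factors <- function(theta, lat, record) {
  times <- record$times
  J <- length(times)
  k <- lat$onset_interval
  tau <- lat$tau
  # consistency of (onset_interval, tau)
  if (is.na(k)) {
    if (is.finite(tau) && tau < times[J]) return(-Inf)
    tau <- Inf
  } else if (k == 0L) {
    if (!isTRUE(tau == 0)) return(-Inf)
  } else {
    if (k < 1L || k >= J) return(-Inf)
    if (!(tau > times[k] && tau < times[k + 1L])) return(-Inf)
  }
  c_path <- as.integer(tau < times)
  if (!is.na(k) && k == 0L) c_path[1L] <- 1L
  if (any(record$diag == 1L & c_path == 0L)) return(-Inf)
  lam <- hazard_rate(theta$zeta, theta$xi, lat$b_effect)
  mu <- mean_trajectory(theta$nu, lat$b_effect, lat$s_flag, tau, theta$beta, times)
  ll <- score_loglik(record$scores, mu, theta$sigma) +
    diagnosis_loglik(record$diag, c_path, tau, theta$delta, times) +
    mixture_logprior(lat$s_flag, theta$p_s) +
    random_effect_logprior(lat$b_effect, theta$sigma_b) +
    path_loglik(c_path, lam, times)
  if (!is.na(k) && k >= 1L)
    ll <- ll + onset_logprior(tau, times[k], times[k + 1L])
  else if (!is.na(k) && k == 0L)
    ll <- ll + onset_logprior(0, 0, 1, at_first = TRUE)
  ll
}

#' Unnormalized joint log-posterior
#'
#' Sum over patients of the six likelihood/system factors (score
#' observations, diagnosis observations, responder mixture, baseline random
#' effect, onset-time prior and latent path) plus the hyperprior.
#' Inconsistent latent configurations yield `-Inf` rather than an error, so
#' samplers can reject them gracefully.
#'
#' @param theta [model_parameters()].
#' @param latents list of [latent_state()]s aligned with the cohort.
#' @param cohort [galad_cohort()].
#' @param priors [prior_spec()].
#' @return scalar unnormalized log-posterior density.
#' @export
joint_log_posterior <- function(theta, latents, cohort,
                                priors = default_prior_spec()) {
  lp <- hyperprior_logdensity(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  for (i in seq_along(cohort$records)) {
    lp <- lp + patient_log_factors(theta, latents[[i]], cohort$records[[i]])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}
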