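# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.nan(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Quadrature configuration for the marginal-likelihood oracle
#'
#' @param gh_nodes adaptive Gauss-Hermite order for the baseline random
#'   effect (nodes are centred and scaled by the Gaussian approximation to
#'   the conditional posterior of `b`).
#' @param tau_nodes Gauss-Legendre order per onset interval.
#' @return list of class `marginal_quad_config`.
#' @export
marginal_quad_config <- function(gh_nodes = 40L, tau_nodes = 15L) {
  if (gh_nodes < 3L || tau_nodes < 3L)
    stop("quadrature order must be at least 3", call. = FALSE)
  structure(list(gh_nodes = as.integer(gh_nodes),
                 tau_nodes = as.integer(tau_nodes)),
            class = "marginal_quad_config")
}

# Adaptive Gauss-Hermite nodes/log-weights for integrating a function
# against the N(0, sigma_b^2) random-effect prior: nodes are centred at the
# Gaussian (Laplace) approximation to the conditional posterior of b given
# the observed scores around a flat mean.  resid_sum is sum(y_obs - nu),
# n_obs the number of observed scores.  The prior density is folded into the
# log-weights, so sum(exp(logw + log f(b))) approximates E_prior[f(b)].
agq_grid <- function(gh, sigma_b, sigma, resid_sum, n_obs) {
  prec <- 1 / sigma_b^2 + n_obs / sigma^2
  b_hat <- (resid_sum / sigma^2) / prec
  s_hat <- 1 / sqrt(prec)
  b <- b_hat + sqrt(2) * s_hat * gh$x
  logw <- log(gh$w) + gh$x^2 + 0.5 * log(2) + log(s_hat) +
    dnorm(b, 0, sigma_b, log = TRUE)
  list(b = b, logw = logw)
}

#' Exact per-patient marginal log-likelihood (small-instance oracle)
#'
#' Integrates the latent variables out of one patient's likelihood: the
#' baseline deviation by Gauss-Hermite quadrature, the responder flag by
#' enumeration, the onset interval by enumeration over every between-visit
#' interval plus "no onset", and the onset day by Gauss-Legendre quadrature
#' on each interval.  Onset strictly before the first visit carries no prior
#' mass (the hazard clock starts at the first visit), so that configuration
#' contributes nothing.  Intended as an independent cross-check on small
#' patients, not as a fitting engine.
#'
#' @param theta [model_parameters()].
#' @param record [patient_record()] with a small number of visits.
#' @param quad [marginal_quad_config()].
#' @return scalar marginal log-likelihood of the patient's scores and
#'   diagnosis indicators.
#' @export
patient_marginal_loglik <- function(theta, record,
                                    quad = marginal_quad_config()) {
  if (!inherits(quad, "marginal_quad_config"))
    quad <- do.call(marginal_quad_config, as.list(quad))
  times <- record$times
  J <- length(times)
  gh <- pracma::gaussHermite(quad$gh_nodes)
  obs <- !is.na(record$scores)
  ag <- agq_grid(gh, theta$sigma_b, theta$sigma,
                 sum(record$scores[obs] - theta$nu), sum(obs))
  b_nodes <- ag$b
  log_wb <- ag$logw

  log_ps <- c(log1p(-theta$p_s), log(theta$p_s))  # S = 0, 1

  cond_b <- vapply(seq_along(b_nodes), function(m) {
    b <- b_nodes[m]
    lam <- hazard_rate(theta$zeta, theta$xi, b)
    terms <- numeric(0L)
    for (s in 0:1) {
      # no onset within the study window
      c0 <- rep(0L, J)
      ll_none <- -lam * times[J] +
        score_loglik(record$scores,
                     mean_trajectory(theta$nu, b, s, Inf, theta$beta, times),
                     theta$sigma) +
        diagnosis_loglik(record$diag, c0, Inf, theta$delta, times)
      terms <- c(terms, log_ps[s + 1L] + ll_none)
      for (k in seq_len(J - 1L)) {
        t0 <- times[k]; t1 <- times[k + 1L]
        gl <- pracma::gaussLegendre(quad$tau_nodes, t0, t1)
        cpath <- as.integer(c(rep(0L, k), rep(1L, J - k)))
        lpath <- -lam * t0 + log1p(-exp(-lam * (t1 - t0)))
        ll_tau <- vapply(seq_along(gl$x), function(r) {
          tau <- gl$x[r]
          score_loglik(record$scores,
                       mean_trajectory(theta$nu, b, s, tau, theta$beta, times),
                       theta$sigma) +
            diagnosis_loglik(record$diag, cpath, tau, theta$delta, times)
        }, numeric(1L))
        int_tau <- logsumexp(log(gl$w) + ll_tau) - log(t1 - t0)
        terms <- c(terms, log_ps[s + 1L] + lpath + int_tau)
      }
    }
    logsumexp(terms)
  }, numeric(1L))

  logsumexp(log_wb + cond_b)
}
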