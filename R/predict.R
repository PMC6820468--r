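#' Informative prior specification for prospective prediction
#'
#' The reduced prediction model (no diagnosis factor, no responder mixture)
#' is fitted per visit under informative priors summarizing the training
#' posterior: a normal for `beta` (truncated at 0 when used, honouring the
#' structural constraint), gammas (shape/rate) for `sigma` and `sigma_b`,
#' and a trivariate normal for `(nu, zeta, xi)` whose spread may be supplied
#' either as a covariance or as a precision matrix.
#'
#' @param beta_mean,beta_sd normal law for `beta`.
#' @param sigma_shape,sigma_rate gamma law for `sigma`.
#' @param sigma_b_shape,sigma_b_rate gamma law for `sigma_b`.
#' @param nzx_mean length-3 mean vector of `(nu, zeta, xi)`.
#' @param nzx_cov 3x3 symmetric positive-definite matrix.
#' @param cov_is_precision if `TRUE`, `nzx_cov` is a precision matrix and is
#'   inverted internally.
#' @return object of class `predictive_prior_spec` (with the covariance
#'   stored, whatever form was supplied).
#' @export
predictive_prior_spec <- function(beta_mean, beta_sd, sigma_shape, sigma_rate,
                                  sigma_b_shape, sigma_b_rate,
                                  nzx_mean, nzx_cov, cov_is_precision = FALSE) {
  if (beta_sd <= 0 || sigma_shape <= 0 || sigma_rate <= 0 ||
      sigma_b_shape <= 0 || sigma_b_rate <= 0)
    stop("predictive_prior_spec: scale parameters must be positive", call. = FALSE)
  nzx_cov <- as.matrix(nzx_cov)
  if (!isTRUE(all.equal(nzx_cov, t(nzx_cov), tolerance = 1e-8)))
    stop("nzx matrix must be symmetric", call. = FALSE)
  if (cov_is_precision) nzx_cov <- solve(nzx_cov)
  ch <- tryCatch(chol(nzx_cov), error = function(e) NULL)
  if (is.null(ch))
    stop("(nu, zeta, xi) covariance is not positive definite", call. = FALSE)
  structure(list(beta_mean = unname(beta_mean), beta_sd = unname(beta_sd),
                 sigma_shape = unname(sigma_shape), sigma_rate = unname(sigma_rate),
                 sigma_b_shape = unname(sigma_b_shape),
                 sigma_b_rate = unname(sigma_b_rate),
                 nzx_mean = unname(nzx_mean), nzx_cov = unname(nzx_cov),
                 nzx_chol = t(ch)),
            class = "predictive_prior_spec")
}

#' Reference informative priors for prediction
#'
#' The moment-matched informative priors obtained from the training-stage
#' fit on the reference surveillance cohort; the `(nu, zeta, xi)` spread is
#' supplied as a precision matrix and inverted internally.
#'
#' @return a [predictive_prior_spec()].
#' @export
default_predictive_priors <- function() {
  predictive_prior_spec(
    beta_mean = 0.00604, beta_sd = 0.000207,
    sigma_shape = 47309, sigma_rate = 102754,
    sigma_b_shape = 3320, sigma_b_rate = 1839,
    nzx_mean = c(-3.218, -10.123, 0.445),
    nzx_cov = rbind(c(523, -35, -44),
                    c(-35, 113, 175),
                    c(-44, 175, 908)),
    cov_is_precision = TRUE)
}

#' Prediction run configuration
#'
#' @param n_adapt adaptation iterations.
#' @param n_iter post-adaptation iterations.
#' @param n_burnin iterations discarded before computing the predictive
#'   probability.
#' @param seed integer seed (every per-visit refit is deterministic given
#'   the seed).
#' @return object of class `predict_config`.
#' @export
predict_config <- function(n_adapt = 300L, n_iter = 2000L, n_burnin = 400L,
                           seed = 1L) {
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter", call. = FALSE)
  structure(list(n_adapt = as.integer(n_adapt), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), seed = as.integer(seed)),
            class = "predict_config")
}

#' Posterior predictive probability of undiagnosed tumour presence
#'
#' Fits the reduced model to one patient's history (the target visit and all
#' previous visits, never later ones) under informative priors and returns
#' the posterior probability that tumour onset has occurred by the target
#' visit.  The reduced model keeps the score observation model, the latent
#' onset process and the baseline random effect, fixes the responder flag to
#' 1, and removes the diagnosis factor and the mixture weight.
#'
#' @param history [patient_record()] truncated at the target visit; must not
#'   contain a positive diagnosis.
#' @param priors [predictive_prior_spec()].
#' @param config [predict_config()].
#' @return object of class `prediction_result`: `patient_id`, `visit`,
#'   `time_days`, `p_hcc`, `n_draws`, `n_eff`.
#' @export
predict_visit <- function(history, priors = default_predictive_priors(),
                          config = predict_config()) {
  stopifnot(inherits(history, "patient_record"),
            inherits(priors, "predictive_prior_spec"))
  if (any(history$diag == 1L))
    stop("prediction history must not contain a positive diagnosis", call. = FALSE)
  J <- length(history$times)
  if (J < 1L) stop("empty history", call. = FALSE)
  res <- function(p, nd, neff)
    structure(list(patient_id = history$patient_id, visit = J,
                   time_days = history$times[J], p_hcc = p,
                   n_draws = nd, n_eff = neff),
              class = "prediction_result")
  if (J == 1L)  # no interval in which onset can have occurred (tau < t convention)
    return(res(0, 0L, 0))
  set.seed(config$seed)
  onset <- reduced_chain(history, priors, config)
  p <- mean(onset)
  res(p, length(onset), ess_binary(onset))
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction %s visit %d (day %.0f): P(tumour present) = %.4f (%d draws)>\n",
              x$patient_id, x$visit, x$time_days, x$p_hcc, x$n_draws))
  invisible(x)
}

# Effective sample size of a binary draw sequence via the initial
# positive-autocorrelation truncation rule.
ess_binary <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L || var(x) == 0) return(n)
  r <- as.vector(acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf)[-1L]
  neg <- which(r <= 0)
  if (length(neg)) r <- r[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(r))
}

# One chain of the reduced (prediction) sampler for a single patient.
# Returns the kept draws of the onset indicator I(tau < t_J).
reduced_chain <- function(history, priors, config) {
  times <- history$times
  y <- history$scores
  J <- length(times)
  lastT <- times[J]

  # initial values at the prior centre
  beta <- max(priors$beta_mean, 1e-8)
  sigma <- priors$sigma_shape / priors$sigma_rate
  sigma_b <- priors$sigma_b_shape / priors$sigma_b_rate
  nzx <- priors$nzx_mean
  b <- 0
  kk <- NA_integer_; tau <- Inf

  score_ll <- function(beta, sigma, nu, tau, b) {
    mu <- nu + b + beta * pmax(times - tau, 0)
    sum(dnorm(y, mu, sigma, log = TRUE), na.rm = TRUE)
  }
  path_ll <- function(lam, kk, tau) {
    if (is.na(kk)) return(-lam * lastT)
    -lam * times[kk] + log1p(-exp(-lam * (times[kk + 1L] - times[kk])))
  }
  lam <- exp(nzx[2L] + nzx[3L] * b)
  sll <- score_ll(beta, sigma, nzx[1L], tau, b)
  pll <- path_ll(lam, kk, tau)

  ls <- c(b = log(0.5), beta = log(priors$beta_sd), sigma = log(0.05),
          sigma_b = log(0.05), nzx = log(0.8))
  acc <- win <- setNames(numeric(length(ls)), names(ls))
  total_iter <- config$n_adapt + config$n_iter
  keep_from <- config$n_adapt + config$n_burnin
  onset <- logical(config$n_iter - config$n_burnin)

  for (iter in seq_len(total_iter)) {
    adapting <- iter <= config$n_adapt

    # onset interval + day (uniform proposal over {1..J-1, none})
    pick <- max(min(ceiling(runif(1L) * J), J), 1L)
    if (pick == J) { k_p <- NA_integer_; tau_p <- Inf }
    else { k_p <- pick; tau_p <- times[pick] + runif(1L) * (times[pick + 1L] - times[pick]) }
    sll_p <- score_ll(beta, sigma, nzx[1L], tau_p, b)
    pll_p <- path_ll(lam, k_p, tau_p)
    if (log(runif(1L)) < (sll_p - sll) + (pll_p - pll)) {
      kk <- k_p; tau <- tau_p; sll <- sll_p; pll <- pll_p
    }
    # onset-day refresh
    if (!is.na(kk)) {
      tau_p <- times[kk] + runif(1L) * (times[kk + 1L] - times[kk])
      sll_p <- score_ll(beta, sigma, nzx[1L], tau_p, b)
      if (log(runif(1L)) < sll_p - sll) { tau <- tau_p; sll <- sll_p }
    }
    # baseline deviation
    b_p <- b + rnorm(1L) * exp(ls["b"])
    lam_p <- exp(nzx[2L] + nzx[3L] * b_p)
    sll_p <- score_ll(beta, sigma, nzx[1L], tau, b_p)
    pll_p <- path_ll(lam_p, kk, tau)
    win["b"] <- win["b"] + 1
    if (log(runif(1L)) < (sll_p - sll) + (pll_p - pll) +
        dnorm(b_p, 0, sigma_b, log = TRUE) - dnorm(b, 0, sigma_b, log = TRUE)) {
      b <- b_p; lam <- lam_p; sll <- sll_p; pll <- pll_p
      acc["b"] <- acc["b"] + 1
    }
    # beta: natural-scale walk, normal prior truncated at 0
    beta_p <- beta + rnorm(1L) * exp(ls["beta"])
    win["beta"] <- win["beta"] + 1
    if (beta_p > 0) {
      sll_p <- score_ll(beta_p, sigma, nzx[1L], tau, b)
      if (log(runif(1L)) < sll_p - sll +
          dnorm(beta_p, priors$beta_mean, priors$beta_sd, log = TRUE) -
          dnorm(beta, priors$beta_mean, priors$beta_sd, log = TRUE)) {
        beta <- beta_p; sll <- sll_p; acc["beta"] <- acc["beta"] + 1
      }
    }
    # sigma: log-scale walk, gamma prior
    sigma_p <- sigma * exp(rnorm(1L) * exp(ls["sigma"]))
    win["sigma"] <- win["sigma"] + 1
    sll_p <- score_ll(beta, sigma_p, nzx[1L], tau, b)
    if (log(runif(1L)) < sll_p - sll +
        dgamma(sigma_p, priors$sigma_shape, priors$sigma_rate, log = TRUE) -
        dgamma(sigma, priors$sigma_shape, priors$sigma_rate, log = TRUE) +
        log(sigma_p) - log(sigma)) {
      sigma <- sigma_p; sll <- sll_p; acc["sigma"] <- acc["sigma"] + 1
    }
    # sigma_b: log-scale walk, gamma prior (only the b prior factor moves)
    sigma_b_p <- sigma_b * exp(rnorm(1L) * exp(ls["sigma_b"]))
    win["sigma_b"] <- win["sigma_b"] + 1
    d <- dnorm(b, 0, sigma_b_p, log = TRUE) - dnorm(b, 0, sigma_b, log = TRUE) +
      dgamma(sigma_b_p, priors$sigma_b_shape, priors$sigma_b_rate, log = TRUE) -
      dgamma(sigma_b, priors$sigma_b_shape, priors$sigma_b_rate, log = TRUE) +
      log(sigma_b_p) - log(sigma_b)
    if (log(runif(1L)) < d) { sigma_b <- sigma_b_p; acc["sigma_b"] <- acc["sigma_b"] + 1 }
    # (nu, zeta, xi): joint walk with the prior Cholesky as proposal shape
    nzx_p <- nzx + as.vector(priors$nzx_chol %*% rnorm(3L)) * exp(ls["nzx"])
    win["nzx"] <- win["nzx"] + 1
    lam_p <- exp(nzx_p[2L] + nzx_p[3L] * b)
    sll_p <- score_ll(beta, sigma, nzx_p[1L], tau, b)
    pll_p <- path_ll(lam_p, kk, tau)
    dmvn <- function(v) {
      z <- forwardsolve(priors$nzx_chol, v - priors$nzx_mean)
      -0.5 * sum(z^2)
    }
    if (log(runif(1L)) < (sll_p - sll) + (pll_p - pll) + dmvn(nzx_p) - dmvn(nzx)) {
      nzx <- nzx_p; lam <- lam_p; sll <- sll_p; pll <- pll_p
      acc["nzx"] <- acc["nzx"] + 1
    }

    if (adapting && iter %% 25L == 0L) {
      for (nm in names(ls)) {
        if (win[nm] > 0) ls[nm] <- adapt_scale(ls[nm], acc[nm] / win[nm])
        acc[nm] <- 0; win[nm] <- 0
      }
    }
    if (iter > keep_from) onset[iter - keep_from] <- !is.na(kk)
  }
  onset
}

#' Predict every windowed visit of a test cohort
#'
#' Applies [predict_visit()] independently at each (patient, visit) pair
#' using only that patient's prior visits, restricted to visits inside the
#' trailing window of observed days.  For diagnosed patients, predictions
#' stop at the first positive visit and the diagnosis indicators are
#' removed from the history (the reduced model never sees them).
#'
#' @param cohort [galad_cohort()].
#' @param priors [predictive_prior_spec()].
#' @param config [predict_config()]; each refit derives its own seed from
#'   `config$seed` and the (patient, visit) position, so edits to later
#'   visits can never change an earlier prediction.
#' @param window_days trailing window (default 1500 days; `Inf` scores every
#'   visit).
#' @return data.frame with columns `patient_id`, `visit`, `time_days`,
#'   `p_hcc`, `n_draws`.
#' @export
predict_cohort <- function(cohort, priors = default_predictive_priors(),
                           config = predict_config(), window_days = 1500) {
  stopifnot(inherits(cohort, "galad_cohort"))
  out <- list()
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    d1 <- first_diag_index(r)
    j_max <- if (is.na(d1)) length(r$times) else d1
    lastT <- r$times[j_max]
    for (j in seq_len(j_max)) {
      if (r$times[j] < lastT - window_days) next
      hist <- patient_record(r$patient_id, r$times[seq_len(j)],
                             r$scores[seq_len(j)], rep(0L, j))
      cfg <- config
      cfg$seed <- (config$seed + 7919L * i + j) %% .Machine$integer.max
      pr <- predict_visit(hist, priors, cfg)
      out[[length(out) + 1L]] <-
        data.frame(patient_id = pr$patient_id, visit = pr$visit,
                   time_days = pr$time_days, p_hcc = pr$p_hcc,
                   n_draws = pr$n_draws)
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), visit = integer(),
                      time_days = numeric(), p_hcc = numeric(),
                      n_draws = integer()))
  do.call(rbind, out)
}

#' Exact-mode predictive probability for short histories (oracle)
#'
#' Computes the same posterior predictive probability as [predict_visit()]
#' without MCMC: onset configurations are enumerated, the onset day and the
#' baseline deviation are integrated by quadrature, and the parameter priors
#' are integrated by plain Monte Carlo importance weighting (prior draws,
#' weights proportional to the patient marginal likelihood).  Feasible only
#' for short histories; used as an independent cross-check of the sampler.
#'
#' @param history [patient_record()] with no positive diagnosis.
#' @param priors [predictive_prior_spec()].
#' @param n_theta number of prior parameter draws.
#' @param quad [marginal_quad_config()].
#' @param seed integer seed for the prior draws.
#' @return scalar probability.
#' @export
predict_visit_exact <- function(history, priors = default_predictive_priors(),
                                n_theta = 2000L,
                                quad = marginal_quad_config(), seed = 1L) {
  stopifnot(inherits(history, "patient_record"))
  if (any(history$diag == 1L))
    stop("prediction history must not contain a positive diagnosis", call. = FALSE)
  times <- history$times
  J <- length(times)
  if (J == 1L) return(0)
  set.seed(seed)
  # prior draws of (beta, sigma, sigma_b, nu, zeta, xi)
  beta_d <- numeric(n_theta)
  for (m in seq_len(n_theta)) {
    repeat { v <- rnorm(1L, priors$beta_mean, priors$beta_sd); if (v > 0) break }
    beta_d[m] <- v
  }
  sig_d <- rgamma(n_theta, priors$sigma_shape, priors$sigma_rate)
  sgb_d <- rgamma(n_theta, priors$sigma_b_shape, priors$sigma_b_rate)
  nzx_d <- t(priors$nzx_mean + priors$nzx_chol %*%
               matrix(rnorm(3L * n_theta), 3L, n_theta))
  gh <- pracma::gaussHermite(quad$gh_nodes)
  log_w <- log_onset <- numeric(n_theta)
  obs <- !is.na(history$scores)
  for (m in seq_len(n_theta)) {
    nu <- nzx_d[m, 1L]; zeta <- nzx_d[m, 2L]; xi <- nzx_d[m, 3L]
    ag <- agq_grid(gh, sgb_d[m], sig_d[m],
                   sum(history$scores[obs] - nu), sum(obs))
    b_nodes <- ag$b
    log_wb <- ag$logw
    tot <- on <- numeric(length(b_nodes))
    for (g in seq_along(b_nodes)) {
      bb <- b_nodes[g]
      lam <- exp(zeta + xi * bb)
      terms <- -lam * times[J] +
        sum(dnorm(history$scores, nu + bb, sig_d[m], log = TRUE), na.rm = TRUE)
      on_terms <- -Inf
      for (k in seq_len(J - 1L)) {
        t0 <- times[k]; t1 <- times[k + 1L]
        gl <- pracma::gaussLegendre(quad$tau_nodes, t0, t1)
        lpath <- -lam * t0 + log1p(-exp(-lam * (t1 - t0)))
        ll_tau <- vapply(gl$x, function(tt) {
          mu <- nu + bb + beta_d[m] * pmax(times - tt, 0)
          sum(dnorm(history$scores, mu, sig_d[m], log = TRUE), na.rm = TRUE)
        }, numeric(1L))
        on_terms <- logsumexp(c(on_terms,
                                lpath + logsumexp(log(gl$w) + ll_tau) - log(t1 - t0)))
      }
      on[g] <- on_terms
      tot[g] <- logsumexp(c(terms, on_terms))
    }
    log_w[m] <- logsumexp(log_wb + tot)
    log_onset[m] <- logsumexp(log_wb + on)
  }
  exp(logsumexp(log_onset) - logsumexp(log_w))
}
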