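#' MCMC configuration
#'
#' Defaults follow the training-stage run lengths used for the reference
#' cohort fit (2 chains, 1000 adaptation iterations, 45,000 iterations with
#' the first 7500 discarded as burn-in).  [mcmc_config_fast()] is a reduced
#' preset suitable for tests and simulation studies.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_adapt adaptation iterations (proposal scales tuned, then frozen;
#'   adaptation draws are discarded).
#' @param n_iter post-adaptation iterations per chain.
#' @param n_burnin iterations (of `n_iter`) discarded by summaries.
#' @param thin storage stride.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param store_latents also store per-patient onset interval, onset day,
#'   responder flag and baseline deviation draws.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_adapt = 1000L, n_iter = 45000L,
                        n_burnin = 7500L, thin = 1L, seed = 1L,
                        store_latents = FALSE) {
  if (n_chains < 1L || n_adapt < 0L || n_iter < 1L || thin < 1L)
    stop("mcmc_config: counts must be positive", call. = FALSE)
  if (n_burnin >= n_iter)
    stop("mcmc_config: n_burnin must be smaller than n_iter", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 store_latents = isTRUE(store_latents)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... overrides passed to [mcmc_config()].
#' @export
mcmc_config_fast <- function(...) {
  args <- list(n_chains = 2L, n_adapt = 1000L, n_iter = 4000L,
               n_burnin = 1000L, thin = 1L)
  args[names(list(...))] <- list(...)
  do.call(mcmc_config, args)
}

# ---- internal padded-matrix cohort representation ------------------------

# Patients are conditionally independent given the parameters, so all
# per-patient quantities are computed as length-n vectors over an n x Jmax
# padded matrix layout; length-n vectors recycle down columns, i.e. row-wise.
cohort_matrices <- function(cohort) {
  recs <- cohort$records
  n <- length(recs)
  Jn <- vapply(recs, function(r) length(r$times), integer(1L))
  Jmax <- max(Jn)
  Tm <- Y <- matrix(NA_real_, n, Jmax)
  Dm <- matrix(NA_integer_, n, Jmax)
  for (i in seq_len(n)) {
    j <- seq_len(Jn[i])
    Tm[i, j] <- recs[[i]]$times
    Y[i, j] <- recs[[i]]$scores
    Dm[i, j] <- recs[[i]]$diag
  }
  d1 <- vapply(recs, first_diag_index, integer(1L))
  countMask <- matrix(FALSE, n, Jmax)
  for (i in seq_len(n))
    countMask[i, seq_len(if (is.na(d1[i])) Jn[i] else d1[i])] <- TRUE
  list(n = n, Jn = Jn, Jmax = Jmax, Tm = Tm, Y = Y, Dm = Dm,
       d1 = d1, lastT = Tm[cbind(seq_len(n), Jn)],
       countMask = countMask, Dpos = which(Dm == 1L),
       ids = vapply(recs, `[[`, character(1L), "patient_id"))
}

# Per-patient Gaussian score log-likelihood (length-n vector).
score_ll_pat <- function(M, beta, sigma, nu, tau, S, b) {
  MU <- nu + b + (beta * S) * pmax(M$Tm - tau, 0)
  rowSums(dnorm(M$Y, MU, sigma, log = TRUE), na.rm = TRUE)
}

# Per-patient latent-path log-probability given onset interval codes
# (NA = no onset, 0 = at first visit, k >= 1 = onset in (t_k, t_{k+1}]).
path_ll_pat <- function(M, lam, kvec) {
  ll <- -lam * M$lastT
  ll[M$lastT == 0] <- 0           # no elapsed time: survival probability 1
  at <- which(!is.na(kvec) & kvec == 0L)
  if (length(at)) ll[at] <- 0
  ii <- which(!is.na(kvec) & kvec >= 1L)
  if (length(ii)) {
    k <- kvec[ii]
    tk <- M$Tm[cbind(ii, k)]
    dtk <- M$Tm[cbind(ii, k + 1L)] - tk
    surv <- -lam[ii] * tk
    surv[tk == 0] <- 0            # avoids 0 * Inf when the hazard overflows
    ll[ii] <- surv + log1p(-exp(-lam[ii] * dtk))
  }
  ll
}

# Per-patient diagnosis log-likelihood.
diag_ll_pat <- function(M, delta, tau) {
  q <- -expm1(-delta * pmax(M$Tm - tau, 0))
  L <- log1p(-q)
  if (length(M$Dpos)) L[M$Dpos] <- log(q[M$Dpos])
  L[!M$countMask] <- 0
  rowSums(L)
}

# Robbins-Monro-style scale adaptation toward a target acceptance rate.
adapt_scale <- function(ls, rate, target = 0.3, step = 0.25) {
  min(max(ls + step * (rate - target), -15), 5)
}

#' Fit the surveillance model by data-augmentation MCMC
#'
#' Metropolis-within-Gibbs over the joint posterior of the eight model
#' parameters and the per-patient latent states.  Each sweep performs, for
#' every patient simultaneously: a joint onset-interval/onset-day proposal
#' restricted to intervals compatible with any observed diagnosis, an
#' onset-day refresh within the current interval, a closed-form Gibbs draw
#' of the responder flag, and a random-walk update of the baseline
#' deviation; followed by random-walk updates of the parameter blocks on
#' transformed scales (log for `beta`, `sigma`, `sigma_b`, `delta`; joint
#' bivariate update for the correlated `(zeta, xi)` pair) and a conjugate
#' Beta-Gibbs draw of `p_s`.  Proposal scales are tuned during the
#' adaptation phase and then frozen.
#'
#' @param cohort [galad_cohort()] (non-empty).
#' @param priors [prior_spec()].
#' @param config [mcmc_config()].
#' @param fixed optional named list of parameters to hold fixed at given
#'   values (their update blocks are skipped); mainly for conditional-
#'   distribution checks.
#' @return object of class `posterior_draws`: per-chain matrices of stored
#'   parameter draws, optional latent draws, per-block acceptance rates, and
#'   the configuration used.
#' @export
fit_mcmc <- function(cohort, priors = default_prior_spec(),
                     config = mcmc_config_fast(), fixed = NULL) {
  stopifnot(inherits(cohort, "galad_cohort"), inherits(config, "mcmc_config"))
  if (!length(cohort$records)) stop("cohort must be non-empty", call. = FALSE)
  M <- cohort_matrices(cohort)
  bad <- which(M$d1 == 1L)
  if (length(bad))
    stop(sprintf("patient %s is diagnosed at the first visit (day 0): no latent onset configuration has positive likelihood",
                 M$ids[bad[1L]]), call. = FALSE)
  chains <- vector("list", config$n_chains)
  latents <- if (config$store_latents) vector("list", config$n_chains) else NULL
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    run <- run_chain(M, priors, config, fixed)
    chains[[ch]] <- run$draws
    accept[[ch]] <- run$accept
    if (config$store_latents) latents[[ch]] <- run$latents
  }
  structure(list(chains = chains, latents = latents, accept = accept,
                 config = config, priors = priors, param_names = PARAM_NAMES),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws: %d chains x %d stored draws (burn-in %d)>\n",
              length(x$chains), nrow(x$chains[[1L]]),
              ceiling(x$config$n_burnin / x$config$thin)))
  invisible(x)
}

# One chain of the full-model sampler.  Uses the global RNG stream.
run_chain <- function(M, priors, config, fixed = NULL) {
  n <- M$n
  th <- prior_midpoint(priors)
  if (!is.null(fixed)) th[names(fixed)] <- fixed
  upd <- setdiff(PARAM_NAMES, names(fixed))
  beta <- th$beta; sigma <- th$sigma; sigma_b <- th$sigma_b; nu <- th$nu
  zeta <- th$zeta; xi <- th$xi; delta <- th$delta; p_s <- th$p_s

  # latents: no onset unless a diagnosis forces one (onset mid-interval
  # before the first positive visit)
  kvec <- rep(NA_integer_, n)
  tau <- rep(Inf, n)
  diag_pat <- !is.na(M$d1)
  for (i in which(diag_pat)) {
    kvec[i] <- M$d1[i] - 1L
    tau[i] <- (M$Tm[i, kvec[i]] + M$Tm[i, kvec[i] + 1L]) / 2
  }
  S <- rep(1L, n)
  b <- rep(0, n)
  lam <- exp(zeta + xi * b)

  sll <- score_ll_pat(M, beta, sigma, nu, tau, S, b)
  pll <- path_ll_pat(M, lam, kvec)
  dll <- diag_ll_pat(M, delta, tau)
  if (!all(is.finite(c(sll, pll, dll)))) {
    i <- which(!is.finite(sll + pll + dll))[1L]
    stop(sprintf("initialization gives an impossible state for patient %s",
                 M$ids[i]), call. = FALSE)
  }

  # proposal log-scales and the (zeta, xi) proposal Cholesky factor
  ls <- c(b = log(0.5), beta = log(0.5), sigma = log(0.2), nu = log(0.5),
          shift = log(0.2), sigma_b = log(0.2), zetaxi = log(1),
          delta = log(0.5))
  Lzx <- diag(c(0.5, 0.2))
  acc <- win <- setNames(numeric(length(ls)), names(ls))
  acc_tot <- try_tot <- setNames(numeric(length(ls)), names(ls))
  zx_hist <- matrix(NA_real_, config$n_adapt, 2L)

  # allowed onset-move choices per patient: intervals 1..J-1 plus "none",
  # restricted to 1..(d1 - 1) when a diagnosis is observed
  m_allow <- ifelse(diag_pat, M$d1 - 1L, M$Jn)

  n_keep <- floor(config$n_iter / config$thin)
  draws <- matrix(NA_real_, n_keep, 8L, dimnames = list(NULL, PARAM_NAMES))
  lat_store <- if (config$store_latents)
    list(k = matrix(NA_integer_, n_keep, n), tau = matrix(NA_real_, n_keep, n),
         S = matrix(NA_integer_, n_keep, n), b = matrix(NA_real_, n_keep, n))
  else NULL

  total_iter <- config$n_adapt + config$n_iter
  adapt_block <- 25L
  for (iter in seq_len(total_iter)) {
    adapting <- iter <= config$n_adapt

    ## (a) joint onset-interval + onset-day move ---------------------------
    pick <- pmax(pmin(ceiling(runif(n) * m_allow), m_allow), 1L)
    k_prop <- ifelse(!diag_pat & pick == M$Jn, NA_integer_, pick)
    tau_prop <- rep(Inf, n)
    ii <- which(!is.na(k_prop))
    if (length(ii)) {
      t0 <- M$Tm[cbind(ii, k_prop[ii])]
      t1 <- M$Tm[cbind(ii, k_prop[ii] + 1L)]
      tau_prop[ii] <- t0 + runif(length(ii)) * (t1 - t0)
    }
    sll_p <- score_ll_pat(M, beta, sigma, nu, tau_prop, S, b)
    pll_p <- path_ll_pat(M, lam, k_prop)
    dll_p <- diag_ll_pat(M, delta, tau_prop)
    ok <- log(runif(n)) < (sll_p - sll) + (pll_p - pll) + (dll_p - dll)
    if (any(ok)) {
      kvec[ok] <- k_prop[ok]; tau[ok] <- tau_prop[ok]
      sll[ok] <- sll_p[ok]; pll[ok] <- pll_p[ok]; dll[ok] <- dll_p[ok]
    }

    ## (b) onset-day refresh within the current interval -------------------
    ii <- which(!is.na(kvec) & kvec >= 1L)
    if (length(ii)) {
      tau_p <- tau
      t0 <- M$Tm[cbind(ii, kvec[ii])]
      t1 <- M$Tm[cbind(ii, kvec[ii] + 1L)]
      tau_p[ii] <- t0 + runif(length(ii)) * (t1 - t0)
      sll_p <- score_ll_pat(M, beta, sigma, nu, tau_p, S, b)
      dll_p <- diag_ll_pat(M, delta, tau_p)
      ok <- log(runif(n)) < (sll_p - sll) + (dll_p - dll)
      ok[-ii] <- FALSE
      if (any(ok)) {
        tau[ok] <- tau_p[ok]; sll[ok] <- sll_p[ok]; dll[ok] <- dll_p[ok]
      }
    }

    ## (c) responder flag: closed-form Bernoulli full conditional ----------
    sll1 <- score_ll_pat(M, beta, sigma, nu, tau, 1L, b)
    sll0 <- score_ll_pat(M, beta, sigma, nu, tau, 0L, b)
    p1 <- 1 / (1 + exp(log1p(-p_s) - log(p_s) + sll0 - sll1))
    S <- rbinom(n, 1L, p1)
    sll <- ifelse(S == 1L, sll1, sll0)

    ## (d) baseline deviation: random-walk Metropolis ----------------------
    b_p <- b + rnorm(n) * exp(ls["b"])
    lam_p <- exp(zeta + xi * b_p)
    sll_p <- score_ll_pat(M, beta, sigma, nu, tau, S, b_p)
    pll_p <- path_ll_pat(M, lam_p, kvec)
    ok <- log(runif(n)) < (sll_p - sll) + (pll_p - pll) +
      dnorm(b_p, 0, sigma_b, log = TRUE) - dnorm(b, 0, sigma_b, log = TRUE)
    if (any(ok)) {
      b[ok] <- b_p[ok]; lam[ok] <- lam_p[ok]
      sll[ok] <- sll_p[ok]; pll[ok] <- pll_p[ok]
    }
    acc["b"] <- acc["b"] + mean(ok); win["b"] <- win["b"] + 1
    acc_tot["b"] <- acc_tot["b"] + mean(ok); try_tot["b"] <- try_tot["b"] + 1

    ## (e) parameter blocks -------------------------------------------------
    if ("beta" %in% upd) {
      # beta (log scale, U(0, h_beta) prior)
      beta_p <- beta * exp(rnorm(1L) * exp(ls["beta"]))
      try_tot["beta"] <- try_tot["beta"] + 1; win["beta"] <- win["beta"] + 1
      if (beta_p < priors$h_beta) {
        sll_p <- score_ll_pat(M, beta_p, sigma, nu, tau, S, b)
        if (log(runif(1L)) < sum(sll_p) - sum(sll) + log(beta_p) - log(beta)) {
          beta <- beta_p; sll <- sll_p
          acc["beta"] <- acc["beta"] + 1; acc_tot["beta"] <- acc_tot["beta"] + 1
        }
      }
    }
    if ("sigma" %in% upd) {
      # sigma (log scale, U(0, h_sigma) prior)
      sigma_p <- sigma * exp(rnorm(1L) * exp(ls["sigma"]))
      try_tot["sigma"] <- try_tot["sigma"] + 1; win["sigma"] <- win["sigma"] + 1
      if (sigma_p < priors$h_sigma) {
        sll_p <- score_ll_pat(M, beta, sigma_p, nu, tau, S, b)
        if (log(runif(1L)) < sum(sll_p) - sum(sll) + log(sigma_p) - log(sigma)) {
          sigma <- sigma_p; sll <- sll_p
          acc["sigma"] <- acc["sigma"] + 1; acc_tot["sigma"] <- acc_tot["sigma"] + 1
        }
      }
    }
    if ("nu" %in% upd) {
      # nu (natural scale, N(0, h_nu) prior with h_nu a variance)
      nu_p <- nu + rnorm(1L) * exp(ls["nu"])
      try_tot["nu"] <- try_tot["nu"] + 1; win["nu"] <- win["nu"] + 1
      sll_p <- score_ll_pat(M, beta, sigma, nu_p, tau, S, b)
      if (log(runif(1L)) < sum(sll_p) - sum(sll) +
          dnorm(nu_p, 0, sqrt(priors$h_nu), log = TRUE) -
          dnorm(nu, 0, sqrt(priors$h_nu), log = TRUE)) {
        nu <- nu_p; sll <- sll_p
        acc["nu"] <- acc["nu"] + 1; acc_tot["nu"] <- acc_tot["nu"] + 1
      }
    }
    if ("nu" %in% upd) {
      # joint recentering of (nu, b): nu + e with every b - e leaves all score
      # means invariant and decouples nu from the random-effect mean
      e <- rnorm(1L) * exp(ls["shift"])
      try_tot["shift"] <- try_tot["shift"] + 1; win["shift"] <- win["shift"] + 1
      b_p <- b - e
      lam_p <- exp(zeta + xi * b_p)
      pll_p <- path_ll_pat(M, lam_p, kvec)
      d <- sum(dnorm(b_p, 0, sigma_b, log = TRUE)) -
        sum(dnorm(b, 0, sigma_b, log = TRUE)) +
        sum(pll_p) - sum(pll) +
        dnorm(nu + e, 0, sqrt(priors$h_nu), log = TRUE) -
        dnorm(nu, 0, sqrt(priors$h_nu), log = TRUE)
      if (log(runif(1L)) < d) {
        nu <- nu + e; b <- b_p; lam <- lam_p; pll <- pll_p
        acc["shift"] <- acc["shift"] + 1; acc_tot["shift"] <- acc_tot["shift"] + 1
      }
    }
    if ("sigma_b" %in% upd) {
      # sigma_b (log scale; only the random-effect prior factor moves)
      sigma_b_p <- sigma_b * exp(rnorm(1L) * exp(ls["sigma_b"]))
      try_tot["sigma_b"] <- try_tot["sigma_b"] + 1; win["sigma_b"] <- win["sigma_b"] + 1
      if (sigma_b_p < priors$h_sigma_b) {
        d <- sum(dnorm(b, 0, sigma_b_p, log = TRUE)) -
          sum(dnorm(b, 0, sigma_b, log = TRUE)) +
          log(sigma_b_p) - log(sigma_b)
        if (log(runif(1L)) < d) {
          sigma_b <- sigma_b_p
          acc["sigma_b"] <- acc["sigma_b"] + 1; acc_tot["sigma_b"] <- acc_tot["sigma_b"] + 1
        }
      }
    }
    if ("zeta" %in% upd) {
      # (zeta, xi): joint bivariate random walk on the path factor
      zx_p <- c(zeta, xi) + as.vector(Lzx %*% rnorm(2L)) * exp(ls["zetaxi"])
      try_tot["zetaxi"] <- try_tot["zetaxi"] + 1; win["zetaxi"] <- win["zetaxi"] + 1
      if (zx_p[1L] > priors$h_zeta[1L] && zx_p[1L] < priors$h_zeta[2L] &&
          zx_p[2L] > priors$h_xi[1L] && zx_p[2L] < priors$h_xi[2L]) {
        lam_p <- exp(zx_p[1L] + zx_p[2L] * b)
        pll_p <- path_ll_pat(M, lam_p, kvec)
        if (log(runif(1L)) < sum(pll_p) - sum(pll)) {
          zeta <- zx_p[1L]; xi <- zx_p[2L]; lam <- lam_p; pll <- pll_p
          acc["zetaxi"] <- acc["zetaxi"] + 1; acc_tot["zetaxi"] <- acc_tot["zetaxi"] + 1
        }
      }
    }
    if ("delta" %in% upd) {
      # delta (log scale, U(0, h_delta) prior)
      delta_p <- delta * exp(rnorm(1L) * exp(ls["delta"]))
      try_tot["delta"] <- try_tot["delta"] + 1; win["delta"] <- win["delta"] + 1
      if (delta_p < priors$h_delta) {
        dll_p <- diag_ll_pat(M, delta_p, tau)
        if (log(runif(1L)) < sum(dll_p) - sum(dll) + log(delta_p) - log(delta)) {
          delta <- delta_p; dll <- dll_p
          acc["delta"] <- acc["delta"] + 1; acc_tot["delta"] <- acc_tot["delta"] + 1
        }
      }
    }
    # p_s: conjugate Beta-Gibbs given the responder flags
    if ("p_s" %in% upd)
      p_s <- rbeta(1L, priors$h_s[1L] + sum(S), priors$h_s[2L] + n - sum(S))

    ## adaptation ----------------------------------------------------------
    if (adapting) {
      zx_hist[iter, ] <- c(zeta, xi)
      if (iter %% adapt_block == 0L) {
        for (nm in names(ls)) {
          if (win[nm] > 0) ls[nm] <- adapt_scale(ls[nm], acc[nm] / win[nm])
          acc[nm] <- 0; win[nm] <- 0
        }
        if (iter >= 200L) {
          cv <- stats::cov(zx_hist[max(1L, iter - 500L):iter, , drop = FALSE])
          cv <- cv + diag(1e-8, 2L)
          Lzx_try <- tryCatch(t(chol(cv)), error = function(e) NULL)
          if (!is.null(Lzx_try)) Lzx <- Lzx_try
        }
      }
    } else {
      it2 <- iter - config$n_adapt
      if (it2 %% config$thin == 0L) {
        row <- it2 %/% config$thin
        draws[row, ] <- c(beta, sigma, sigma_b, nu, zeta, xi, delta, p_s)
        if (!is.null(lat_store)) {
          lat_store$k[row, ] <- kvec; lat_store$tau[row, ] <- tau
          lat_store$S[row, ] <- S; lat_store$b[row, ] <- b
        }
      }
    }
  }
  list(draws = draws, latents = lat_store,
       accept = ifelse(try_tot > 0, acc_tot / try_tot, NA_real_))
}
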