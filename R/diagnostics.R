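# Post-burn-in draw matrices, one per chain.
chain_matrices <- function(draws, discard_burnin = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  drop_n <- if (discard_burnin) ceiling(draws$config$n_burnin / draws$config$thin) else 0L
  if (drop_n == 0L) return(draws$chains)
  lapply(draws$chains, function(m) m[-seq_len(drop_n), , drop = FALSE])
}

#' Pooled post-burn-in draws
#'
#' @param draws [fit_mcmc()] output.
#' @param discard_burnin drop the burn-in rows of each chain first.
#' @return matrix with one column per parameter.
#' @export
pooled_draws <- function(draws, discard_burnin = TRUE) {
  do.call(rbind, chain_matrices(draws, discard_burnin))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non rank-normalized) PSRF per parameter, computed from the
#' post-burn-in portion of at least two chains.  Values that fall below 1
#' through finite-sample noise are truncated to 1, so identical chains
#' report exactly 1.
#'
#' @param draws [fit_mcmc()] output with `n_chains >= 2`.
#' @return named vector of PSRF values.
#' @export
gelman_rubin <- function(draws) {
  cm <- chain_matrices(draws)
  m <- length(cm)
  if (m < 2L)
    stop("gelman_rubin needs at least 2 chains; rerun with n_chains >= 2 or use a split-chain variant",
         call. = FALSE)
  n <- nrow(cm[[1L]])
  vapply(seq_len(ncol(cm[[1L]])), function(p) {
    means <- vapply(cm, function(x) mean(x[, p]), numeric(1L))
    vars <- vapply(cm, function(x) var(x[, p]), numeric(1L))
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) return(1)
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  }, numeric(1L)) |> setNames(colnames(cm[[1L]]))
}

#' Posterior summary table
#'
#' Mean and 0.05/0.95 quantiles per parameter, chains pooled after burn-in
#' removal, in the canonical column order `beta, sigma, sigma_b, nu, zeta,
#' xi, delta, p_s`.
#'
#' @param draws [fit_mcmc()] output.
#' @return data.frame with columns `parameter`, `mean`, `q05`, `q95`.
#' @export
summarize_posterior <- function(draws) {
  x <- pooled_draws(draws)
  if (!nrow(x)) stop("no stored draws to summarize", call. = FALSE)
  data.frame(parameter = colnames(x),
             mean = colMeans(x),
             q05 = apply(x, 2L, quantile, probs = 0.05, names = FALSE),
             q95 = apply(x, 2L, quantile, probs = 0.95, names = FALSE),
             row.names = NULL)
}

#' Moment-matched informative priors from posterior draws
#'
#' Approximates the training-stage posterior for use as informative priors
#' in prospective prediction: gamma laws for `sigma` and `sigma_b`
#' (shape/rate from the posterior mean and variance), a normal law for
#' `beta`, and a trivariate normal with the empirical mean vector and
#' covariance for `(nu, zeta, xi)`.  A goodness report (maximum absolute
#' quantile deviation per approximated margin over the 5%..95% grid) is
#' attached as the `qq` attribute.
#'
#' @param draws [fit_mcmc()] output.
#' @return a [predictive_prior_spec()].
#' @export
approximate_posterior_as_priors <- function(draws) {
  x <- pooled_draws(draws)
  if (!nrow(x)) stop("no stored draws", call. = FALSE)
  mom <- function(v, nm) {
    m <- mean(v); s2 <- var(v)
    if (!is.finite(s2) || s2 <= 0)
      stop(sprintf("draws for %s are degenerate (zero variance)", nm), call. = FALSE)
    c(mean = m, var = s2)
  }
  gam <- function(v, nm) {
    mv <- mom(v, nm)
    c(shape = unname(mv["mean"]^2 / mv["var"]),
      rate = unname(mv["mean"] / mv["var"]))
  }
  g_s <- gam(x[, "sigma"], "sigma")
  g_sb <- gam(x[, "sigma_b"], "sigma_b")
  mb <- mom(x[, "beta"], "beta")
  nzx <- x[, c("nu", "zeta", "xi")]
  spec <- predictive_prior_spec(
    beta_mean = unname(mb["mean"]), beta_sd = sqrt(unname(mb["var"])),
    sigma_shape = g_s["shape"], sigma_rate = g_s["rate"],
    sigma_b_shape = g_sb["shape"], sigma_b_rate = g_sb["rate"],
    nzx_mean = colMeans(nzx), nzx_cov = cov(nzx), cov_is_precision = FALSE)
  p <- seq(0.05, 0.95, by = 0.05)
  qq <- c(
    sigma = max(abs(quantile(x[, "sigma"], p, names = FALSE) -
                      qgamma(p, g_s["shape"], g_s["rate"]))),
    sigma_b = max(abs(quantile(x[, "sigma_b"], p, names = FALSE) -
                        qgamma(p, g_sb["shape"], g_sb["rate"]))),
    beta = max(abs(quantile(x[, "beta"], p, names = FALSE) -
                     qnorm(p, mb["mean"], sqrt(mb["var"])))))
  attr(spec, "qq") <- qq
  spec
}
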