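#' Model parameters
#'
#' The eight parameters of the surveillance model: post-onset slope `beta`
#' (score units/day, > 0), within-patient score SD `sigma`, between-patient
#' baseline SD `sigma_b`, population mean baseline `nu`, log-hazard intercept
#' `zeta` and baseline coefficient `xi` for the onset hazard
#' `lambda = exp(zeta + xi * b)`, diagnosis hazard `delta` (per day, > 0) and
#' responder probability `p_s`.
#'
#' @param beta,sigma,sigma_b,nu,zeta,xi,delta,p_s scalar values, see above.
#' @return a named object of class `model_parameters`.
#' @export
model_parameters <- function(beta, sigma, sigma_b, nu, zeta, xi, delta, p_s) {
  th <- c(beta = beta, sigma = sigma, sigma_b = sigma_b, nu = nu,
          zeta = zeta, xi = xi, delta = delta, p_s = p_s)
  if (anyNA(th) || any(!is.finite(th)))
    stop("all parameters must be finite", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (sigma_b <= 0) stop("sigma_b must be > 0", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (p_s < 0 || p_s > 1) stop("p_s must lie in [0, 1]", call. = FALSE)
  structure(as.list(th), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  print(unlist(x[PARAM_NAMES]))
  invisible(x)
}

#' Default parameter values for a hepatocellular-carcinoma surveillance cohort
#'
#' Posterior-mean parameter values from fitting the model to a large Japanese
#' hospital cohort of cirrhosis patients under GALAD-score surveillance.
#' These are the package's reference operating point: the synthetic-cohort
#' simulator uses them as its default generating values, and the derived
#' hazard/probability report evaluates its closed forms at them.
#'
#' @return a [model_parameters()] object.
#' @export
#' @examples
#' th <- default_parameters()
#' hazard_rate(th$zeta, th$xi, b = 0)   # onset hazard at an average baseline
default_parameters <- function() {
  model_parameters(beta = 0.00604, sigma = 0.460, sigma_b = 1.805,
                   nu = -3.218, zeta = -10.123, xi = 0.445,
                   delta = 0.000312, p_s = 0.656)
}

#' Prior specification for the model hyperparameters
#'
#' Families are fixed by the model: uniforms on `beta`, `sigma`, `sigma_b`,
#' `delta` (lower bound 0), uniforms on `zeta` and `xi` with both bounds
#' free, a zero-mean normal on `nu` parameterized by its *variance* `h_nu`,
#' and a Beta on `p_s`.  The defaults are the vague choices used for
#' training-stage inference.
#'
#' @param h_beta,h_sigma,h_sigma_b,h_delta upper uniform bounds (> 0).
#' @param h_nu prior variance of `nu` (> 0).  Note: variance, not SD and not
#'   a precision.
#' @param h_zeta,h_xi length-2 (lower, upper) uniform bounds.
#' @param h_s length-2 positive Beta shape parameters for `p_s`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(h_beta = 0.1, h_sigma = 100, h_sigma_b = 100,
                       h_nu = 1000, h_zeta = c(-60, 0), h_xi = c(-1, 5),
                       h_delta = 0.15, h_s = c(0.5, 0.5)) {
  for (nm in c("h_beta", "h_sigma", "h_sigma_b", "h_nu", "h_delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("prior_spec: %s must be a positive scalar", nm), call. = FALSE)
  }
  for (nm in c("h_zeta", "h_xi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[1L] >= v[2L])
      stop(sprintf("prior_spec: %s must be ordered (lower, upper) bounds", nm),
           call. = FALSE)
  }
  if (!is.numeric(h_s) || length(h_s) != 2L || any(h_s <= 0))
    stop("prior_spec: h_s must be two positive Beta shapes", call. = FALSE)
  structure(list(h_beta = h_beta, h_sigma = h_sigma, h_sigma_b = h_sigma_b,
                 h_nu = h_nu, h_zeta = h_zeta, h_xi = h_xi,
                 h_delta = h_delta, h_s = h_s),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
default_prior_spec <- function() prior_spec()

# Midpoints of the prior, used for sampler initialization.
prior_midpoint <- function(ps) {
  model_parameters(beta = ps$h_beta / 2, sigma = ps$h_sigma / 2,
                   sigma_b = ps$h_sigma_b / 2, nu = 0,
                   zeta = mean(ps$h_zeta), xi = mean(ps$h_xi),
                   delta = ps$h_delta / 2,
                   p_s = ps$h_s[1L] / sum(ps$h_s))
}
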