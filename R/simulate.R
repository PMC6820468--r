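#' Visit-schedule specification for the synthetic cohort
#'
#' Emulates an irregular hospital surveillance schedule: inter-visit gaps
#' are gamma-distributed with a given mean (days) and coefficient of
#' variation, truncated at the end of follow-up.  The defaults reproduce the
#' structure of a real 5-year screening cohort: roughly 15 visits per
#' patient over about 5 years, with about a quarter of visits missing a
#' complete biomarker score.
#'
#' @param n_patients number of patients.
#' @param followup_days total follow-up span in days.
#' @param mean_intervisit mean gap between visits in days.
#' @param intervisit_dispersion coefficient of variation of the gaps
#'   (0 gives an equally spaced grid).
#' @param p_missing_score probability that a visit's score is missing.
#' @return object of class `schedule_spec`.
#' @export
schedule_spec <- function(n_patients = 100L, followup_days = 1825,
                          mean_intervisit = 120, intervisit_dispersion = 0.4,
                          p_missing_score = 0.25) {
  if (n_patients < 0L) stop("n_patients must be non-negative", call. = FALSE)
  if (followup_days <= 0 || mean_intervisit <= 0)
    stop("followup_days and mean_intervisit must be positive", call. = FALSE)
  if (intervisit_dispersion < 0)
    stop("intervisit_dispersion must be non-negative", call. = FALSE)
  if (p_missing_score < 0 || p_missing_score >= 1)
    stop("p_missing_score must lie in [0, 1)", call. = FALSE)
  if (followup_days < mean_intervisit)
    stop("follow-up shorter than one mean inter-visit gap", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 followup_days = followup_days,
                 mean_intervisit = mean_intervisit,
                 intervisit_dispersion = intervisit_dispersion,
                 p_missing_score = p_missing_score),
            class = "schedule_spec")
}

#' Draw one visit schedule
#'
#' Visit times start at day 0; gaps are gamma with the spec's mean and
#' coefficient of variation, and the schedule is truncated at the end of
#' follow-up.  Always returns at least two visits.
#'
#' @param spec [schedule_spec()].
#' @return numeric vector of visit times in days.
#' @export
make_schedule <- function(spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  cv <- spec$intervisit_dispersion
  n_draw <- ceiling(3 * spec$followup_days / spec$mean_intervisit) + 10L
  repeat {
    gaps <- if (cv < 1e-12) rep(spec$mean_intervisit, n_draw)
            else rgamma(n_draw, shape = 1 / cv^2,
                        scale = spec$mean_intervisit * cv^2)
    times <- c(0, cumsum(gaps))
    times <- times[times <= spec$followup_days]
    if (length(times) >= 2L) return(times)
  }
}

#' Simulate one patient from the generative model
#'
#' Draws the baseline deviation, responder flag and a continuous-time onset
#' day (exponential waiting time with the log-linear hazard, started at the
#' first visit), then the Gaussian scores around the change-point mean
#' trajectory and the lagging diagnosis indicators.  Visits after the first
#' positive diagnosis are dropped by default, mirroring how surveillance
#' databases censor post-diagnosis follow-up.
#'
#' @param theta [model_parameters()].
#' @param spec [schedule_spec()].
#' @param times optional fixed visit times (otherwise drawn via
#'   [make_schedule()]).
#' @param keep_post_diagnosis keep visits after the first positive diagnosis
#'   (the diagnosis indicator then stays 1, absorbing).
#' @return list with elements `record` ([patient_record()]) and `truth`
#'   ([latent_state()]).
#' @export
simulate_patient <- function(theta, spec, times = NULL,
                             keep_post_diagnosis = FALSE) {
  stopifnot(inherits(theta, "model_parameters"))
  if (is.null(times)) times <- make_schedule(spec)
  b <- rnorm(1L, 0, theta$sigma_b)
  s <- rbinom(1L, 1L, theta$p_s)
  lam <- hazard_rate(theta$zeta, theta$xi, b)
  tau <- rexp(1L, lam)

  mu <- mean_trajectory(theta$nu, b, s, tau, theta$beta, times)
  scores <- rnorm(length(times), mu, theta$sigma)
  scores[runif(length(times)) < spec$p_missing_score] <- NA_real_

  on <- tau < times
  q <- ifelse(on, -expm1(-theta$delta * pmax(times - tau, 0)), 0)
  diag <- as.integer(runif(length(times)) < q)
  if (any(diag == 1L)) {
    d1 <- which(diag == 1L)[1L]
    if (keep_post_diagnosis) {
      diag[d1:length(diag)] <- 1L
    } else {
      keep <- seq_len(d1)
      times <- times[keep]; scores <- scores[keep]; diag <- diag[keep]
    }
  }

  J <- length(times)
  if (tau >= times[J]) {
    k <- NA_integer_; tau_rec <- Inf
  } else {
    k <- max(which(times < tau))  # tau in (t_k, t_{k+1}]; ties have measure 0
    tau_rec <- tau
  }
  list(record = patient_record("tmp", times, scores, diag),
       truth = latent_state(k, tau_rec, s, b, times))
}

#' Simulate a surveillance cohort
#'
#' Vectorized [simulate_patient()] with reproducible seeding; the generating
#' parameters and seed are recorded in the returned cohort so that the
#' simulation truth travels with the data.
#'
#' @param theta [model_parameters()]; defaults to the reference cohort
#'   operating point [default_parameters()].
#' @param spec [schedule_spec()].
#' @param seed optional integer seed.
#' @param keep_post_diagnosis passed to [simulate_patient()].
#' @return a [galad_cohort()] with `truth`, `theta_true` and `seed` filled in.
#' @export
#' @examples
#' coh <- simulate_cohort(spec = schedule_spec(n_patients = 20), seed = 1)
#' coh
simulate_cohort <- function(theta = default_parameters(),
                            spec = schedule_spec(), seed = NULL,
                            keep_post_diagnosis = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_patients
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_patient(theta, spec, keep_post_diagnosis = keep_post_diagnosis)
    sim$record$patient_id <- sprintf("P%04d", i)
    records[[i]] <- sim$record
    truth[[i]] <- sim$truth
  }
  galad_cohort(records, truth = truth, theta_true = theta, seed = seed)
}

#' Stratified train/test split of a cohort
#'
#' Patient-level split stratified by ever-diagnosed status, with the test
#' share rounded half up within each stratum.  Truth (when present) follows
#' the records.
#'
#' @param cohort [galad_cohort()].
#' @param test_fraction fraction of patients assigned to the test set.
#' @param seed optional integer seed.
#' @return list with `train` and `test` cohorts.
#' @export
split_train_test <- function(cohort, test_fraction = 0.25, seed = NULL) {
  stopifnot(inherits(cohort, "galad_cohort"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  diagnosed <- vapply(cohort$records, function(r) any(r$diag == 1L), logical(1L))
  test_idx <- integer(0L)
  for (stratum in list(which(diagnosed), which(!diagnosed))) {
    if (!length(stratum)) next
    if (length(stratum) < 2L)
      warning("a diagnosis stratum has fewer than 2 patients", call. = FALSE)
    n_test <- floor(length(stratum) * test_fraction + 0.5)  # round half up
    if (n_test > 0L)
      test_idx <- c(test_idx, sample(stratum, n_test))
  }
  subset_cohort <- function(idx) {
    galad_cohort(cohort$records[idx],
                 truth = if (is.null(cohort$truth)) NULL else cohort$truth[idx],
                 theta_true = cohort$theta_true, seed = cohort$seed)
  }
  list(train = subset_cohort(setdiff(seq_along(cohort$records), test_idx)),
       test = subset_cohort(sort(test_idx)))
}
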