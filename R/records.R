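#' Longitudinal surveillance record for one patient
#'
#' Bundles the visit times (days since the first screening visit), the
#' biomarker score at each visit (possibly missing), and the binary clinical
#' diagnosis indicator at each visit.  Diagnosis is absorbing: once a patient
#' is diagnosed the indicator stays 1, and in the canonical cleaned data all
#' visits after the first positive one are dropped.
#'
#' @param patient_id scalar identifier (coerced to character).
#' @param times numeric vector of day offsets; strictly increasing and
#'   starting at 0.
#' @param scores numeric vector of biomarker scores, `NA` for missing.
#' @param diag integer/logical vector of diagnosis indicators, monotone
#'   non-decreasing.  A visit may carry `diag == 1` with a missing score
#'   (a diagnosis-date record).
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, times, scores, diag) {
  times <- as.numeric(times)
  scores <- as.numeric(scores)
  diag <- as.integer(diag)
  if (length(times) != length(scores) || length(times) != length(diag))
    stop("times, scores and diag must have equal length", call. = FALSE)
  if (length(times) < 1L) stop("a record needs at least one visit", call. = FALSE)
  if (anyNA(times)) stop("visit times must not be missing", call. = FALSE)
  if (times[1L] != 0)
    stop(sprintf("patient %s: first visit time must be 0", patient_id), call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop(sprintf("patient %s: visit times must be strictly increasing", patient_id),
         call. = FALSE)
  if (anyNA(diag) || any(diag < 0L | diag > 1L))
    stop(sprintf("patient %s: diag must be 0/1", patient_id), call. = FALSE)
  if (length(diag) > 1L && any(diff(diag) < 0L))
    stop(sprintf("patient %s: diagnosis indicator must be monotone (absorbing)",
                 patient_id), call. = FALSE)
  structure(list(patient_id = as.character(patient_id)[1L],
                 times = times, scores = scores, diag = diag),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d visits over %.0f days, %s>\n",
              x$patient_id, length(x$times), max(x$times),
              if (any(x$diag == 1L)) "diagnosed" else "not diagnosed"))
  invisible(x)
}

#' Latent disease state for one patient
#'
#' The tumour-presence path is reparameterized as an onset interval plus an
#' exact onset day `tau`.  `onset_interval = k` means onset in
#' `(times[k], times[k+1]]`; `NA` means no onset by the last visit
#' (`tau = Inf`); `0` means tumour already present at the first visit
#' (`tau = 0`, a point-mass convention).  The per-visit indicator path is
#' derived as `c_j = I(tau < t_j)`.
#'
#' @param onset_interval integer index `k`, `NA` (none) or `0` (at first visit).
#' @param tau onset day offset; `Inf` when there is no onset.
#' @param s_flag responder indicator (1 = biomarker trend responds to onset).
#' @param b_effect patient baseline deviation from the population mean score.
#' @param times the patient's visit times (used to validate consistency and
#'   derive the path).
#' @return object of class `latent_state` with a derived `c_path` element.
#' @export
latent_state <- function(onset_interval, tau, s_flag, b_effect, times) {
  J <- length(times)
  if (is.na(onset_interval)) {
    if (is.finite(tau) && tau < times[J])
      stop("onset_interval NA (none) requires tau >= last visit time", call. = FALSE)
    tau <- Inf
  } else if (onset_interval == 0L) {
    if (!isTRUE(tau == 0)) stop("AT_FIRST convention requires tau == 0", call. = FALSE)
  } else {
    k <- as.integer(onset_interval)
    if (k < 1L || k >= J) stop("onset_interval out of range", call. = FALSE)
    if (!(tau > times[k] && tau < times[k + 1L]))
      stop("tau must lie inside the open onset interval", call. = FALSE)
  }
  c_path <- as.integer(tau < times)
  if (!is.na(onset_interval) && onset_interval == 0L) c_path[1L] <- 1L
  structure(list(onset_interval = if (is.na(onset_interval)) NA_integer_
                                  else as.integer(onset_interval),
                 tau = tau, s_flag = as.integer(s_flag),
                 b_effect = as.numeric(b_effect), c_path = c_path),
            class = "latent_state")
}

#' Cohort of patient records
#'
#' A cohort holds a list of [patient_record()] objects, optionally paired
#' with the true latent states and generating parameters when the cohort is
#' simulated.
#'
#' @param records list of `patient_record`s.
#' @param truth optional list of [latent_state()]s aligned with `records`.
#' @param theta_true optional [model_parameters()] used to generate the data.
#' @param seed optional integer seed recorded for reproducibility.
#' @return object of class `galad_cohort`.
#' @export
galad_cohort <- function(records, truth = NULL, theta_true = NULL, seed = NULL) {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1L), "patient_record")
  if (length(records) && !all(ok)) stop("records must be patient_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1L), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort", call. = FALSE)
  if (!is.null(truth) && length(truth) != length(records))
    stop("truth must align with records", call. = FALSE)
  structure(list(records = records, truth = truth,
                 theta_true = theta_true, seed = seed),
            class = "galad_cohort")
}

#' @export
print.galad_cohort <- function(x, ...) {
  nd <- sum(vapply(x$records, function(r) any(r$diag == 1L), logical(1L)))
  cat(sprintf("<galad_cohort: %d patients (%d diagnosed), %d observations%s>\n",
              length(x$records), nd,
              sum(vapply(x$records, function(r) length(r$times), integer(1L))),
              if (is.null(x$truth)) "" else ", with simulation truth"))
  invisible(x)
}

#' @export
length.galad_cohort <- function(x) length(x$records)

#' @param row.names,optional unused, for generic consistency.
#' @param ... unused.
#' @rdname galad_cohort
#' @export
as.data.frame.galad_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!length(x$records))
    return(data.frame(patient_id = character(), time_days = numeric(),
                      score = numeric(), diag = integer()))
  do.call(rbind, lapply(x$records, function(r)
    data.frame(patient_id = r$patient_id, time_days = r$times,
               score = r$scores, diag = r$diag, row.names = NULL)))
}

# Rebuild a cohort from a long-format data frame (validates each record).
cohort_from_df <- function(df) {
  df <- df[order(df$patient_id, df$time_days), , drop = FALSE]
  recs <- lapply(split(df, df$patient_id, drop = TRUE), function(d)
    patient_record(d$patient_id[1L], d$time_days, d$score, d$diag))
  names(recs) <- NULL
  galad_cohort(recs)
}

# Visit index of the first positive diagnosis, or NA.
first_diag_index <- function(record) {
  w <- which(record$diag == 1L)
  if (length(w)) w[1L] else NA_integer_
}
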