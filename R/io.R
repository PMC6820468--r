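#' Read and write surveillance cohorts as long-format CSV
#'
#' The canonical on-disk dialect is one row per visit with a header
#' `patient_id,time_days,score,diag`; a missing score is an empty field.
#' Writing a simulated cohort also writes a JSON truth/manifest sidecar
#' (`<path>.truth.json`) holding the generating parameters, the seed and the
#' per-patient latent truth; [read_cohort()] restores it when present.
#' Round trips are lossless and row order is irrelevant: rows are sorted by
#' `(patient_id, time_days)` on read, and every record invariant is checked
#' with an error naming the offending patient and row.
#'
#' @param cohort [galad_cohort()].
#' @param path CSV file path.
#' @param truth_sidecar write/read the JSON sidecar when truth is available.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   [galad_cohort()].
#' @export
write_cohort <- function(cohort, path, truth_sidecar = TRUE) {
  stopifnot(inherits(cohort, "galad_cohort"))
  df <- as.data.frame(cohort)
  # 17 significant digits so doubles survive the text round trip exactly
  for (col in c("time_days", "score")) {
    v <- formatC(df[[col]], digits = 17, format = "g")
    v[is.na(df[[col]])] <- NA
    df[[col]] <- v
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  if (truth_sidecar && !is.null(cohort$truth)) {
    man <- list(
      seed = cohort$seed,
      theta_true = unclass(cohort$theta_true),
      patients = lapply(seq_along(cohort$records), function(i) {
        tr <- cohort$truth[[i]]
        list(patient_id = cohort$records[[i]]$patient_id,
             onset_interval = tr$onset_interval,
             tau = if (is.finite(tr$tau)) tr$tau else "Inf",
             s_flag = tr$s_flag, b_effect = tr$b_effect)
      }))
    jsonlite::write_json(man, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_sidecar = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, na.strings = "",
                 colClasses = c(patient_id = "character", time_days = "numeric",
                                score = "numeric", diag = "integer"))
  need <- c("patient_id", "time_days", "score", "diag")
  if (!all(need %in% names(df)))
    stop(sprintf("cohort CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df$.row <- seq_len(nrow(df))
  df <- df[order(df$patient_id, df$time_days), , drop = FALSE]
  dup <- duplicated(df[, c("patient_id", "time_days")])
  if (any(dup))
    stop(sprintf("duplicate (patient, time) at row %d (patient %s, day %g)",
                 df$.row[dup][1L], df$patient_id[dup][1L], df$time_days[dup][1L]),
         call. = FALSE)
  recs <- lapply(split(df, df$patient_id, drop = TRUE), function(d) {
    rec <- tryCatch(patient_record(d$patient_id[1L], d$time_days, d$score, d$diag),
                    error = function(e)
                      stop(sprintf("%s (rows %s)", conditionMessage(e),
                                   paste(range(d$.row), collapse = "-")),
                           call. = FALSE))
    rec
  })
  names(recs) <- NULL
  cohort <- galad_cohort(recs)
  sidecar <- paste0(path, ".truth.json")
  if (truth_sidecar && file.exists(sidecar)) {
    man <- jsonlite::read_json(sidecar)
    ids <- vapply(cohort$records, `[[`, character(1L), "patient_id")
    tr_ids <- vapply(man$patients, `[[`, character(1L), "patient_id")
    truth <- lapply(match(ids, tr_ids), function(j) {
      p <- man$patients[[j]]
      tau <- if (identical(p$tau, "Inf")) Inf else as.numeric(p$tau)
      k <- if (is.null(p$onset_interval)) NA_integer_ else as.integer(p$onset_interval)
      i <- match(p$patient_id, ids)
      latent_state(k, tau, p$s_flag, p$b_effect, cohort$records[[i]]$times)
    })
    theta <- if (!is.null(man$theta_true)) do.call(model_parameters, man$theta_true) else NULL
    cohort <- galad_cohort(cohort$records, truth = truth, theta_true = theta,
                           seed = if (is.null(man$seed)) NULL else as.integer(man$seed))
  }
  cohort
}

#' Derived hazard and probability report
#'
#' Applies the model's closed forms to a set of (posterior-mean) parameter
#' values: the onset hazard at baseline deviations of -2, 0 and +2 score
#' points; the corresponding 6-month (182.5-day) onset probabilities; the
#' probabilities of clinical diagnosis within a trimester (91.25 days), one
#' year (365 days) and three years (1095 days) of onset; and the 6-month
#' mean-score rise for a responder.
#'
#' @param params a [model_parameters()] object, a named numeric vector with
#'   the eight parameter names, or a [summarize_posterior()] table (the
#'   `mean` column is used).
#' @return data.frame with columns `quantity` and `value`.
#' @export
#' @examples
#' derived_quantities_report(default_parameters())
derived_quantities_report <- function(params) {
  if (is.data.frame(params)) {
    if (!all(c("parameter", "mean") %in% names(params)))
      stop("summary table must have 'parameter' and 'mean' columns", call. = FALSE)
    v <- setNames(params$mean, params$parameter)
  } else v <- unlist(params)
  missing_p <- setdiff(PARAM_NAMES, names(v))
  if (length(missing_p))
    stop(sprintf("missing parameter(s): %s", paste(missing_p, collapse = ", ")),
         call. = FALSE)
  half_year <- 182.5
  lam <- hazard_rate(v[["zeta"]], v[["xi"]], c(-2, 0, 2))
  onset6m <- -expm1(-lam * half_year)
  pdiag <- -expm1(-v[["delta"]] * c(91.25, 365, 1095))
  data.frame(
    quantity = c("hazard_b_minus2", "hazard_b0", "hazard_b_plus2",
                 "onset_6m_b_minus2", "onset_6m_b0", "onset_6m_b_plus2",
                 "diagnosis_3m", "diagnosis_1y", "diagnosis_3y",
                 "score_rise_6m"),
    value = c(lam, onset6m, pdiag, v[["beta"]] * half_year),
    row.names = NULL)
}
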