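#' Test-set exclusion window
#'
#' Drops, for never-diagnosed patients only, all visits within the trailing
#' window before their last visit (default two years).  This guards the
#' negative labels against tumours that were present but not yet diagnosed
#' at the end of follow-up.  Diagnosed patients are untouched.  Idempotent.
#'
#' @param cohort [galad_cohort()].
#' @param window_days trailing window in days.
#' @return filtered [galad_cohort()].
#' @export
apply_exclusion_window <- function(cohort, window_days = 730) {
  stopifnot(inherits(cohort, "galad_cohort"))
  # the window is anchored at each patient's last visit *before any
  # filtering*, so repeated application never drops further visits
  ref <- attr(cohort, "exclusion_ref")
  if (is.null(ref)) {
    ref <- vapply(cohort$records, function(r) max(r$times), numeric(1L))
    names(ref) <- vapply(cohort$records, `[[`, character(1L), "patient_id")
  }
  recs <- lapply(seq_along(cohort$records), function(i) {
    r <- cohort$records[[i]]
    if (any(r$diag == 1L) || window_days <= 0) return(r)
    keep <- r$times <= ref[[r$patient_id]] - window_days
    if (!any(keep)) keep[1L] <- TRUE  # never drop a patient entirely
    patient_record(r$patient_id, r$times[keep], r$scores[keep], r$diag[keep])
  })
  out <- galad_cohort(recs, truth = cohort$truth,
                      theta_true = cohort$theta_true, seed = cohort$seed)
  attr(out, "exclusion_ref") <- ref
  out
}

#' Declare detections from per-visit scores
#'
#' A detection is declared at every visit whose score (model probability or
#' raw biomarker value) reaches the cut-point; missing scores never trigger
#' a detection.
#'
#' @param scores data.frame with columns `patient_id`, `time_days` and a
#'   score column.
#' @param cutpoint scalar cut-point.
#' @param score_col name of the score column (defaults to `p_hcc` if
#'   present, else `score`).
#' @return data.frame of class `detection_series` with columns `patient_id`,
#'   `time_days`, `flag`, and the cut-point as attribute `cutpoint`.
#' @export
detect <- function(scores, cutpoint, score_col = NULL) {
  if (is.null(score_col))
    score_col <- if ("p_hcc" %in% names(scores)) "p_hcc" else "score"
  s <- scores[[score_col]]
  out <- data.frame(patient_id = scores$patient_id,
                    time_days = scores$time_days,
                    flag = !is.na(s) & s >= cutpoint)
  attr(out, "cutpoint") <- cutpoint
  class(out) <- c("detection_series", class(out))
  out
}

# Split cohort patients by ever-diagnosed status and collect diagnosis times.
cohort_labels <- function(cohort) {
  ids <- vapply(cohort$records, `[[`, character(1L), "patient_id")
  d1 <- vapply(cohort$records, first_diag_index, integer(1L))
  t_diag <- vapply(seq_along(cohort$records), function(i)
    if (is.na(d1[i])) NA_real_ else cohort$records[[i]]$times[d1[i]], numeric(1L))
  data.frame(patient_id = ids, diagnosed = !is.na(d1), t_diag = t_diag)
}

#' Longitudinal confusion metrics
#'
#' Sensitivity per patient (share of diagnosed patients with any detection
#' at or before their diagnosis visit), specificity per patient (share of
#' never-diagnosed patients with no detection at any scored visit) and
#' specificity per observation (share of non-detected observations among the
#' scored observations of never-diagnosed patients).  Detections at a
#' diagnosed patient's visits after diagnosis are ignored.  Empty
#' denominators yield `NA`.
#'
#' @param cohort [galad_cohort()].
#' @param detections output of [detect()] covering (a subset of) the
#'   cohort's visits.
#' @return named list with `sensitivity`, `specificity_patient`,
#'   `specificity_observation`.
#' @export
confusion_metrics <- function(cohort, detections) {
  lab <- cohort_labels(cohort)
  d <- merge(detections, lab, by = "patient_id")
  pos <- d[d$diagnosed & d$time_days <= d$t_diag, , drop = FALSE]
  neg <- d[!d$diagnosed, , drop = FALSE]
  pos_pat <- unique(pos$patient_id)
  neg_pat <- unique(neg$patient_id)
  sens <- if (!length(pos_pat)) NA_real_ else
    mean(vapply(pos_pat, function(p) any(pos$flag[pos$patient_id == p]), logical(1L)))
  spec_p <- if (!length(neg_pat)) NA_real_ else
    mean(vapply(neg_pat, function(p) !any(neg$flag[neg$patient_id == p]), logical(1L)))
  spec_o <- if (!nrow(neg)) NA_real_ else mean(!neg$flag)
  list(sensitivity = sens, specificity_patient = spec_p,
       specificity_observation = spec_o)
}

#' Timeliness of detection
#'
#' For each diagnosed patient, the earliest visit such that it and every
#' subsequent scored visit up to and including the diagnosis visit is
#' flagged; timeliness is the mean of (diagnosis time - that visit's time)
#' over patients for which such a visit exists.  Patients never consistently
#' detected through diagnosis are excluded from the mean; with no qualifying
#' patient the result is `NA`.
#'
#' @inheritParams confusion_metrics
#' @return mean days between consistent detection and clinical diagnosis.
#' @export
timeliness <- function(cohort, detections) {
  lab <- cohort_labels(cohort)
  lab <- lab[lab$diagnosed, , drop = FALSE]
  if (!nrow(lab)) return(NA_real_)
  vals <- numeric(0L)
  for (i in seq_len(nrow(lab))) {
    d <- detections[detections$patient_id == lab$patient_id[i] &
                      detections$time_days <= lab$t_diag[i], , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$time_days), , drop = FALSE]
    consistent <- rev(cumprod(rev(d$flag))) == 1  # flagged from here through diagnosis
    if (!d$flag[nrow(d)]) next                    # diagnosis visit itself not flagged
    vals <- c(vals, lab$t_diag[i] - min(d$time_days[consistent]))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# Low-level ROC from scalar scores and binary labels; cut-point grid is the
# sorted unique scores plus +/-Inf; a detection is score >= cutpoint.
roc_points <- function(score, label) {
  keep <- !is.na(score)
  score <- score[keep]; label <- as.logical(label[keep])
  grid <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  sens <- vapply(grid, function(ct) {
    if (!any(label)) NA_real_ else mean(score[label] >= ct)
  }, numeric(1L))
  spec <- vapply(grid, function(ct) {
    if (all(label)) NA_real_ else mean(score[!label] < ct)
  }, numeric(1L))
  data.frame(cutpoint = grid, sensitivity = sens, specificity = spec)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1L) + tail(tpr[o], -1L)) / 2)
}

#' ROC curve and area for a longitudinal detection rule
#'
#' Sweeps the cut-point over the observed score values.  Two kinds:
#' `"observation"` treats every scored observation of a never-diagnosed
#' patient as a negative unit and every scored observation of a diagnosed
#' patient at or before diagnosis as a positive unit; `"patient"` reduces
#' each patient to their maximum score (over visits at or before diagnosis
#' for cases) so both axes are per patient.  With all scores equal the curve
#' is the diagonal and the area 0.5.
#'
#' @param cohort [galad_cohort()].
#' @param scores data.frame of per-visit scores (see [detect()]).
#' @param specificity_kind `"observation"` or `"patient"`.
#' @param score_col score column name (default as in [detect()]).
#' @return list of class `roc_report`: `points` (cut-point grid with
#'   sensitivity and specificity), `auroc`, `kind`.
#' @export
roc_and_auroc <- function(cohort, scores,
                          specificity_kind = c("observation", "patient"),
                          score_col = NULL) {
  specificity_kind <- match.arg(specificity_kind)
  if (is.null(score_col))
    score_col <- if ("p_hcc" %in% names(scores)) "p_hcc" else "score"
  lab <- cohort_labels(cohort)
  d <- merge(scores, lab, by = "patient_id")
  d <- d[d$diagnosed & d$time_days <= d$t_diag | !d$diagnosed, , drop = FALSE]
  if (specificity_kind == "observation") {
    pts <- roc_points(d[[score_col]], d$diagnosed)
  } else {
    agg <- tapply(d[[score_col]], d$patient_id, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    lab2 <- lab$diagnosed[match(names(agg), lab$patient_id)]
    pts <- roc_points(as.numeric(agg), lab2)
  }
  auc <- trapezoid_auc(1 - pts$specificity, pts$sensitivity)
  structure(list(points = pts, auroc = auc, kind = specificity_kind),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report (%s): %d cut-points, AUROC = %.4f>\n",
              x$kind, nrow(x$points), x$auroc))
  invisible(x)
}

#' Cut-point maximizing sensitivity + per-patient specificity
#'
#' Argmax over the ROC grid of the sum of sensitivity and specificity; ties
#' are broken toward the larger cut-point (fewer detections).
#'
#' @param report a `"patient"`-kind [roc_and_auroc()] report.
#' @return scalar cut-point.
#' @export
best_cutpoint <- function(report) {
  pts <- report$points
  j <- pts$sensitivity + pts$specificity
  if (all(is.na(j))) stop("degenerate ROC report", call. = FALSE)
  cands <- which(j == max(j, na.rm = TRUE))
  max(pts$cutpoint[cands])
}

#' Full evaluation report at a cut-point
#'
#' Assembles the confusion metrics, timeliness and both ROC kinds for one
#' per-visit score series.
#'
#' @param cohort [galad_cohort()].
#' @param scores per-visit score data.frame.
#' @param cutpoint scalar cut-point for the operating-point metrics.
#' @param score_col score column name.
#' @return list of class `eval_report`.
#' @export
evaluate_detection <- function(cohort, scores, cutpoint, score_col = NULL) {
  det <- detect(scores, cutpoint, score_col)
  cm <- confusion_metrics(cohort, det)
  structure(list(cutpoint = cutpoint,
                 sensitivity = cm$sensitivity,
                 specificity_patient = cm$specificity_patient,
                 specificity_observation = cm$specificity_observation,
                 timeliness = timeliness(cohort, det),
                 roc_observation = roc_and_auroc(cohort, scores, "observation", score_col),
                 roc_patient = roc_and_auroc(cohort, scores, "patient", score_col)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report at cut-point %.3g>\n",
                     "  sensitivity (patient)        %.3f\n",
                     "  specificity (patient)        %.3f\n",
                     "  specificity (observation)    %.3f\n",
                     "  timeliness (days)            %.1f\n",
                     "  AUROC per observation        %.3f\n",
                     "  AUROC per patient            %.3f\n"),
              x$cutpoint, x$sensitivity, x$specificity_patient,
              x$specificity_observation, x$timeliness,
              x$roc_observation$auroc, x$roc_patient$auroc))
  invisible(x)
}
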