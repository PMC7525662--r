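#' Absorbed doses from residence times (MIRD schema)
#'
#' Computes `D_T = sum_S tau_S * S(T <- S)` for every target organ: an exact
#' matrix-vector product over labelled sources. The source vector is the
#' organ taus plus the remainder; every source must exist as a column of the
#' S-value matrix (the join is by label, never by position). The remainder
#' is treated as an ordinary source column; no internal mass-weighted
#' remainder correction is applied.
#'
#' @param rts A [residence_time_set()].
#' @param svalues An [svalue_matrix()] in mGy/(MBq h).
#' @return Named numeric vector of absorbed doses per target, mGy/MBq.
#' @export
absorbed_doses <- function(rts, svalues) {
  stopifnot(inherits(rts, "residence_time_set"),
            inherits(svalues, "svalue_matrix"))
  src <- c(rts$tau, remainder = rts$remainder)
  miss <- setdiff(names(src), colnames(svalues$S))
  if (length(miss))
    stop("source organ not in S-value matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  drop(svalues$S[, names(src), drop = FALSE] %*% src)[rownames(svalues$S)]
}

#' Effective dose from absorbed doses
#'
#' The tissue-weighted sum `E = sum_T w_T D_T`. For positron/photon
#' emitters the radiation weighting factor is 1, so organ mGy/MBq and
#' effective mSv/MBq coincide numerically.
#'
#' @param doses Named numeric vector of absorbed doses (mGy/MBq).
#' @param tissue_weights Named numeric vector of w_T summing to 1; every
#'   weighted organ must be present among the doses.
#' @return Effective dose, mSv/MBq.
#' @export
effective_dose <- function(doses, tissue_weights) {
  w <- tissue_weights
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("weights sum %.6g != 1", sum(w)), call. = FALSE)
  miss <- setdiff(names(w), names(doses))
  if (length(miss))
    stop("weight for unknown target: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sum(w * doses[names(w)])
}

#' Run one dosimetry model on a subject scan
#'
#' Composes the pipeline residence times -> (optional) organ-mass
#' normalisation -> absorbed doses -> effective dose, and labels the result
#' with the model descriptor (reconstruction method, normalised flag,
#' phantom). Eight such models arise per subject from the combinations of
#' reconstruction (FBP/iterative), normalisation (on/off) and phantom sex.
#'
#' @param scan A [subject_scan()].
#' @param svalues [svalue_matrix()] for the chosen phantom.
#' @param normalise Apply rat-to-human organ-mass normalisation?
#' @param rat_masses,human_masses [organ_mass_table()]s, required when
#'   `normalise = TRUE`.
#' @param decay A [decay_constants()].
#' @param anchor,remainder_tol Passed to [residence_times()].
#' @return Object of class `dose_report`: `absorbed` (named mGy/MBq),
#'   `effective` (mSv/MBq), `phantom`, `model` descriptor.
#' @export
run_dosimetry_model <- function(scan, svalues, normalise = FALSE,
                                rat_masses = NULL, human_masses = NULL,
                                decay = decay_constants(), anchor = TRUE,
                                remainder_tol = 0.02) {
  rts <- residence_times(scan, decay, anchor = anchor,
                         remainder_tol = remainder_tol)
  if (normalise) {
    if (is.null(rat_masses) || is.null(human_masses))
      stop("normalise = TRUE needs rat and human organ-mass tables",
           call. = FALSE)
    rts <- normalise_residence_times(rts, rat_masses, human_masses,
                                     remainder_tol = remainder_tol)
  }
  dose_report(rts, svalues)
}

#' Dose report from residence times and an S-value matrix
#'
#' @param rts A [residence_time_set()].
#' @param svalues An [svalue_matrix()].
#' @return Object of class `dose_report`.
#' @export
dose_report <- function(rts, svalues) {
  ab <- absorbed_doses(rts, svalues)
  eff <- effective_dose(ab, svalues$tissue_weights)
  structure(
    list(absorbed = ab, effective = eff, phantom = svalues$phantom,
         model = list(reconstruction = rts$reconstruction,
                      normalised = rts$normalised,
                      phantom = svalues$phantom)),
    class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>", model_label(x$model), "\n")
  print(round(x$absorbed, 6))
  cat("effective dose:", signif(x$effective, 6), "mSv/MBq\n")
  invisible(x)
}

model_label <- function(model) {
  paste(model$phantom,
        if (model$normalised) "normalised" else "non-normalised",
        model$reconstruction, sep = ", ")
}

#' Rank target organs by absorbed dose
#'
#' @param report A [dose_report()] or a named dose vector.
#' @param k Number of top organs to return.
#' @return Character vector of the k highest-dosed targets, ties broken
#'   lexicographically.
#' @export
rank_organs <- function(report, k = 3) {
  stopifnot(k >= 1)
  doses <- if (inherits(report, "dose_report")) report$absorbed else report
  ord <- order(-doses, names(doses), method = "radix")
  names(doses)[ord][seq_len(min(k, length(doses)))]
}

#' Write a dose report to CSV
#'
#' One row per target (`target,absorbed_mGy_per_MBq`) plus an
#' `effective_dose` row, with model-descriptor columns.
#'
#' @param report A [dose_report()].
#' @param path Output CSV path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(report, path, comment = NULL) {
  stopifnot(inherits(report, "dose_report"))
  df <- data.frame(
    target = c(names(report$absorbed), "effective_dose"),
    absorbed_mGy_per_MBq = fmt_num(c(report$absorbed, report$effective)),
    phantom = report$model$phantom,
    reconstruction = report$model$reconstruction,
    normalised = report$model$normalised)
  write_csv_commented(df, path, comment)
  invisible(path)
}
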