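#' Physical decay constants for the radionuclide
#'
#' Defaults to fluorine-18 (half-life 109.77 min). `lambda` is per minute.
#'
#' @param half_life_min Physical half-life in minutes.
#' @return Object of class `decay_constants` with fields `half_life`
#'   (minutes) and `lambda` (1/min).
#' @export
decay_constants <- function(half_life_min = 109.77) {
  stopifnot(is.numeric(half_life_min), length(half_life_min) == 1L)
  if (half_life_min <= 0) stop("half-life must be positive", call. = FALSE)
  structure(list(half_life = half_life_min, lambda = log(2) / half_life_min),
            class = "decay_constants")
}

#' Remove decay correction from a time-activity curve
#'
#' Converts decay-corrected activities back to physically decaying ones by
#' multiplying the activity at each frame midpoint t by exp(-lambda t). The
#' decay-only tail extrapolation is only meaningful on physically decaying
#' activity, so this runs (automatically, inside [residence_times()]) before
#' any integration of a decay-corrected curve.
#'
#' @param x A [tac()].
#' @param decay A [decay_constants()].
#' @return The `tac` with physical decay reinstated and
#'   `decay_corrected = FALSE`. If the curve is already uncorrected it is
#'   returned unchanged with a warning.
#' @export
uncorrect_decay <- function(x, decay = decay_constants()) {
  stopifnot(inherits(x, "tac"), inherits(decay, "decay_constants"))
  if (!x$decay_corrected) {
    warning("tac for ", x$organ, " is already non-decay-corrected; no-op")
    return(x)
  }
  mid <- frame_midpoints(x)
  x$frames$activity <- x$frames$activity * exp(-decay$lambda * mid)
  x$decay_corrected <- FALSE
  x
}

#' Trapezoidal area under a time-activity curve
#'
#' Integrates activity over time by the trapezoid rule. Activities in %ID and
#' times in minutes are converted so the area comes out in
#' fraction-of-injected-dose x hours, the natural unit for residence times.
#' For a `tac` the abscissae are the frame midpoints; an optional anchor
#' point can be prepended (see [residence_times()] for the default
#' anchoring policy).
#'
#' @param x Either a numeric vector of times in minutes (with `activity`
#'   supplied), or a [tac()].
#' @param ... Passed to methods.
#' @return Area in fraction x hours.
#' @export
trapezoid_auc <- function(x, ...) UseMethod("trapezoid_auc")

#' @rdname trapezoid_auc
#' @param activity Activities in %ID at the times `x` (default method).
#' @export
trapezoid_auc.default <- function(x, activity, ...) {
  t_min <- as.numeric(x)
  if (length(t_min) < 2L)
    stop("need at least 2 time points for trapezoidal integration",
         call. = FALSE)
  if (is.unsorted(t_min, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(activity < 0)) stop("negative activity", call. = FALSE)
  a <- activity / 100
  area_min <- sum((a[-1] + a[-length(a)]) / 2 * diff(t_min))
  minutes_to_hours(area_min)
}

#' @rdname trapezoid_auc
#' @param anchor Optional `c(time_min, activity_pct)` point prepended before
#'   integration, or `NULL` to integrate from the first frame midpoint.
#' @export
trapezoid_auc.tac <- function(x, anchor = NULL, ...) {
  t_min <- frame_midpoints(x)
  act <- x$frames$activity
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == 2L)
    t_min <- c(anchor[1], t_min)
    act <- c(anchor[2], act)
  }
  trapezoid_auc(t_min, act)
}

#' Residence time of the post-scan decay tail
#'
#' Beyond the last sample only physical decay is assumed, so the remaining
#' time-integrated activity is the integral of
#' `A_end * exp(-lambda (t - t_end))` from the last sample to infinity:
#' `A_end / lambda`, independent of where the scan ended.
#'
#' @param activity_end Activity at the last sample, %ID.
#' @param decay A [decay_constants()].
#' @return Tail residence time in hours.
#' @export
tail_residence <- function(activity_end, decay = decay_constants()) {
  if (any(activity_end < 0)) stop("negative activity", call. = FALSE)
  minutes_to_hours((activity_end / 100) / decay$lambda)
}

#' Physical upper bound on whole-body residence time
#'
#' A bolus that never leaves the body and only decays physically has
#' residence time 1/lambda; no physically valid non-decay-corrected
#' whole-body curve can integrate above it.
#'
#' @param decay A [decay_constants()].
#' @return Bound in hours (2.6394 h for fluorine-18).
#' @export
max_whole_body_tau <- function(decay = decay_constants()) {
  minutes_to_hours(1 / decay$lambda)
}

#' Residence times for a subject scan
#'
#' For every source organ, the whole body and the remainder, computes the
#' residence time tau (hours) as the trapezoidal area under the sampled
#' curve plus a physical-decay tail from the last frame midpoint
#' ([tail_residence()]). Decay-corrected input is converted by
#' [uncorrect_decay()] first (with a message). With `anchor = TRUE` a t = 0
#' point is prepended: organs start at 0 %ID, the whole body at 100 %ID,
#' reflecting the intravenous bolus. The remainder is whole-body tau minus
#' the summed organ taus; a small negative remainder (VOI overlap) is
#' clamped to zero, a large one is an error.
#'
#' @param scan A [subject_scan()].
#' @param decay A [decay_constants()].
#' @param anchor Prepend the t = 0 bolus anchor (default `TRUE`).
#' @param remainder_tol Clamp threshold: a remainder deficit below this
#'   fraction of whole-body tau is clamped to 0 with a warning (default
#'   0.02); beyond it, error.
#' @return Object of class `residence_time_set`: named `tau` vector (hours)
#'   per organ, `whole_body`, `remainder`, `reconstruction`, `normalised`.
#' @export
residence_times <- function(scan, decay = decay_constants(), anchor = TRUE,
                            remainder_tol = 0.02) {
  stopifnot(inherits(scan, "subject_scan"), inherits(decay, "decay_constants"))

  one_tau <- function(tc, anchor_point) {
    if (tc$decay_corrected) {
      message("uncorrecting physical decay for ", tc$organ)
      tc <- uncorrect_decay(tc, decay)
    }
    auc <- trapezoid_auc(tc, anchor = anchor_point)
    a_end <- tc$frames$activity[nrow(tc$frames)]
    auc + tail_residence(a_end, decay)
  }

  tau <- vapply(scan$tacs, one_tau,
                anchor_point = if (anchor) c(0, 0) else NULL,
                FUN.VALUE = numeric(1))
  wb <- one_tau(scan$whole_body, if (anchor) c(0, 100) else NULL)

  bound <- max_whole_body_tau(decay)
  if (wb > bound * 1.05)
    stop(sprintf(
      "whole-body tau %.4f h exceeds the physical-decay bound %.4f h",
      wb, bound), call. = FALSE)

  residence_time_set(tau, wb, reconstruction = scan$reconstruction,
                     normalised = FALSE, remainder_tol = remainder_tol)
}

#' Construct a residence-time set
#'
#' Usually produced by [residence_times()]; exposed so externally computed
#' taus can enter the dose engine. The remainder is derived as
#' `whole_body - sum(tau)` under the clamping rule.
#'
#' @param tau Named numeric vector of source-organ residence times (hours).
#' @param whole_body Whole-body residence time (hours).
#' @param reconstruction Reconstruction label (`"FBP"` or `"iterative"`).
#' @param normalised Logical: have organ-mass scaling factors been applied?
#' @param remainder_tol See [residence_times()].
#' @return Object of class `residence_time_set`.
#' @export
residence_time_set <- function(tau, whole_body,
                               reconstruction = c("FBP", "iterative"),
                               normalised = FALSE, remainder_tol = 0.02) {
  reconstruction <- match.arg(reconstruction)
  if (is.null(names(tau)) || any(names(tau) == ""))
    stop("tau must be a named vector", call. = FALSE)
  if (any(tau < 0) || whole_body < 0)
    stop("negative residence time", call. = FALSE)
  remainder <- whole_body - sum(tau)
  if (remainder < 0) {
    if (-remainder < remainder_tol * whole_body) {
      warning(sprintf(
        "source taus exceed whole-body tau by %.3g h (< %g%% of whole-body); remainder clamped to 0",
        -remainder, 100 * remainder_tol))
      remainder <- 0
    } else {
      stop(sprintf(
        "negative remainder: source taus exceed whole-body tau by %.3g h (> %g%% tolerance)",
        -remainder, 100 * remainder_tol), call. = FALSE)
    }
  }
  structure(list(tau = tau, whole_body = whole_body, remainder = remainder,
                 reconstruction = reconstruction,
                 normalised = isTRUE(normalised)),
            class = "residence_time_set")
}

#' @export
print.residence_time_set <- function(x, ...) {
  cat("<residence_time_set>", x$reconstruction,
      if (x$normalised) "(normalised)" else "(non-normalised)", "\n")
  out <- c(x$tau, remainder = x$remainder, whole_body = x$whole_body)
  print(round(out, 5))
  invisible(x)
}

#' Write residence times to CSV
#'
#' Columns `organ,tau_h,reconstruction,normalised`, with `remainder` and
#' `whole_body` as ordinary rows.
#'
#' @param rts A [residence_time_set()].
#' @param path Output CSV path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
write_residence_times <- function(rts, path, comment = NULL) {
  stopifnot(inherits(rts, "residence_time_set"))
  tau <- c(rts$tau, remainder = rts$remainder, whole_body = rts$whole_body)
  write_csv_commented(
    data.frame(organ = names(tau), tau_h = fmt_num(tau),
               reconstruction = rts$reconstruction,
               normalised = rts$normalised),
    path, comment)
  invisible(path)
}

#' Read residence times from CSV
#'
#' Inverse of [write_residence_times()].
#'
#' @param path CSV path.
#' @return A [residence_time_set()].
#' @export
read_residence_times <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("organ", "tau_h") %in% names(df)))
    stop("residence-time file must have columns organ,tau_h", call. = FALSE)
  wb <- df$tau_h[df$organ == "whole_body"]
  if (length(wb) != 1L)
    stop("residence-time file must have one whole_body row", call. = FALSE)
  src <- df[!df$organ %in% c("whole_body", "remainder"), ]
  residence_time_set(
    stats::setNames(src$tau_h, src$organ), wb,
    reconstruction = df$reconstruction[1],
    normalised = isTRUE(as.logical(df$normalised[1])))
}
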