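match_dose_pairs <- function(predicted, true) {
  if (!is.null(names(predicted)) && !is.null(names(true))) {
    common <- intersect(names(predicted), names(true))
    if (length(common) < length(predicted) || length(common) < length(true))
      warning("unmatched organ labels dropped: ",
              paste(union(setdiff(names(predicted), common),
                          setdiff(names(true), common)), collapse = ", "))
    list(predicted = predicted[common], true = true[common],
         organs = common)
  } else {
    if (length(predicted) != length(true))
      stop("unnamed dose vectors must have equal length", call. = FALSE)
    list(predicted = predicted, true = true,
         organs = names(predicted) %||% as.character(seq_along(predicted)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regression of predicted on true doses
#'
#' Ordinary least squares of predicted dose as a function of true dose,
#' pairs matched by organ label. The slope is the quantity of interest: its
#' standard error and 95% confidence interval come from the t distribution
#' with the residual degrees of freedom. An intercept is fitted by default
#' (only the slope feeds the bias summary); `through_origin = TRUE` forces
#' the line through zero.
#'
#' @param predicted,true Named numeric dose vectors (mGy/MBq), matched by
#'   organ label (or unnamed, paired positionally).
#' @param through_origin Fit without intercept?
#' @param level Confidence level (default 0.95).
#' @return Object of class `prediction_fit`: `slope`, `sem`, `r2`,
#'   `ci` (low, high), `intercept`, `n`, `df`, `through_origin`.
#' @export
fit_prediction_line <- function(predicted, true, through_origin = FALSE,
                                level = 0.95) {
  m <- match_dose_pairs(predicted, true)
  n <- length(m$true)
  if (n < 3L) stop("need at least 3 matched dose pairs", call. = FALSE)
  if (stats::var(m$true) == 0)
    stop("zero variance in true doses", call. = FALSE)
  d <- data.frame(pred = as.numeric(m$predicted), tru = as.numeric(m$true))
  fit <- if (through_origin) stats::lm(pred ~ 0 + tru, data = d)
         else stats::lm(pred ~ tru, data = d)
  ## exact fits (noiseless constructions) are legitimate inputs here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- unname(stats::coef(fit)["tru"])
  sem <- sm$coefficients["tru", "Std. Error"]
  dfree <- fit$df.residual
  tq <- stats::qt(1 - (1 - level) / 2, dfree)
  structure(
    list(slope = slope, sem = sem, r2 = sm$r.squared,
         ci = c(low = slope - tq * sem, high = slope + tq * sem),
         intercept = if (through_origin) 0
                     else unname(stats::coef(fit)["(Intercept)"]),
         n = n, df = dfree, through_origin = through_origin,
         organs = m$organs),
    class = "prediction_fit")
}

#' @export
print.prediction_fit <- function(x, ...) {
  cat(sprintf(
    "<prediction_fit> slope %.4f +/- %.4f (95%% CI %.4f, %.4f), r2 %.4f, n %d\n",
    x$slope, x$sem, x$ci["low"], x$ci["high"], x$r2, x$n))
  invisible(x)
}

#' Mean percentage bias of a dosimetry model
#'
#' The scalar summary of prediction error: the absolute value of 1 minus the
#' regression slope, times 100. A slope of 1 (line of identity) gives 0%;
#' over- and underestimation of the same relative magnitude give the same
#' bias.
#'
#' @param slope Regression slope (or a [fit_prediction_line()] object).
#' @return Bias in percent.
#' @export
mean_percent_bias <- function(slope) {
  if (inherits(slope, "prediction_fit")) slope <- slope$slope
  if (!all(is.finite(slope))) stop("non-finite slope", call. = FALSE)
  abs(1 - slope) * 100
}

#' Does the fitted slope differ from the line of identity?
#'
#' A model predicts without multiplicative bias when its slope is
#' statistically compatible with 1; the check is whether 1 lies inside the
#' slope's 95% confidence interval (inclusive bounds).
#'
#' @param slope Fitted slope (or a [fit_prediction_line()], in which case
#'   `ci` is taken from it).
#' @param ci Length-2 confidence interval (low, high).
#' @return `"differs"` or `"does not differ"`.
#' @export
identity_line_test <- function(slope, ci = NULL) {
  if (inherits(slope, "prediction_fit")) {
    ci <- slope$ci
    slope <- slope$slope
  }
  stopifnot(length(ci) == 2L, ci[1] <= ci[2])
  if (1 >= ci[1] && 1 <= ci[2]) "does not differ" else "differs"
}

#' Bias report for one dosimetry model
#'
#' Fits the prediction line and summarises it the way a model-comparison
#' table is laid out: r2, mean % bias, slope +/- SEM and its 95% CI.
#'
#' @param predicted,true Named dose vectors (mGy/MBq).
#' @param model Model descriptor list (`reconstruction`, `normalised`,
#'   `phantom`) or a label string.
#' @param lli_included Is the LLI wall pair part of the fit (bookkeeping
#'   flag for the sensitivity analysis)?
#' @param through_origin Passed to [fit_prediction_line()].
#' @return Object of class `bias_report`.
#' @export
bias_report <- function(predicted, true, model = "unlabelled",
                        lli_included = "LLI wall" %in% names(predicted),
                        through_origin = FALSE) {
  fit <- fit_prediction_line(predicted, true, through_origin)
  structure(
    list(model = model, r2 = fit$r2, slope = fit$slope, sem = fit$sem,
         ci = fit$ci, mean_percent_bias = mean_percent_bias(fit$slope),
         n = fit$n, lli_included = isTRUE(lli_included),
         identity = identity_line_test(fit)),
    class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  lab <- if (is.list(x$model)) model_label(x$model) else x$model
  cat(sprintf(
    "<bias_report> %s\n  r2 %.4f | bias %.2f%% | slope %.4f +/- %.4f | 95%% CI %.4f, %.4f | %s identity\n",
    lab, x$r2, x$mean_percent_bias, x$slope, x$sem,
    x$ci["low"], x$ci["high"], x$identity))
  invisible(x)
}

#' Bland-Altman agreement between predicted and true doses
#'
#' Pairwise differences (predicted - true) against pairwise means, with the
#' limits of agreement at mean difference +/- 1.96 SD.
#'
#' @param predicted,true Named dose vectors, matched by organ label.
#' @return Object of class `agreement_summary`: `mean_diff`, `sd_diff`,
#'   `loa` (lower, upper), `differences` and `means` per organ.
#' @export
bland_altman <- function(predicted, true) {
  m <- match_dose_pairs(predicted, true)
  if (length(m$true) < 2L)
    stop("need at least 2 matched pairs", call. = FALSE)
  d <- as.numeric(m$predicted) - as.numeric(m$true)
  mu <- (as.numeric(m$predicted) + as.numeric(m$true)) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(mean_diff = md, sd_diff = sdd,
         loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
         differences = stats::setNames(d, m$organs),
         means = stats::setNames(mu, m$organs)),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> mean diff %.4g, SD %.4g, LoA (%.4g, %.4g), n %d\n",
    x$mean_diff, x$sd_diff, x$loa[1], x$loa[2], length(x$differences)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x An [bland_altman()] summary.
#' @param ... Passed to [plot()].
#' @export
plot.agreement_summary <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of predicted and true dose (mGy/MBq)",
                 ylab = "Predicted - true dose (mGy/MBq)", ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Sensitivity of the bias fit to the LLI wall
#'
#' The lower large intestine wall is anatomically incomparable between rat
#' and human (rats lack a gallbladder and differ in gut layout), so its dose
#' pair can distort the prediction line. This refits with and without the
#' LLI pair; precision improvement is summarised as the ratio of mean
#' percent biases (with / without).
#'
#' @param predicted,true Named dose vectors including an LLI pair.
#' @param lli_label Label of the LLI pair (default `"LLI wall"`).
#' @param through_origin Passed to the fits.
#' @return List: `bias_with`, `bias_without`, `improvement_ratio`, plus the
#'   two `prediction_fit`s.
#' @export
lli_sensitivity <- function(predicted, true, lli_label = "LLI wall",
                            through_origin = FALSE) {
  if (!(lli_label %in% names(predicted)) || !(lli_label %in% names(true)))
    stop("LLI absent from dose pairs", call. = FALSE)
  fit_with <- fit_prediction_line(predicted, true, through_origin)
  keep <- setdiff(names(predicted), lli_label)
  if (length(keep) < 3L)
    stop("removing LLI leaves fewer than 3 pairs", call. = FALSE)
  fit_without <- fit_prediction_line(predicted[keep], true[keep],
                                     through_origin)
  bw <- mean_percent_bias(fit_with)
  bo <- mean_percent_bias(fit_without)
  list(bias_with = bw, bias_without = bo,
       improvement_ratio = bw / bo,
       fit_with = fit_with, fit_without = fit_without)
}

#' Pooled underestimation correction factor
#'
#' Pools the mean percent biases of normalised-FBP dosimetry models (the
#' configuration that underestimates clinical doses consistently) into a
#' single headline correction factor: the arithmetic mean bias and its
#' (min, max) range. Rounding to integer percent happens only at report
#' level; the returned values keep full precision.
#'
#' @param reports List of [bias_report()]s, or a numeric vector of mean
#'   percent biases.
#' @return List: `mean_percent`, `range` (low, high), `rounded_percent`,
#'   `n`.
#' @export
correction_factor <- function(reports) {
  if (is.numeric(reports)) {
    biases <- reports
  } else {
    if (length(reports) == 0) stop("empty report set", call. = FALSE)
    biases <- vapply(reports, function(r) r$mean_percent_bias, numeric(1))
    descr <- lapply(reports, function(r) r$model)
    is_nf <- vapply(descr, function(m) {
      is.list(m) && isTRUE(m$normalised) &&
        identical(m$reconstruction, "FBP")
    }, logical(1))
    if (!all(is_nf))
      warning("mixed model types: correction factor expects normalised-FBP models")
  }
  if (length(biases) == 0) stop("empty report set", call. = FALSE)
  list(mean_percent = mean(biases),
       range = c(low = min(biases), high = max(biases)),
       rounded_percent = round(mean(biases)),
       n = length(biases))
}

#' Correct predicted doses for systematic model bias
#'
#' Default mode divides predictions by the fitted slope, mapping them onto
#' the line of identity. The simplified mode uses the pooled headline bias
#' of an underestimating model: `corrected = predicted / (1 - bias/100)`.
#'
#' @param predicted Numeric dose vector (mGy/MBq).
#' @param slope Fitted slope (> 0), used in `mode = "slope"`.
#' @param bias_percent Mean percent bias (< 100), used in
#'   `mode = "simplified"` for underestimating models.
#' @param mode `"slope"` or `"simplified"`.
#' @return Corrected doses.
#' @export
apply_correction <- function(predicted, slope = NULL, bias_percent = NULL,
                             mode = c("slope", "simplified")) {
  mode <- match.arg(mode)
  if (mode == "slope") {
    if (is.null(slope)) stop("slope required", call. = FALSE)
    if (slope <= 0) stop("slope must be positive", call. = FALSE)
    predicted / slope
  } else {
    if (is.null(bias_percent)) stop("bias_percent required", call. = FALSE)
    if (bias_percent >= 100)
      stop("simplified correction needs bias < 100%", call. = FALSE)
    predicted / (1 - bias_percent / 100)
  }
}

#' Compare residence times across reconstruction methods
#'
#' Regresses iteratively reconstructed residence times on FBP ones over
#' matched organ/subject pairs, and reports the fitted slope with its 95%
#' CI, r2 and the pairwise mean ratio. A slope above 1 means iterative
#' reconstruction systematically inflates residence-time estimates.
#'
#' @param tau_fbp,tau_iter Matched numeric vectors of residence times
#'   (hours); named vectors are matched by label.
#' @param through_origin Passed to the regression.
#' @return List: `slope`, `sem`, `r2`, `ci`, `mean_ratio`, `n`, `fit`.
#' @export
compare_reconstructions <- function(tau_fbp, tau_iter,
                                    through_origin = FALSE) {
  m <- match_dose_pairs(tau_iter, tau_fbp)
  if (length(m$true) < 3L)
    stop("need at least 3 matched tau pairs", call. = FALSE)
  fit <- fit_prediction_line(m$predicted, m$true, through_origin)
  ratio <- as.numeric(m$predicted) / as.numeric(m$true)
  list(slope = fit$slope, sem = fit$sem, r2 = fit$r2, ci = fit$ci,
       mean_ratio = mean(ratio[is.finite(ratio)]), n = fit$n, fit = fit)
}

#' Write bias reports to CSV
#'
#' Columns mirror the model-comparison table layout:
#' `model,r2,mean_pct_bias,slope,sem,ci_low,ci_high,n,lli_included`.
#'
#' @param reports List of [bias_report()]s (or a single one).
#' @param path Output CSV path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
write_bias_reports <- function(reports, path, comment = NULL) {
  if (inherits(reports, "bias_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      model = if (is.list(r$model)) model_label(r$model) else r$model,
      r2 = r$r2, mean_pct_bias = r$mean_percent_bias, slope = r$slope,
      sem = r$sem, ci_low = r$ci["low"], ci_high = r$ci["high"],
      n = r$n, lli_included = r$lli_included, row.names = NULL)
  }))
  write_csv_commented(df, path, comment)
  invisible(path)
}
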