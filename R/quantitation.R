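#' Signature deuterium channel of a target over an interferent
#'
#' The smallest channel k flagged as deuterated for the target but not for
#' the isobaric interferent; that channel carries target-only signal and can
#' be ratioed against an internal standard for absolute quantitation. The
#' relation is asymmetric: the interferent may have no signature of its own.
#'
#' @param target,interferent `hdx_judgment`s (from [judge_deuteration()]),
#'   or integer vectors of flagged channels.
#' @return Integer channel index k.
#' @export
signature_channel <- function(target, interferent) {
  tf <- if (inherits(target, "hdx_judgment")) target$flagged else as.integer(target)
  nf <- if (inherits(interferent, "hdx_judgment")) interferent$flagged else as.integer(interferent)
  uniq <- setdiff(tf, nf)
  if (length(uniq) == 0L) {
    stop("no signature channel: every deuterium peak of the target is shared with the interferent")
  }
  min(uniq)
}

#' Fit a linear internal-standard calibration curve
#'
#' Ordinary least squares of response (target signature-channel intensity
#' ratioed to the internal-standard channel, D_t/D_is) against concentration,
#' with the Pearson correlation of the points as the linearity measure.
#' Responses are built from absolute channel intensities — the IS ratio
#' already removes the run-to-run scale, and base-peak renormalization would
#' distort linearity.
#'
#' @param concentration Numeric concentrations (>= 3 distinct values).
#' @param response Numeric responses, same length.
#' @param units Concentration units label (e.g. `"ug/mL"`).
#' @return Object of class `"hdx_calibration"`: `slope`, `intercept`,
#'   `pearson_r`, `points` (data frame), `units`.
#' @export
fit_calibration <- function(concentration, response, units = "ug/mL") {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 3L) {
    stop("calibration needs at least 3 distinct concentrations")
  }
  if (stats::var(concentration) == 0) stop("zero concentration variance")
  fit <- stats::lm.fit(cbind(1, concentration), response)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 pearson_r = stats::cor(concentration, response),
                 points = data.frame(concentration = concentration,
                                     response = response),
                 units = units),
            class = "hdx_calibration")
}

#' @export
print.hdx_calibration <- function(x, digits = 4, ...) {
  cat("Internal-standard calibration curve\n")
  cat(sprintf("  response = %.*g + %.*g x concentration (%s)\n",
              digits, x$intercept, digits, x$slope, x$units))
  cat(sprintf("  Pearson r = %.4f over %d points\n",
              x$pearson_r, nrow(x$points)))
  invisible(x)
}

#' @export
coef.hdx_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.hdx_calibration <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$points$concentration
          else if (is.list(newdata)) newdata$concentration else newdata
  object$intercept + object$slope * conc
}

#' @export
residuals.hdx_calibration <- function(object, ...) {
  object$points$response - predict(object)
}

#' @export
plot.hdx_calibration <- function(x, ...) {
  graphics::plot(x$points$concentration, x$points$response,
                 xlab = sprintf("concentration (%s)", x$units),
                 ylab = "response (D_t / D_is)", ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

#' Inverse-predict concentration from a response
#'
#' @param response Numeric responses.
#' @param curve An `hdx_calibration`.
#' @return Numeric concentrations; negative estimates are returned as-is
#'   with a `below_range` attribute flagging them.
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "hdx_calibration"))
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (response - curve$intercept) / curve$slope
  attr(conc, "below_range") <- conc < 0
  conc
}
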