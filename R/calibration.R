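#' Fit a densitometric calibration curve
#'
#' Ordinary least-squares straight line `signal = slope * amount + intercept`
#' through a dilution series of recombinant protein standards, as used to
#' convert Western-blot band intensities into absolute protein amounts.
#'
#' @param standards data frame with columns `amount_pg` (strictly positive,
#'   at least two distinct values) and `signal` (non-negative densitometric
#'   units).
#' @param force_zero fit through the origin (`signal = slope * amount`).
#'   Default `FALSE`: the intercept absorbs background signal.
#' @param log_linear fit `signal = slope * log10(amount) + intercept`
#'   instead; useful when the detector response saturates. Default `FALSE`.
#' @return a `calibration_curve` list with `slope`, `intercept`, `r_squared`,
#'   `valid_range` (the standard amounts spanned), `usable` (slope > 0),
#'   `force_zero`, `log_linear` and the underlying `fit`.
#' @export
fit_calibration <- function(standards, force_zero = FALSE, log_linear = FALSE) {
  stopifnot(all(c("amount_pg", "signal") %in% names(standards)))
  amount <- as.numeric(standards$amount_pg)
  signal <- as.numeric(standards$signal)
  if (any(amount <= 0)) stop("standard amounts must be strictly positive")
  if (any(signal < 0)) stop("standard signals must be non-negative")
  if (length(unique(amount)) < 2L)
    stop("need at least two distinct standard amounts to fit a line")
  x <- if (log_linear) log10(amount) else amount
  fit <- if (force_zero) stats::lm(signal ~ x - 1) else stats::lm(signal ~ x)
  co <- stats::coef(fit)
  slope <- unname(if (force_zero) co[["x"]] else co[["x"]])
  intercept <- if (force_zero) 0 else unname(co[["(Intercept)"]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 valid_range = range(amount), usable = slope > 0,
                 force_zero = force_zero, log_linear = log_linear, fit = fit),
            class = "calibration_curve")
}

#' Predicted signal for a given amount
#'
#' The forward direction of the calibration curve; [quantify_signal()] is its
#' inverse.
#'
#' @param curve a [fit_calibration()] result.
#' @param amount_pg protein amounts in pg.
#' @return predicted densitometric signals.
#' @export
predict_signal <- function(curve, amount_pg) {
  x <- if (curve$log_linear) log10(amount_pg) else amount_pg
  curve$slope * x + curve$intercept
}

#' Quantify protein amounts from densitometric signals
#'
#' Inverts the calibration curve: `amount = (signal - intercept) / slope`
#' (back-transformed from log10 for log-linear curves). Estimates outside the
#' standards' amount range are flagged `extrapolated`; negative estimates are
#' clamped to 0 and flagged, never reported as negative amounts.
#'
#' @param signal densitometric signal(s).
#' @param curve a usable [fit_calibration()] curve (positive slope).
#' @return data frame with columns `signal`, `amount_pg`, `extrapolated`,
#'   `clamped`.
#' @export
quantify_signal <- function(signal, curve) {
  if (!isTRUE(curve$usable))
    stop("calibration curve is unusable (slope <= 0)")
  x <- (as.numeric(signal) - curve$intercept) / curve$slope
  amount <- if (curve$log_linear) 10^x else x
  clamped <- !is.na(amount) & amount < 0
  amount[clamped] <- 0
  extrapolated <- !is.na(amount) &
    (amount < curve$valid_range[1L] | amount > curve$valid_range[2L])
  data.frame(signal = as.numeric(signal), amount_pg = amount,
             extrapolated = extrapolated, clamped = clamped)
}

#' Max-normalized relative quantification
#'
#' Expresses densitometric signals relative to the strongest band (set to 1),
#' the within-blot relative readout used when no recombinant standard series
#' is available. Scale-invariant: multiplying every signal by a constant
#' leaves the result unchanged.
#'
#' @param signal non-negative densitometric signals.
#' @return signals divided by their maximum.
#' @export
relative_signal <- function(signal) {
  signal <- as.numeric(signal)
  if (any(signal < 0)) stop("signals must be non-negative")
  m <- max(signal)
  if (m <= 0) stop("all signals are zero")
  signal / m
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve: signal = %.4g * %s + %.4g (R^2 = %.4f)%s\n",
    x$slope, if (x$log_linear) "log10(amount_pg)" else "amount_pg",
    x$intercept, x$r_squared, if (x$usable) "" else " [UNUSABLE: slope <= 0]"))
  cat(sprintf("  valid range: %.4g - %.4g pg\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
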