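#' Construct a phosphate standard curve
#'
#' @param slope AU per uM phosphate (> 0).
#' @param intercept AU at zero phosphate.
#' @param fit_residual root-mean-square residual of the fit in AU
#'   (`NA` for a curve stated rather than fitted).
#' @return A `standard_curve` object.
#' @seealso [fit_phosphate_standard_curve()]
#' @export
standard_curve <- function(slope, intercept = 0, fit_residual = NA_real_) {
  stopifnot(is.numeric(slope), length(slope) == 1L)
  if (!is.finite(slope) || slope <= 0) stop("standard curve slope must be positive")
  structure(
    list(slope = slope, intercept = intercept, fit_residual = fit_residual),
    class = "standard_curve"
  )
}

#' Fit a KH2PO4 phosphate standard curve
#'
#' Ordinary least-squares line `AU = slope * uM + intercept` through
#' calibration points, the equation used to translate the 360 nm absorbance
#' change into phosphate release.
#'
#' @param concentrations phosphate concentrations in uM (at least two
#'   distinct values).
#' @param absorbances matching absorbances in AU.
#' @return A [standard_curve()] with the root-mean-square residual recorded.
#' @examples
#' fit_phosphate_standard_curve(c(0, 10), c(0.1, 0.2))
#' @export
fit_phosphate_standard_curve <- function(concentrations, absorbances) {
  stopifnot(is.numeric(concentrations), is.numeric(absorbances),
            length(concentrations) == length(absorbances),
            length(concentrations) >= 2L)
  if (length(unique(concentrations)) < 2L) {
    stop("degenerate curve: all concentrations are equal")
  }
  fit <- lm(absorbances ~ concentrations)
  standard_curve(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    fit_residual = sqrt(mean(fit$residuals^2))
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve: AU =", format(x$slope, digits = 6), "* uM +",
      format(x$intercept, digits = 6),
      if (is.finite(x$fit_residual)) paste("(RMS residual", format(x$fit_residual, digits = 3), "AU)") else "",
      "\n")
  invisible(x)
}

#' Estimate ATP hydrolysis rate from the linear phase
#'
#' Fits a least-squares line to the absorbance points within the first
#' `window_minutes` (the linear phase, conventionally the first 10 min) and
#' divides the AU/min slope by the standard-curve slope to obtain the
#' phosphate release rate in uM/min. Points after the window (e.g. a
#' saturating plateau) do not influence the estimate.
#'
#' @param series an `absorbance_series` data.frame (`time`, `au`) with
#'   strictly increasing times.
#' @param curve a [standard_curve()].
#' @param window_minutes end of the fit window in minutes (default 10);
#'   at least 3 points must fall in `[0, window_minutes]`.
#' @param baseline optional second `absorbance_series` (e.g. a no-protein
#'   control) whose windowed rate is subtracted; off by default.
#' @return A `rate_estimate`: list with `rate` (uM/min), `window`
#'   (start, end minutes) and `r_squared` of the windowed fit.
#' @export
atpase_rate <- function(series, curve, window_minutes = 10, baseline = NULL) {
  stopifnot(is.data.frame(series), all(c("time", "au") %in% names(series)))
  stopifnot(inherits(curve, "standard_curve"))
  if (any(diff(series$time) <= 0)) stop("times must be strictly increasing")
  in_win <- series$time >= 0 & series$time <= window_minutes
  if (sum(in_win) < 3L) stop("window too sparse: fewer than 3 points within the window")
  fit <- lm(au ~ time, data = series[in_win, ])
  rate <- unname(coef(fit)[2L]) / curve$slope
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.null(baseline)) {
    rate <- rate - atpase_rate(baseline, curve, window_minutes)$rate
  }
  structure(
    list(rate = rate, window = c(0, window_minutes), r_squared = r2),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("ATPase rate:", format(x$rate, digits = 6), "uM/min over",
      x$window[1L], "-", x$window[2L], "min (r^2 =",
      format(x$r_squared, digits = 4), ")\n")
  invisible(x)
}
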