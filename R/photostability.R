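#' Power-law photodegradation of releasable drug
#'
#' UV irradiation degrades part of the loaded active compound, so the
#' fraction released over a fixed 24-h window declines with irradiation
#' time. The decline is modelled as a power law,
#' \deqn{Q(t_{irr}) = Q_{max} (1 + t_{irr})^b,}
#' where \eqn{Q_{max}} is the released amount of the non-irradiated sample
#' (the anchor at \eqn{t_{irr} = 0}) and the exponent \eqn{b} is negative
#' for a photodegrading compound.
#'
#' @param t_irr Irradiation time in hours, non-negative.
#' @param qmax Released amount at zero irradiation, percent, positive.
#' @param b Dimensionless exponent.
#' @return Released amount, percent.
#' @examples
#' photolaw_q(10, 82, -0.15167) # ~57
#' @export
photolaw_q <- function(t_irr, qmax, b) {
  if (any(!is.finite(t_irr)) || any(t_irr < 0)) {
    stop("'t_irr' must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(qmax) || qmax <= 0) {
    stop("'qmax' must be positive", call. = FALSE)
  }
  qmax * (1 + t_irr)^b
}

#' Construct an irradiation series
#'
#' Pairs of UV irradiation time (hours) and the released fraction measured
#' over a fixed 24-h window (percent). A `t_irr = 0` entry is required: it
#' anchors `Qmax`.
#'
#' @param t_irr_h Irradiation hours, non-negative, strictly increasing,
#'   first entry 0.
#' @param q24_pct Released percent after the fixed release window.
#' @return An object of class `irradiation_series` (a data frame).
#' @export
irradiation_series <- function(t_irr_h, q24_pct) {
  t_irr_h <- as.numeric(t_irr_h)
  q24_pct <- as.numeric(q24_pct)
  if (length(t_irr_h) != length(q24_pct)) {
    stop("'t_irr_h' and 'q24_pct' must have equal length", call. = FALSE)
  }
  if (length(t_irr_h) < 2L) {
    stop("need at least 2 points", call. = FALSE)
  }
  if (t_irr_h[1] != 0) {
    stop("series must include a t_irr = 0 entry (anchors Qmax)",
      call. = FALSE
    )
  }
  if (any(diff(t_irr_h) <= 0)) {
    stop("'t_irr_h' must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(t_irr_h = t_irr_h, q24_pct = q24_pct)
  class(out) <- c("irradiation_series", "data.frame")
  out
}

#' Fit the photodegradation power law
#'
#' Deterministic closed-form least squares in log–log coordinates:
#' \eqn{\log Q} regressed on \eqn{\log(1 + t_{irr})}; `qmax` is the
#' exponentiated intercept and `b` the slope. An optional nonlinear
#' refinement (Levenberg–Marquardt in the original coordinates, started
#' from the closed-form solution) is off by default.
#'
#' @param series An [irradiation_series()] (or data frame with columns
#'   `t_irr_h`, `q24_pct`).
#' @param refine If `TRUE`, polish the log-space solution by nonlinear
#'   least squares in the original coordinates.
#' @return An object of class `photo_fit`: list with `qmax`, `b`, `r2`
#'   (computed on the original percent scale) and `fitted`.
#' @examples
#' fit <- fit_photolaw(irradiation_series(c(0, 10), c(82, 57)))
#' fit$b # close to -0.1517
#' @export
fit_photolaw <- function(series, refine = FALSE) {
  if (!inherits(series, "irradiation_series")) {
    series <- irradiation_series(series$t_irr_h, series$q24_pct)
  }
  q <- series$q24_pct
  if (any(q <= 0)) {
    stop("released amounts must be positive for the log-log fit",
      call. = FALSE
    )
  }
  x <- log(1 + series$t_irr_h)
  y <- log(q)
  fit <- stats::lm.fit(cbind(1, x), y)
  qmax <- exp(fit$coefficients[[1]])
  b <- fit$coefficients[[2]]
  if (refine) {
    nl <- tryCatch(
      minpack.lm::nlsLM(q24 ~ qmax * (1 + t)^b,
        data = data.frame(t = series$t_irr_h, q24 = q),
        start = list(qmax = qmax, b = b),
        lower = c(qmax = 1e-9, b = -Inf)
      ),
      error = function(e) NULL
    )
    if (!is.null(nl)) {
      co <- stats::coef(nl)
      qmax <- co[["qmax"]]
      b <- co[["b"]]
    }
  }
  fitted_vals <- photolaw_q(series$t_irr_h, qmax, b)
  r2 <- if (stats::var(q) > 0) r_squared(q, fitted_vals) else NA_real_
  structure(
    list(
      qmax = qmax, b = b, r2 = r2, fitted = fitted_vals,
      t_irr_h = series$t_irr_h, refined = refine
    ),
    class = "photo_fit"
  )
}

#' @export
print.photo_fit <- function(x, ...) {
  cat(sprintf(
    "Photodegradation power law: Qmax = %.4g%%, b = %.5g, R^2 = %.4g\n",
    x$qmax, x$b, x$r2
  ))
  invisible(x)
}

#' Photolytic loss at a given irradiation time
#'
#' Absolute loss in percentage points, `qmax - Q(t_irr)`. This is the
#' difference of two printed release percentages (e.g. 82% to 57% is a
#' 25-point loss); for the loss relative to the non-irradiated amount use
#' [loss_at_relative()].
#'
#' @param fit A `photo_fit`.
#' @param t_irr Irradiation time, hours.
#' @return Loss in percentage points, non-negative for `b <= 0`.
#' @export
loss_at <- function(fit, t_irr) {
  stopifnot(inherits(fit, "photo_fit"))
  fit$qmax - photolaw_q(t_irr, fit$qmax, fit$b)
}

#' @rdname loss_at
#' @return `loss_at_relative`: loss as a percent of `qmax`.
#' @export
loss_at_relative <- function(fit, t_irr) {
  100 * loss_at(fit, t_irr) / fit$qmax
}
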