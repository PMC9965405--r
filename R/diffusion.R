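#' Fickian diffusion coefficients from plane-sheet release asymptotics
#'
#' For one-dimensional Fickian diffusion out of a plane sheet of
#' half-thickness \eqn{L} with constant diffusivity \eqn{D}, the released
#' fraction \eqn{M_t/M_\infty} obeys two classical asymptotic laws:
#'
#' * short time (valid up to about \eqn{M_t/M_\infty = 0.6}):
#'   \eqn{M_t/M_\infty = (2/L)\sqrt{Dt/\pi}}, linear in \eqn{\sqrt{t}};
#' * long time: \eqn{1 - M_t/M_\infty = (8/\pi^2)\exp(-\pi^2 D t / 4L^2)},
#'   a single exponential.
#'
#' `estimate_D_short` regresses \eqn{M_t/M_\infty} on \eqn{\sqrt{t}}
#' through the origin over the points below `cutoff` and inverts the slope
#' \eqn{s} as \eqn{D = \pi (s L / 2)^2}. `estimate_D_long` regresses
#' \eqn{\ln[(M_\infty - M_t)/M_\infty]} on \eqn{t} over the points above
#' `floor` and inverts the slope \eqn{m} as \eqn{D = -4 L^2 m / \pi^2};
#' its intercept can be checked against the theoretical
#' \eqn{\ln(8/\pi^2) \approx -0.210}.
#'
#' `L` is the half-thickness of the mat (release from both faces); halve a
#' measured full thickness before passing it in. Times are stored in hours
#' and converted to seconds internally, so with `L` in cm the estimate is
#' in cm^2/s.
#'
#' @param curve A [release_curve()] (times in hours, cumulative percent).
#' @param L Half-thickness of the sheet, cm.
#' @param m_inf Total releasable amount on the `q_pct` scale (percent).
#'   Often the fitted Gompertz plateau or the last observed value; see
#'   [m_inf_value()].
#' @param cutoff Short-time regime boundary on `Mt/M_inf`, in (0, 1];
#'   default 0.6, the standard validity range of the square-root law.
#' @param floor Long-time regime boundary on `Mt/M_inf`, in [0, 1);
#'   default 0.4.
#' @return An object of class `diffusion_estimate`: a list with `D`
#'   (cm^2/s), `regime`, `half_thickness_L`, `slope`, `intercept`,
#'   `n_points_used`, `r2_fit`, `m_inf`, `units` and `flags`.
#' @examples
#' rc <- generate_fickian_series_curve(
#'   D = 1e-8, L = 0.01,
#'   times_h = seq(0.05, 8, by = 0.05)
#' )
#' estimate_D_short(rc, L = 0.01, m_inf = 100)$D
#' estimate_D_long(rc, L = 0.01, m_inf = 100)$D
#' @name diffusion_estimation
NULL

new_diffusion_estimate <- function(D, regime, L, slope, intercept, n, r2,
                                   m_inf, flags = character()) {
  structure(
    list(
      D = D, regime = regime, half_thickness_L = L, slope = slope,
      intercept = intercept, n_points_used = n, r2_fit = r2,
      m_inf = m_inf, units = "cm2/s", flags = flags
    ),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "D (%s regime) = %.4g %s  [L = %g cm, %d points, fit R^2 = %.4f]\n",
    x$regime, x$D, x$units, x$half_thickness_L, x$n_points_used, x$r2_fit
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname diffusion_estimation
#' @export
estimate_D_short <- function(curve, L, m_inf, cutoff = 0.6) {
  assert_release_curve(curve)
  if (!is.finite(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  if (!is.finite(m_inf) || m_inf <= 0) {
    stop("'m_inf' must be positive", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff > 1) stop("'cutoff' must be in (0, 1]", call. = FALSE)
  frac <- curve$q_pct / m_inf
  t_s <- curve$time_h * 3600
  keep <- frac <= cutoff & t_s > 0
  if (sum(keep) < 2L) {
    stop(sprintf(
      "no short-time regime: fewer than 2 points with Mt/Minf <= %.3g", cutoff
    ), call. = FALSE)
  }
  x <- sqrt(t_s[keep])
  y <- frac[keep]
  slope <- sum(x * y) / sum(x^2) # through-origin least squares
  flags <- character()
  if (slope <= 0) flags <- "non-physical: non-positive slope"
  D <- pi * (slope * L / 2)^2
  r2 <- if (stats::var(y) > 0) r_squared(y, slope * x) else NA_real_
  new_diffusion_estimate(
    D, "short_time", L, slope,
    intercept = 0,
    n = sum(keep), r2 = r2, m_inf = m_inf, flags = flags
  )
}

#' @rdname diffusion_estimation
#' @export
estimate_D_long <- function(curve, L, m_inf, floor = 0.4) {
  assert_release_curve(curve)
  if (!is.finite(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  if (!is.finite(m_inf) || m_inf <= 0) {
    stop("'m_inf' must be positive", call. = FALSE)
  }
  if (floor < 0 || floor >= 1) stop("'floor' must be in [0, 1)", call. = FALSE)
  frac <- curve$q_pct / m_inf
  t_s <- curve$time_h * 3600
  flags <- character()
  if (any(frac >= 1)) {
    warning(sprintf(
      "%d point(s) with Mt >= Minf excluded from long-time regression",
      sum(frac >= 1)
    ), call. = FALSE)
    flags <- c(flags, "points at or above m_inf excluded")
  }
  keep <- frac >= floor & frac < 1
  if (sum(keep) < 2L) {
    stop(sprintf(
      "no long-time regime: fewer than 2 points with %.3g <= Mt/Minf < 1",
      floor
    ), call. = FALSE)
  }
  y <- log(1 - frac[keep])
  x <- t_s[keep]
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (slope >= 0) flags <- c(flags, "non-physical: non-negative slope")
  D <- -4 * L^2 * slope / pi^2
  r2 <- if (stats::var(y) > 0) {
    r_squared(y, intercept + slope * x)
  } else {
    NA_real_
  }
  new_diffusion_estimate(
    D, "long_time", L, slope, intercept,
    n = sum(keep), r2 = r2, m_inf = m_inf, flags = flags
  )
}

#' Resolve the total releasable amount for diffusion analysis
#'
#' The release asymptotics need the equilibrium amount `M_inf` on the
#' `q_pct` scale. Three policies: the fitted Gompertz plateau (default),
#' the last observed point, or an explicit value.
#'
#' @param curve A [release_curve()].
#' @param policy One of `"gompertz"`, `"last"`, `"value"`.
#' @param value Explicit value (percent) when `policy = "value"`.
#' @return A list with `m_inf` (percent) and `policy`.
#' @export
m_inf_value <- function(curve, policy = c("gompertz", "last", "value"),
                        value = NULL) {
  policy <- match.arg(policy)
  m_inf <- switch(policy,
    gompertz = {
      fit <- fit_release_model(curve, "gompertz")
      if (!fit$converged) {
        warning("Gompertz fit for m_inf did not converge; using last point",
          call. = FALSE
        )
        policy <- "last"
        utils::tail(curve$q_pct, 1)
      } else {
        unname(fit$params[["Qmax"]])
      }
    },
    last = utils::tail(curve$q_pct, 1),
    value = {
      if (is.null(value) || !is.finite(value) || value <= 0) {
        stop("policy 'value' requires a positive 'value'", call. = FALSE)
      }
      value
    }
  )
  list(m_inf = m_inf, policy = policy)
}
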