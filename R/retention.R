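#' Gravimetric liquid retention
#'
#' Relative equilibrium mass change of a soaked membrane, in percent of
#' its dry mass. The signed-uptake convention is used: positive values are
#' liquid uptake (mass gain), negative values mass loss. The opposite
#' orientation, dry-mass minus equilibrated mass, is available via
#' `convention = "dry_minus_wet"` for comparison with reports that print
#' the formula that way.
#'
#' @param m0 Dry mass, g, positive.
#' @param meq Equilibrated (soaked) mass, g, non-negative.
#' @param convention `"uptake"` (default, `(meq - m0)/m0 * 100`) or
#'   `"dry_minus_wet"` (`(m0 - meq)/m0 * 100`).
#' @return Retention degree in percent (vectorised).
#' @examples
#' retention_signed(0.200, 0.314) # +57: uptake
#' retention_signed(0.200, 0.170) # -15: mass loss
#' @export
retention_signed <- function(m0, meq,
                             convention = c("uptake", "dry_minus_wet")) {
  convention <- match.arg(convention)
  if (any(!is.finite(m0)) || any(m0 <= 0)) {
    stop("dry mass 'm0' must be positive", call. = FALSE)
  }
  if (any(!is.finite(meq)) || any(meq < 0)) {
    stop("equilibrated mass 'meq' must be non-negative", call. = FALSE)
  }
  q <- (meq - m0) / m0 * 100
  if (convention == "dry_minus_wet") -q else q
}

#' Summarise contact-angle replicate readings
#'
#' Sample mean and standard deviation of replicate contact-angle readings,
#' with a hydrophobicity flag (mean angle above 90 degrees).
#'
#' @param readings Numeric vector of angles in degrees, each in (0, 180).
#' @return An object of class `angle_summary`: list with `mean`, `sd`,
#'   `n`, `hydrophobic` and the readings.
#' @examples
#' summarize_angles(c(129, 129, 130, 128, 129))
#' @export
summarize_angles <- function(readings) {
  readings <- as.numeric(readings)
  if (length(readings) < 1L) {
    stop("need at least one reading", call. = FALSE)
  }
  if (any(!is.finite(readings)) || any(readings <= 0) ||
    any(readings >= 180)) {
    stop("contact angles must lie in (0, 180) degrees", call. = FALSE)
  }
  m <- mean(readings)
  structure(
    list(
      mean = m,
      sd = if (length(readings) > 1L) stats::sd(readings) else NA_real_,
      n = length(readings),
      hydrophobic = m > 90,
      readings = readings
    ),
    class = "angle_summary"
  )
}

#' @export
print.angle_summary <- function(x, ...) {
  cat(sprintf(
    "Contact angle: %.1f deg %s (n = %d)%s\n", x$mean,
    if (is.na(x$sd)) "" else sprintf("+/- %.1f", x$sd), x$n,
    if (x$hydrophobic) " [hydrophobic]" else ""
  ))
  invisible(x)
}
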