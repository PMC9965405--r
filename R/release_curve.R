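#' Construct a cumulative release curve
#'
#' A `release_curve` holds one cumulative in-vitro release measurement
#' series: sampling times in hours and the cumulative percent of the
#' loaded drug released up to each time.
#'
#' @param time_h Numeric vector of sampling times in hours; must be
#'   non-negative, finite and strictly increasing.
#' @param q_pct Numeric vector of cumulative percent released (0-100 scale;
#'   values slightly above 100 are tolerated as measurement noise).
#' @param medium Free-text label of the release medium (e.g. `"PBS"`,
#'   `"pH3"`).
#' @param replicate Optional integer replicate identifier.
#' @param unit Unit of `q_pct`: `"percent"` (default) or `"fraction"`.
#'   Fractions are converted to percent on input.
#' @param cumulative_validated If `TRUE`, assert that the series is
#'   non-decreasing within `tol` percentage points.
#' @param tol Tolerance, in percentage points, for transient decreases in a
#'   cumulative-validated curve. Default 1.5 allows ordinary sampling noise.
#'
#' @return An object of class `release_curve`: a data frame with columns
#'   `time_h` and `q_pct` plus `medium` and `replicate` attributes.
#' @examples
#' rc <- release_curve(c(1, 4, 24), c(36, 58, 78), medium = "PBS")
#' rc
#' @export
release_curve <- function(time_h, q_pct, medium = "unspecified",
                          replicate = NA_integer_,
                          unit = c("percent", "fraction"),
                          cumulative_validated = FALSE, tol = 1.5) {
  unit <- match.arg(unit)
  time_h <- as.numeric(time_h)
  q_pct <- as.numeric(q_pct)
  if (length(time_h) != length(q_pct)) {
    stop("'time_h' and 'q_pct' must have the same length", call. = FALSE)
  }
  if (length(time_h) == 0L) {
    warning("constructing an empty release curve", call. = FALSE)
  } else {
    if (anyNA(time_h) || any(!is.finite(time_h))) {
      stop("'time_h' must be finite", call. = FALSE)
    }
    if (any(time_h < 0)) stop("'time_h' must be non-negative", call. = FALSE)
    if (any(diff(time_h) <= 0)) {
      stop("'time_h' must be strictly increasing", call. = FALSE)
    }
    if (anyNA(q_pct) || any(!is.finite(q_pct))) {
      stop("'q_pct' must be finite", call. = FALSE)
    }
  }
  if (unit == "fraction") q_pct <- 100 * q_pct
  if (cumulative_validated && length(q_pct) > 1L) {
    drops <- -diff(q_pct)
    if (any(drops > tol)) {
      stop(sprintf(
        "curve flagged cumulative-validated decreases by %.3g points (tolerance %.3g)",
        max(drops), tol
      ), call. = FALSE)
    }
  }
  out <- data.frame(time_h = time_h, q_pct = q_pct)
  attr(out, "medium") <- as.character(medium)
  attr(out, "replicate") <- replicate
  attr(out, "cumulative_validated") <- cumulative_validated
  class(out) <- c("release_curve", "data.frame")
  out
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf(
    "Release curve: %d points, medium '%s'%s\n", nrow(x),
    attr(x, "medium"),
    if (!is.na(attr(x, "replicate"))) {
      sprintf(", replicate %s", attr(x, "replicate"))
    } else ""
  ))
  if (nrow(x) > 0L) {
    cat(sprintf(
      "  t = %.3g..%.3g h, Q = %.3g..%.3g %%\n",
      min(x$time_h), max(x$time_h), min(x$q_pct), max(x$q_pct)
    ))
  }
  invisible(x)
}

is_release_curve <- function(x) inherits(x, "release_curve")

assert_release_curve <- function(x) {
  if (!is_release_curve(x)) {
    stop("expected a 'release_curve' object; see release_curve()",
      call. = FALSE
    )
  }
  invisible(x)
}
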