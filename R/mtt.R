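#' Background-corrected MTT absorbance
#'
#' Subtracts the 655 nm background reading from the 595 nm formazan
#' signal, per well. A negative corrected signal (over-subtraction) is
#' returned with a warning rather than silently clipped.
#'
#' @param a595 Absorbance at 595 nm, non-negative (vectorised).
#' @param a655 Background absorbance at 655 nm, non-negative.
#' @return Corrected absorbance, `a595 - a655`.
#' @export
corrected_signal <- function(a595, a655) {
  if (any(!is.finite(a595)) || any(a595 < 0) ||
    any(!is.finite(a655)) || any(a655 < 0)) {
    stop("absorbances must be finite and non-negative", call. = FALSE)
  }
  out <- a595 - a655
  if (any(out < 0)) {
    warning(sprintf(
      "%d corrected signal(s) negative (background exceeds signal)",
      sum(out < 0)
    ), call. = FALSE)
  }
  out
}

#' Percent residual viability relative to untreated controls
#'
#' Mean corrected absorbance of the treated wells as a percentage of the
#' mean of the untreated wells, with a delta-method standard error
#' propagated from the replicate variances of both groups. The statistic
#' is invariant under joint rescaling of all absorbances (path-length
#' independence).
#'
#' @param treated,untreated Numeric vectors of background-corrected
#'   absorbances (see [corrected_signal()]); both non-empty, and the
#'   untreated mean must be positive.
#' @return A list with `viability_pct`, `se_pct`, `n_treated`,
#'   `n_untreated`.
#' @examples
#' percent_viability(c(0.14, 0.15), c(0.70, 0.72))
#' @export
percent_viability <- function(treated, untreated) {
  treated <- as.numeric(treated)
  untreated <- as.numeric(untreated)
  if (length(treated) < 1L || length(untreated) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mu_u <- mean(untreated)
  if (!is.finite(mu_u) || mu_u <= 0) {
    stop("mean untreated signal must be positive", call. = FALSE)
  }
  mu_t <- mean(treated)
  se_t <- if (length(treated) > 1L) {
    stats::sd(treated) / sqrt(length(treated))
  } else {
    NA_real_
  }
  se_u <- if (length(untreated) > 1L) {
    stats::sd(untreated) / sqrt(length(untreated))
  } else {
    NA_real_
  }
  v <- 100 * mu_t / mu_u
  se <- (100 / mu_u) * sqrt(se_t^2 + (mu_t / mu_u)^2 * se_u^2)
  list(
    viability_pct = v, se_pct = se,
    n_treated = length(treated), n_untreated = length(untreated)
  )
}

#' Viability table from a plate record
#'
#' Aggregates per-well corrected signals by group and timepoint and
#' normalises each group to the control group of the same timepoint.
#'
#' @param plate Data frame with columns `well_id`, `group`, `timepoint_h`,
#'   `a595`, `a655` (see [read_plate_csv()] / [generate_plate()]).
#' @param control_group Name of the untreated control group.
#' @return Data frame with one row per non-control group and timepoint:
#'   `group`, `timepoint_h`, `viability_pct`, `se_pct`, `n_wells`.
#' @export
viability_table <- function(plate, control_group = "untreated") {
  req <- c("well_id", "group", "timepoint_h", "a595", "a655")
  miss <- setdiff(req, names(plate))
  if (length(miss)) {
    stop("plate record missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!control_group %in% plate$group) {
    stop(sprintf("control group '%s' absent from plate", control_group),
      call. = FALSE
    )
  }
  plate$corrected <- corrected_signal(plate$a595, plate$a655)
  out <- list()
  for (tp in sort(unique(plate$timepoint_h))) {
    sub <- plate[plate$timepoint_h == tp, ]
    ctrl <- sub$corrected[sub$group == control_group]
    if (length(ctrl) == 0L) {
      warning(sprintf("no '%s' wells at timepoint %g h; skipped",
        control_group, tp
      ), call. = FALSE)
      next
    }
    for (g in setdiff(unique(sub$group), control_group)) {
      trt <- sub$corrected[sub$group == g]
      pv <- percent_viability(trt, ctrl)
      out[[length(out) + 1L]] <- data.frame(
        group = g, timepoint_h = tp,
        viability_pct = pv$viability_pct, se_pct = pv$se_pct,
        n_wells = pv$n_treated, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      group = character(), timepoint_h = numeric(),
      viability_pct = numeric(), se_pct = numeric(), n_wells = integer()
    ))
  }
  do.call(rbind, out)
}
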