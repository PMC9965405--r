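#' Seeded synthetic release curves
#'
#' Evaluates one of the four kinetic models on a time grid and adds
#' additive Gaussian noise in percentage points (optionally with a
#' proportional component), emulating the burst-then-plateau shape of a
#' cumulative release experiment. Output is a deterministic function of
#' the arguments and `seed`.
#'
#' @param model Model name (see [kinetic_models]).
#' @param params Named parameter vector for that model (e.g.
#'   `c(Qmax = 83, alpha = 0.83, beta = -2.7)`).
#' @param times Explicit time grid in hours; overrides the grid spec.
#' @param n_times,t_range,spacing Grid spec: number of points, range in
#'   hours, `"log"` (default) or `"linear"` spacing. The default grid, 12
#'   log-spaced points in 0.5–170 h, mirrors a week-long release
#'   experiment sampled densely early on.
#' @param sigma Additive Gaussian noise SD, percentage points (default 2).
#' @param prop_sigma Optional proportional noise SD (fraction of the
#'   model value), default 0.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param clip Optional length-2 numeric bounds to truncate noisy values
#'   to a physical range, e.g. `c(0, 105)`; `NULL` (default) disables
#'   clipping.
#' @param medium Medium label attached to the curve.
#' @return A [release_curve()].
#' @examples
#' generate_release_curve(
#'   model = "gompertz",
#'   params = c(Qmax = 83, alpha = 0.83, beta = -2.7), sigma = 2, seed = 1
#' )
#' @export
generate_release_curve <- function(model,
                                   params,
                                   times = NULL,
                                   n_times = 12,
                                   t_range = c(0.5, 170),
                                   spacing = c("log", "linear"),
                                   sigma = 2,
                                   prop_sigma = 0,
                                   seed = NULL,
                                   clip = NULL,
                                   medium = "synthetic") {
  spacing <- match.arg(spacing)
  spec <- kinetic_model_spec(model)
  if (!all(spec$params %in% names(params))) {
    stop(sprintf(
      "model '%s' needs parameters: %s", spec$name,
      paste(spec$params, collapse = ", ")
    ), call. = FALSE)
  }
  if (sigma < 0 || prop_sigma < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (is.null(times)) {
    times <- if (spacing == "log") {
      if (any(t_range <= 0)) {
        stop("log spacing requires a positive time range", call. = FALSE)
      }
      exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_times))
    } else {
      seq(t_range[1], t_range[2], length.out = n_times)
    }
  }
  if (spec$needs_positive_t && any(times <= 0)) {
    stop(sprintf("model '%s' requires times > 0", spec$name), call. = FALSE)
  }
  q <- spec$fn(times, as.list(params))
  if (sigma > 0 || prop_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, sigma) +
      if (prop_sigma > 0) stats::rnorm(length(q), 0, prop_sigma * abs(q)) else 0
  }
  if (!is.null(clip)) q <- pmin(pmax(q, clip[1]), clip[2])
  release_curve(times, q, medium = medium)
}

#' Exact plane-sheet release series
#'
#' Full eigenfunction solution for Fickian release from a plane sheet of
#' half-thickness `L` (release from both faces, constant diffusivity):
#' \deqn{M_t/M_\infty = 1 - \sum_{m \ge 0} \frac{8}{(2m+1)^2 \pi^2}
#'   \exp\!\left[-\frac{(2m+1)^2 \pi^2 D t}{4 L^2}\right].}
#' The short-time square-root law and the long-time single exponential
#' are this series' two asymptotic regimes, which makes it the natural
#' independent check for the diffusion estimators. Terms are added until
#' the dropped tail is below 1e-10 (starting from `n_terms`, doubling as
#' needed); \eqn{t = 0} returns exactly zero.
#'
#' @param D Diffusion coefficient, cm^2/s, positive.
#' @param L Half-thickness, cm, positive.
#' @param times_h Times in hours, non-negative, strictly increasing.
#' @param n_terms Initial number of series terms (default 200).
#' @param m_inf Scale of the output curve in percent (default 100).
#' @return A [release_curve()] with `q_pct = m_inf * Mt/Minf`.
#' @export
generate_fickian_series_curve <- function(D, L, times_h, n_terms = 200,
                                          m_inf = 100) {
  if (!is.finite(D) || D <= 0) stop("'D' must be positive", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  if (n_terms < 1) stop("'n_terms' must be >= 1", call. = FALSE)
  check_time_nonneg(times_h)
  t_s <- times_h * 3600
  frac <- vapply(t_s, function(ts) {
    if (ts == 0) {
      return(0)
    }
    nt <- n_terms
    repeat {
      m <- 0:(nt - 1)
      lam <- (2 * m + 1)^2 * pi^2
      terms <- (8 / lam) * exp(-lam * D * ts / (4 * L^2))
      # remaining tail is bounded by the next term times a convergent factor
      next_term <- (8 / ((2 * nt + 1)^2 * pi^2)) *
        exp(-(2 * nt + 1)^2 * pi^2 * D * ts / (4 * L^2))
      if (next_term < 1e-10 || nt >= 2^20) break
      nt <- nt * 2L
    }
    max(0, min(1, 1 - sum(terms)))
  }, numeric(1))
  release_curve(times_h, m_inf * frac, medium = "fickian_series")
}

#' Synthetic rough surface profile with a target Ra
#'
#' Generates a smoothed Gaussian random field (white noise convolved with
#' a Gaussian kernel) and linearly rescales its deviations from the mean
#' line so the computed Ra equals `target_ra` exactly (the metric is
#' linear in the deviations).
#'
#' @param target_ra Desired Ra, in z units (gray levels), non-negative.
#' @param n Number of samples, at least 2.
#' @param seed Integer RNG seed.
#' @param correlation_length Gaussian smoothing kernel SD, samples.
#' @param mean_level Mean line of the output profile.
#' @return A [surface_profile()].
#' @export
generate_surface_profile <- function(target_ra, n, seed = NULL,
                                     correlation_length = 10,
                                     mean_level = 128) {
  if (!is.finite(target_ra) || target_ra < 0) {
    stop("'target_ra' must be non-negative", call. = FALSE)
  }
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (target_ra == 0) {
    return(surface_profile(seq_len(n), rep(mean_level, n)))
  }
  half <- ceiling(3 * correlation_length)
  kern <- stats::dnorm(-half:half, sd = correlation_length)
  kern <- kern / sum(kern)
  noise <- stats::rnorm(n + 2 * half)
  z <- stats::filter(noise, kern, sides = 2)
  z <- as.numeric(z[(half + 1):(half + n)])
  dev <- z - mean(z)
  ra <- mean(abs(dev))
  if (ra == 0) dev <- rep(c(-1, 1), length.out = n) - mean(rep(c(-1, 1), length.out = n))
  dev <- dev * target_ra / mean(abs(dev))
  surface_profile(seq_len(n), mean_level + dev)
}

#' Synthetic irradiation series
#'
#' Power-law photodegradation series with optional additive Gaussian
#' noise, seeded.
#'
#' @param qmax Non-irradiated released amount, percent.
#' @param b Power-law exponent.
#' @param times Irradiation times in hours, starting at 0; default the
#'   0–10 h horizon of a UV stress test.
#' @param sigma Additive noise SD, percentage points.
#' @param seed Integer RNG seed.
#' @return An [irradiation_series()].
#' @export
generate_irradiation_series <- function(qmax, b,
                                        times = c(0, 0.5, 1, 2, 5, 10),
                                        sigma = 0, seed = NULL) {
  q <- photolaw_q(times, qmax, b)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- pmax(q + stats::rnorm(length(q), 0, sigma), 1e-6)
  }
  irradiation_series(times, q)
}

#' Synthetic MTT plate
#'
#' Emulates a viability plate: untreated wells at a baseline corrected
#' signal (default 0.65 = 0.70 signal over 0.05 background), treated
#' groups scaled by their viability effect, with Gaussian well-to-well
#' noise. Seeded and deterministic.
#'
#' @param groups Character vector of treated group names.
#' @param effects Viability fractions in [0, 1.2], one per group.
#' @param n_wells Wells per group (including untreated), at least 1.
#' @param timepoint_h Timepoint label, hours.
#' @param seed Integer RNG seed.
#' @param baseline_a595,background_a655 Untreated plate means.
#' @param noise_sd Well noise SD on a595 (background noise is a tenth).
#' @return Data frame with columns `well_id`, `group`, `timepoint_h`,
#'   `a595`, `a655`.
#' @export
generate_plate <- function(groups, effects, n_wells = 3, timepoint_h = 24,
                           seed = NULL, baseline_a595 = 0.70,
                           background_a655 = 0.05, noise_sd = 0.02) {
  if (length(groups) != length(effects)) {
    stop("'groups' and 'effects' must have equal length", call. = FALSE)
  }
  if (any(effects < 0 | effects > 1.2)) {
    stop("'effects' must lie in [0, 1.2]", call. = FALSE)
  }
  if (n_wells < 1) stop("'n_wells' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  all_groups <- c("untreated", groups)
  all_effects <- c(1, effects)
  rows <- lapply(seq_along(all_groups), function(i) {
    signal <- background_a655 +
      all_effects[i] * (baseline_a595 - background_a655)
    data.frame(
      well_id = sprintf("%s_w%d", all_groups[i], seq_len(n_wells)),
      group = all_groups[i],
      timepoint_h = timepoint_h,
      a595 = pmax(signal + stats::rnorm(n_wells, 0, noise_sd), 0),
      a655 = pmax(
        background_a655 + stats::rnorm(n_wells, 0, noise_sd / 10), 0
      ),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
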