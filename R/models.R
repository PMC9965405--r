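#' Dissolution model equations
#'
#' The four classical cumulative-release laws used to describe drug release
#' from a polymeric matrix, all returning cumulative percent released:
#'
#' * zero-order: \eqn{Q = K_0 t} — constant-rate release;
#' * Higuchi: \eqn{Q = K_H \sqrt{t}} — diffusion from a planar matrix;
#' * Korsmeyer–Peppas: \eqn{Q = K_R t^n} — empirical power law whose
#'   exponent diagnoses the transport mechanism (\eqn{n \le 0.5} indicates
#'   Fickian diffusion from a thin film);
#' * Gompertz: \eqn{Q = Q_{max} \exp[-\alpha \exp(\beta \log_{10} t)]} — a
#'   sigmoid with a plateau at \eqn{Q_{max}}; \eqn{\beta} (negative for a
#'   release curve) is the dissolution-rate shape parameter per decade of
#'   time. The base-10 logarithm is the dissolution-literature convention
#'   and is what this package uses throughout.
#'
#' @param t Time in hours. Must be non-negative (strictly positive for the
#'   Gompertz model, whose log term is undefined at zero).
#' @param k0,kH,kR Kinetic constants in %/h, %/h^0.5 and %/h^n.
#' @param n Release exponent, dimensionless, must be positive.
#' @param qmax Plateau release, percent, must be positive.
#' @param alpha Gompertz scale parameter, dimensionless, positive for a
#'   physically meaningful curve.
#' @param beta Gompertz shape parameter, dimensionless; negative values give
#'   a curve rising towards `qmax`.
#'
#' @return Cumulative percent released, same length as `t`.
#' @examples
#' zero_order_q(10, 0.66)
#' higuchi_q(4, 9.49)
#' korsmeyer_peppas_q(4, 48.60, 0.13)
#' gompertz_q(50, 83, 0.83, -2.7)
#' @name kinetic_models
NULL

check_time_nonneg <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be finite and non-negative", call. = FALSE)
  }
  invisible(t)
}

#' @rdname kinetic_models
#' @export
zero_order_q <- function(t, k0) {
  check_time_nonneg(t)
  k0 * t
}

#' @rdname kinetic_models
#' @export
higuchi_q <- function(t, kH) {
  check_time_nonneg(t)
  kH * sqrt(t)
}

#' @rdname kinetic_models
#' @export
korsmeyer_peppas_q <- function(t, kR, n) {
  check_time_nonneg(t)
  if (!is.finite(n) || n <= 0) {
    stop("release exponent 'n' must be positive", call. = FALSE)
  }
  kR * t^n
}

#' @rdname kinetic_models
#' @export
gompertz_q <- function(t, qmax, alpha, beta) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("Gompertz model requires t > 0 (log10 undefined at 0)",
      call. = FALSE
    )
  }
  if (!is.finite(qmax) || qmax <= 0) {
    stop("'qmax' must be positive", call. = FALSE)
  }
  qmax * exp(-alpha * exp(beta * log10(t)))
}

# Registry of fittable models: parameter names, bounds and the
# deterministic initialisation rule used by fit_release_model().
kinetic_model_spec <- function(name) {
  name <- match.arg(name, c(
    "zero_order", "gompertz", "higuchi",
    "korsmeyer_peppas"
  ))
  switch(name,
    zero_order = list(
      name = "zero_order", params = "K0", n_params = 1L,
      fn = function(t, p) zero_order_q(t, p[["K0"]]),
      needs_positive_t = FALSE
    ),
    higuchi = list(
      name = "higuchi", params = "KH", n_params = 1L,
      fn = function(t, p) higuchi_q(t, p[["KH"]]),
      needs_positive_t = FALSE
    ),
    korsmeyer_peppas = list(
      name = "korsmeyer_peppas", params = c("KR", "n"), n_params = 2L,
      fn = function(t, p) korsmeyer_peppas_q(t, p[["KR"]], p[["n"]]),
      lower = c(KR = 1e-9, n = 1e-6),
      upper = c(KR = Inf, n = 1),
      needs_positive_t = TRUE
    ),
    gompertz = list(
      name = "gompertz", params = c("Qmax", "alpha", "beta"), n_params = 3L,
      fn = function(t, p) gompertz_q(t, p[["Qmax"]], p[["alpha"]], p[["beta"]]),
      lower = c(Qmax = 1e-6, alpha = 1e-6, beta = -Inf),
      upper = c(Qmax = 110, alpha = Inf, beta = Inf),
      needs_positive_t = TRUE
    )
  )
}

kinetic_model_names <- function() {
  c("zero_order", "gompertz", "higuchi", "korsmeyer_peppas")
}
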