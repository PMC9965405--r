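#' Coefficient of determination against the mean baseline
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with \eqn{SS_{tot}} taken about the
#' mean of the observations. The mean baseline is used for every model,
#' including no-intercept ones, so a model that fits worse than a flat line
#' at the observed mean yields a negative value — release data near a
#' plateau routinely produce \eqn{R^2 < 0} for the zero-order and Higuchi
#' laws.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 2).
#' @return A single numeric value, at most 1, unbounded below.
#' @examples
#' r_squared(c(0, 10), c(10, 0)) # -3
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("all observations identical: R^2 undefined (zero total sum of squares)",
      call. = FALSE
    )
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# Deterministic starting values, one rule per model (no random restarts):
#   Qmax0 = max(q); alpha0 from the earliest positive-time point via
#   alpha = -ln(q/Qmax0); beta0 = -1; K0/KH/KR by linear regression in the
#   transformed coordinate; n0 = 0.5.
fit_start_values <- function(name, t, q) {
  switch(name,
    zero_order = c(K0 = sum(q * t) / sum(t^2)),
    higuchi = c(KH = sum(q * sqrt(t)) / sum(t)),
    korsmeyer_peppas = c(KR = max(sum(q * sqrt(t)) / sum(t), 1e-6), n = 0.5),
    gompertz = {
      qmax0 <- max(q)
      q1 <- max(q[which.min(t)], 1e-3)
      alpha0 <- -log(min(q1 / qmax0, 0.999))
      c(Qmax = qmax0, alpha = max(alpha0, 1e-3), beta = -1)
    }
  )
}

#' Fit one dissolution model to a release curve
#'
#' Bounded nonlinear least squares (Levenberg–Marquardt via
#' \pkg{minpack.lm}) with a deterministic initialisation rule, so repeated
#' fits of the same data are identical. The one-parameter zero-order and
#' Higuchi models are solved in closed form (they are linear in their
#' single constant). Points at `t = 0` are excluded from Gompertz and
#' Korsmeyer–Peppas fits, where the model (or its log-space
#' initialisation) is undefined, and the exclusion is recorded.
#'
#' Parameter bounds enforce physical positivity: `K0, KH, KR > 0`,
#' `0 < Qmax <= 110` (headroom above 100 for noisy plateaus), `alpha > 0`,
#' `0 < n <= 1` (Fickian through Case-II transport); `beta` is
#' unconstrained in sign.
#'
#' @param curve A [release_curve()].
#' @param model Model name: one of `"zero_order"`, `"gompertz"`,
#'   `"higuchi"`, `"korsmeyer_peppas"`.
#' @return An object of class `release_fit` with elements `model`,
#'   `params` (named numeric), `r2`, `fitted`, `residuals`, `n_obs`,
#'   `converged`, `diagnostics`, `n_excluded_t0` and the data actually
#'   fitted. Non-convergent fits carry their diagnostics rather than
#'   silent `NaN` parameters.
#' @examples
#' rc <- generate_release_curve(
#'   model = "gompertz", params = c(Qmax = 83, alpha = 0.83, beta = -2.7),
#'   n_times = 12, t_range = c(0.5, 170), sigma = 0
#' )
#' fit <- fit_release_model(rc, "gompertz")
#' fit$params
#' @seealso [compare_models()], [predict.release_fit()]
#' @export
fit_release_model <- function(curve, model) {
  assert_release_curve(curve)
  spec <- kinetic_model_spec(model)
  t <- curve$time_h
  q <- curve$q_pct

  n_excluded_t0 <- 0L
  if (spec$needs_positive_t && any(t == 0)) {
    n_excluded_t0 <- sum(t == 0)
    keep <- t > 0
    t <- t[keep]
    q <- q[keep]
  }
  if (length(t) < spec$n_params + 1L) {
    stop(sprintf(
      "model '%s' needs at least %d points (after any t=0 exclusion), got %d",
      spec$name, spec$n_params + 1L, length(t)
    ), call. = FALSE)
  }
  if (spec$n_params >= 2L && length(unique(q)) == 1L) {
    stop(sprintf(
      "degenerate curve (all q identical) rejected for model '%s'",
      spec$name
    ), call. = FALSE)
  }

  start <- fit_start_values(spec$name, t, q)
  converged <- TRUE
  diagnostics <- "closed-form least squares"
  params <- start

  if (spec$n_params > 1L) {
    df <- data.frame(t = t, q = q)
    formula <- switch(spec$name,
      korsmeyer_peppas = q ~ KR * t^n,
      gompertz = q ~ Qmax * exp(-alpha * exp(beta * log10(t)))
    )
    fit <- tryCatch(
      minpack.lm::nlsLM(formula,
        data = df, start = as.list(start),
        lower = spec$lower[spec$params], upper = spec$upper[spec$params],
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-13, ptol = 1e-13
        )
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      converged <- FALSE
      diagnostics <- conditionMessage(fit)
      params <- start # best available: deterministic starting values
    } else {
      info <- fit$convInfo
      converged <- isTRUE(info$isConv) || (info$stopCode %in% 1:4)
      diagnostics <- if (converged) "converged" else info$stopMessage
      params <- stats::coef(fit)
    }
  } else {
    # closed-form solutions can only violate positivity on pathological data
    if (params <= 0) {
      converged <- FALSE
      diagnostics <- "non-physical (non-positive) rate constant"
    }
  }

  fitted_vals <- spec$fn(t, as.list(params))
  r2 <- if (stats::var(q) > 0) r_squared(q, fitted_vals) else NA_real_
  structure(
    list(
      model = spec$name,
      params = params,
      r2 = r2,
      fitted = fitted_vals,
      residuals = q - fitted_vals,
      n_obs = length(t),
      n_excluded_t0 = n_excluded_t0,
      converged = converged,
      diagnostics = diagnostics,
      time_h = t,
      q_pct = q,
      medium = attr(curve, "medium")
    ),
    class = "release_fit"
  )
}

#' Predict from a fitted dissolution model
#'
#' Predictions regenerate exactly from the stored parameters: calling
#' `predict` at the fitted times reproduces `fit$fitted` bit-identically.
#'
#' @param object A `release_fit`.
#' @param newdata Optional numeric vector of times in hours (defaults to
#'   the fitted times).
#' @param ... Unused.
#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_h else as.numeric(newdata)
  kinetic_model_spec(object$model)$fn(t, as.list(object$params))
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit (%s): R^2 = %.4g, %d points%s\n", x$model,
    if (x$converged) "converged" else "NOT converged", x$r2, x$n_obs,
    if (x$n_excluded_t0 > 0) {
      sprintf(" (%d t=0 point(s) excluded)", x$n_excluded_t0)
    } else ""
  ))
  print(round(x$params, 6))
  if (!x$converged) cat("  diagnostics:", x$diagnostics, "\n")
  invisible(x)
}

#' Fit and rank several dissolution models on one curve
#'
#' Fits each requested model with [fit_release_model()] and ranks the
#' results by decreasing \eqn{R^2}. A model that fails to fit does not
#' abort the others; its error message is kept as a diagnostic and it is
#' ranked last. Ties in \eqn{R^2} are broken by fewer parameters, then by
#' model name.
#'
#' @param curve A [release_curve()].
#' @param models Character vector of model names; default all four.
#' @return An object of class `model_comparison`: a list with `fits` (the
#'   per-model `release_fit` objects or error stubs, in ranked order) and
#'   `table`, a ranked data frame with one row per model.
#' @examples
#' rc <- generate_release_curve(
#'   model = "gompertz", params = c(Qmax = 83, alpha = 0.83, beta = -2.7),
#'   n_times = 12, t_range = c(0.5, 170), sigma = 2, seed = 7
#' )
#' compare_models(rc)
#' @export
compare_models <- function(curve, models = kinetic_model_names()) {
  assert_release_curve(curve)
  if (length(models) < 1L) stop("need at least one model", call. = FALSE)
  fits <- lapply(models, function(m) {
    tryCatch(fit_release_model(curve, m), error = function(e) {
      structure(
        list(
          model = m, params = NULL, r2 = NA_real_, n_obs = nrow(curve),
          converged = FALSE, diagnostics = conditionMessage(e),
          medium = attr(curve, "medium")
        ),
        class = c("release_fit_error", "release_fit")
      )
    })
  })
  n_par <- vapply(
    models, function(m) kinetic_model_spec(m)$n_params, integer(1)
  )
  r2 <- vapply(fits, function(f) f$r2 %||% NA_real_, numeric(1))
  ord <- order(-ifelse(is.na(r2), -Inf, r2), n_par, models)
  fits <- fits[ord]
  tab <- data.frame(
    rank = seq_along(fits),
    model = models[ord],
    n_params = n_par[ord],
    r2 = r2[ord],
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(fits = fits, table = tab, medium = attr(curve, "medium")),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (medium '%s'):\n", x$medium))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Long-format report table of a model comparison
#'
#' One row per fitted parameter (plus an `R2` row per model), the layout
#' conventionally used to report dissolution-model parameters side by
#' side.
#'
#' @param comparison A `model_comparison`.
#' @return A data frame with columns `medium`, `model`, `parameter`,
#'   `value`, `converged`.
#' @export
comparison_report <- function(comparison) {
  stopifnot(inherits(comparison, "model_comparison"))
  rows <- lapply(comparison$fits, function(f) {
    pr <- if (is.null(f$params)) {
      data.frame(parameter = character(), value = numeric())
    } else {
      data.frame(
        parameter = names(f$params), value = unname(f$params),
        stringsAsFactors = FALSE
      )
    }
    pr <- rbind(pr, data.frame(parameter = "R2", value = f$r2))
    pr$model <- f$model
    pr$converged <- isTRUE(f$converged)
    pr
  })
  out <- do.call(rbind, rows)
  out$medium <- comparison$medium
  out[, c("medium", "model", "parameter", "value", "converged")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
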