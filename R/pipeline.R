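#' Run the full release-analysis pipeline
#'
#' Sequences the whole analysis on one or more release curves: fits and
#' ranks the kinetic models per medium, estimates short- and long-time
#' diffusion coefficients when a membrane thickness is supplied, fits the
#' photodegradation power law when an irradiation series is supplied, and
#' writes a CSV + JSON report bundle. Stage failures are isolated: a
#' failing stage is recorded in `$errors` and the remaining stages still
#' run.
#'
#' @param config A named list (or path to a YAML/JSON file readable by
#'   [read_pipeline_config()]) with elements:
#' \describe{
#'   \item{release_csv}{character vector of release-curve CSV paths, or}
#'   \item{curves}{a list of [release_curve()] objects (alternative to
#'     `release_csv`);}
#'   \item{models}{model names to fit (default all four);}
#'   \item{thickness_cm}{measured full mat thickness in cm; halved
#'     internally for the plane-sheet half-thickness (optional);}
#'   \item{m_inf_policy}{`"gompertz"` (default), `"last"` or `"value"`
#'     (with `m_inf`);}
#'   \item{short_cutoff, long_floor}{regime boundaries (defaults 0.6,
#'     0.4);}
#'   \item{irradiation_csv}{optional irradiation-series CSV path;}
#'   \item{out_prefix}{output path prefix for [write_report()]
#'     (optional: no files written when absent);}
#'   \item{seed}{integer seed recorded in the report metadata.}
#' }
#' @return A list of class `relkin_pipeline`: `comparisons`, `diffusion`,
#'   `photo`, `errors`, `paths` (written files) and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  curves <- config$curves
  if (is.null(curves) && !is.null(config$release_csv)) {
    curves <- lapply(config$release_csv, function(p) {
      tryCatch(read_release_csv(p), error = function(e) note(paste0("read:", p), e))
    })
    curves <- Filter(Negate(is.null), curves)
  }
  if (is.null(curves) || length(curves) == 0L) {
    stop("pipeline config supplies no release curves", call. = FALSE)
  }

  models <- config$models %||% kinetic_model_names()
  comparisons <- lapply(curves, function(cv) {
    tryCatch(compare_models(cv, models),
      error = function(e) note(paste0("fit:", attr(cv, "medium")), e)
    )
  })
  comparisons <- Filter(Negate(is.null), comparisons)

  diffusion <- NULL
  if (!is.null(config$thickness_cm)) {
    L <- config$thickness_cm / 2 # half-thickness: release from both faces
    cutoff <- config$short_cutoff %||% 0.6
    floor_ <- config$long_floor %||% 0.4
    diffusion <- list()
    for (cv in curves) {
      med <- attr(cv, "medium")
      est <- tryCatch(
        {
          mi <- m_inf_value(cv,
            policy = config$m_inf_policy %||% "gompertz",
            value = config$m_inf
          )
          list(
            short = estimate_D_short(cv, L, mi$m_inf, cutoff = cutoff),
            long = estimate_D_long(cv, L, mi$m_inf, floor = floor_),
            m_inf_policy = mi$policy
          )
        },
        error = function(e) note(paste0("diffusion:", med), e)
      )
      if (!is.null(est)) diffusion[[med]] <- est
    }
  }

  photo <- NULL
  if (!is.null(config$irradiation_csv)) {
    photo <- tryCatch(
      fit_photolaw(read_irradiation_csv(config$irradiation_csv)),
      error = function(e) note("photostability", e)
    )
  } else {
    message("no irradiation series supplied: photostability stage skipped")
  }

  paths <- NULL
  if (!is.null(config$out_prefix)) {
    flat_diff <- if (!is.null(diffusion)) {
      unlist(lapply(names(diffusion), function(m) {
        stats::setNames(
          diffusion[[m]][c("short", "long")],
          paste(m, c("short", "long"), sep = "_")
        )
      }), recursive = FALSE)
    }
    paths <- tryCatch(
      write_report(comparisons, config$out_prefix,
        diffusion = flat_diff, photo = photo,
        meta = list(seed = config$seed, config = config[
          setdiff(names(config), "curves")
        ])
      ),
      error = function(e) note("report", e)
    )
  }

  structure(
    list(
      comparisons = comparisons, diffusion = diffusion, photo = photo,
      errors = errors, paths = paths, config = config
    ),
    class = "relkin_pipeline"
  )
}

#' @export
print.relkin_pipeline <- function(x, ...) {
  cat(sprintf(
    "relkin pipeline: %d curve(s), %d error(s)\n",
    length(x$comparisons), length(x$errors)
  ))
  for (cmp in x$comparisons) print(cmp)
  if (length(x$errors)) {
    cat("Stage errors:\n")
    for (s in names(x$errors)) cat(sprintf("  %s: %s\n", s, x$errors[[s]]))
  }
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`, requires the \pkg{yaml} package) or JSON.
#'
#' @param path Config file path.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
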