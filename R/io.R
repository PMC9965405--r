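# CSV dialects: UTF-8, decimal point, '#' comment lines skipped.

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path,
    comment.char = "#", strip.white = TRUE,
    stringsAsFactors = FALSE
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf(
      "%s: missing required column(s): %s", path,
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf(
        "%s: non-numeric '%s' value(s) at data row(s) %s", path, col,
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    df[[col]] <- vals
  }
  df
}

#' Read and write release-curve CSV files
#'
#' Dialect: header `time_h,q_pct` with optional `medium` and `replicate`
#' columns; UTF-8, decimal point, lines starting with `#` skipped. The
#' write/read pair round-trips a curve exactly.
#'
#' @param path File path.
#' @return `read_release_csv`: a [release_curve()] (empty, with a
#'   warning, for a headered but empty file).
#' @export
read_release_csv <- function(path) {
  df <- read_checked_csv(path, c("time_h", "q_pct"), c("time_h", "q_pct"))
  medium <- if ("medium" %in% names(df) && nrow(df) > 0) {
    df$medium[1]
  } else {
    "unspecified"
  }
  replicate <- if ("replicate" %in% names(df) && nrow(df) > 0) {
    as.integer(df$replicate[1])
  } else {
    NA_integer_
  }
  if (nrow(df) == 0L) {
    warning(sprintf("%s: no data rows; empty curve", path), call. = FALSE)
    return(suppressWarnings(
      release_curve(numeric(0), numeric(0), medium = medium)
    ))
  }
  release_curve(df$time_h, df$q_pct, medium = medium, replicate = replicate)
}

#' @rdname read_release_csv
#' @param curve A [release_curve()].
#' @export
write_release_csv <- function(curve, path) {
  assert_release_curve(curve)
  # 17 significant digits so that read(write(x)) is bit-exact for doubles
  df <- data.frame(
    time_h = sprintf("%.17g", curve$time_h),
    q_pct = sprintf("%.17g", curve$q_pct),
    medium = attr(curve, "medium"), replicate = attr(curve, "replicate")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an irradiation-series CSV (`t_irr_h,q24_pct`)
#' @param path File path.
#' @return An [irradiation_series()].
#' @export
read_irradiation_csv <- function(path) {
  df <- read_checked_csv(path, c("t_irr_h", "q24_pct"), c("t_irr_h", "q24_pct"))
  irradiation_series(df$t_irr_h, df$q24_pct)
}

#' Read a surface-profile CSV (`x,z`)
#' @param path File path.
#' @return A [surface_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- read_checked_csv(path, c("x", "z"), c("x", "z"))
  surface_profile(df$x, df$z)
}

#' Read a retention CSV (`sample,medium,m0_g,meq_g`)
#' @param path File path.
#' @return The data frame with an added `q_signed_pct` column.
#' @export
read_retention_csv <- function(path) {
  df <- read_checked_csv(
    path, c("sample", "medium", "m0_g", "meq_g"), c("m0_g", "meq_g")
  )
  df$q_signed_pct <- retention_signed(df$m0_g, df$meq_g)
  df
}

#' Read an MTT plate CSV (`well_id,group,timepoint_h,a595,a655`)
#' @param path File path.
#' @return The plate data frame.
#' @export
read_plate_csv <- function(path) {
  read_checked_csv(
    path, c("well_id", "group", "timepoint_h", "a595", "a655"),
    c("timepoint_h", "a595", "a655")
  )
}

#' Write an analysis report bundle
#'
#' Writes the kinetic-model comparison as a long-format CSV (model,
#' parameter, value per medium) and the full results — fits, diffusion
#' estimates, photodegradation fit, run metadata — as one JSON file.
#'
#' @param comparisons A list of `model_comparison` objects (one per
#'   medium), or a single one.
#' @param path_prefix Output path prefix; `<prefix>_fits.csv` and
#'   `<prefix>.json` are written.
#' @param diffusion Optional list of `diffusion_estimate` objects.
#' @param photo Optional `photo_fit`.
#' @param meta Optional named list of run metadata (seed, config, ...).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(comparisons, path_prefix, diffusion = NULL,
                         photo = NULL, meta = NULL) {
  if (inherits(comparisons, "model_comparison")) {
    comparisons <- list(comparisons)
  }
  tab <- do.call(rbind, lapply(comparisons, comparison_report))
  csv_path <- paste0(path_prefix, "_fits.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)

  payload <- list(
    meta = c(
      list(package = "relkin", version = as.character(
        utils::packageVersion("relkin")
      )),
      meta
    ),
    fits = lapply(comparisons, function(cmp) {
      list(
        medium = cmp$medium,
        table = cmp$table,
        models = lapply(cmp$fits, function(f) {
          list(
            model = f$model, params = as.list(f$params), r2 = f$r2,
            converged = isTRUE(f$converged), diagnostics = f$diagnostics,
            n_obs = f$n_obs
          )
        })
      )
    }),
    diffusion = if (!is.null(diffusion)) {
      lapply(diffusion, function(d) unclass(d))
    },
    photostability = if (!is.null(photo)) {
      list(qmax = photo$qmax, b = photo$b, r2 = photo$r2)
    }
  )
  json_path <- paste0(path_prefix, ".json")
  jsonlite::write_json(payload, json_path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(c(csv = csv_path, json = json_path))
}
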