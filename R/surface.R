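#' Sampled surface profile
#'
#' A uniformly sampled height (or grayscale-intensity) trace along a line,
#' as produced by profilometry or by averaging a band of rows of an SEM
#' image. Positions must be strictly increasing with uniform spacing; the
#' evaluation length is the sampled span.
#'
#' @param x Sampled positions (pixels or micrometres), strictly
#'   increasing, uniformly spaced (relative tolerance 1e-9).
#' @param z Height or intensity values (gray levels 0-255 when
#'   image-derived).
#' @return An object of class `surface_profile` (a data frame with
#'   attribute `evaluation_length`).
#' @export
surface_profile <- function(x, z) {
  x <- as.numeric(x)
  z <- as.numeric(z)
  if (length(x) != length(z)) {
    stop("'x' and 'z' must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(x) || anyNA(z) || any(!is.finite(c(x, z)))) {
    stop("profile values must be finite", call. = FALSE)
  }
  dx <- diff(x)
  if (any(dx <= 0)) stop("'x' must be strictly increasing", call. = FALSE)
  if (diff(range(dx)) > 1e-9 * mean(dx)) {
    stop("'x' must be uniformly spaced (relative tolerance 1e-9)",
      call. = FALSE
    )
  }
  out <- data.frame(x = x, z = z)
  attr(out, "evaluation_length") <- x[length(x)] - x[1]
  class(out) <- c("surface_profile", "data.frame")
  out
}

#' Mean-line roughness metrics Ra and RMS
#'
#' Deviations are taken from the mean line (the arithmetic mean of the
#' profile) before averaging, so a flat but offset profile has zero
#' roughness:
#' \deqn{R_a = \frac{1}{L}\int_0^L |Z(x) - \bar Z| \, dx, \qquad
#'       RMS = \left[\frac{1}{L}\int_0^L (Z(x) - \bar Z)^2 \, dx\right]^{1/2}.}
#' On a uniform grid both integrals reduce to simple arithmetic means over
#' the samples (midpoint rule); no filtering or windowing is applied. By
#' the power-mean inequality `rms >= ra` always, with equality when all
#' absolute deviations are equal.
#'
#' @param profile A [surface_profile()].
#' @return An object of class `roughness_result`: list with `ra`, `rms`
#'   and `mean_line`, in the units of `z`.
#' @examples
#' p <- surface_profile(1:4, c(1, 2, 3, 6))
#' roughness(p) # ra 1.5, rms ~1.871
#' @export
roughness <- function(profile) {
  if (!inherits(profile, "surface_profile")) {
    stop("expected a 'surface_profile'; see surface_profile()", call. = FALSE)
  }
  mean_line <- mean(profile$z)
  dev <- profile$z - mean_line
  structure(
    list(
      ra = mean(abs(dev)),
      rms = sqrt(mean(dev^2)),
      mean_line = mean_line
    ),
    class = "roughness_result"
  )
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf(
    "Ra = %.4g, RMS = %.4g (mean line %.4g)\n", x$ra, x$rms, x$mean_line
  ))
  invisible(x)
}

#' Extract an intensity profile from a band of image rows
#'
#' Emulates the plot-profile operation on a grayscale image: the profile
#' is the column-wise mean of the selected rows, with pixel column indices
#' as positions.
#'
#' @param gray_matrix Numeric matrix of gray levels (rows = image rows).
#' @param row_band Integer vector of row indices to average; default the
#'   single middle row.
#' @return A [surface_profile()] with `x` the column indices.
#' @export
profile_from_image_row <- function(gray_matrix,
                                   row_band = ceiling(nrow(gray_matrix) / 2)) {
  if (!is.matrix(gray_matrix) || !is.numeric(gray_matrix)) {
    stop("'gray_matrix' must be a numeric matrix", call. = FALSE)
  }
  row_band <- as.integer(row_band)
  if (length(row_band) == 0L) stop("empty row band", call. = FALSE)
  if (any(row_band < 1L) || any(row_band > nrow(gray_matrix))) {
    stop("row band outside matrix bounds", call. = FALSE)
  }
  z <- colMeans(gray_matrix[row_band, , drop = FALSE])
  surface_profile(seq_len(ncol(gray_matrix)), z)
}

#' Read a grayscale image as a 0-255 gray-level matrix
#'
#' Convenience reader for PNG (via \pkg{png}) or TIFF (via \pkg{tiff})
#' micrographs; multi-channel images are averaged to one gray channel.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @return Numeric matrix of gray levels in 0-255.
#' @export
read_gray_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format (expect .png or .tif/.tiff)",
      call. = FALSE
    )
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img * 255
}
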