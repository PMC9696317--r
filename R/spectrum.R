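#' Construct a spectrum
#'
#' The universal carrier for all FTIR operations: a pair of equal-length
#' numeric vectors, wavenumber (cm\eqn{^{-1}}, strictly increasing) and
#' absorbance (a.u.).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm\eqn{^{-1}}.
#'   Strictly increasing after construction; a strictly decreasing input
#'   (common for FTIR instrument exports) is reversed with a message.
#' @param absorbance Numeric vector of absorbance values, same length.
#' @return An object of class \code{"spectrum"}: a list with elements
#'   \code{wavenumbers} and \code{absorbance}.
#' @examples
#' s <- spectrum(1600:1700, exp(-((1600:1700 - 1655) / 10)^2))
#' s
#' @export
spectrum <- function(wavenumbers, absorbance) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  if (length(wavenumbers) < 3)
    stop("a spectrum needs at least 3 points", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(absorbance) ||
      !all(is.finite(wavenumbers)) || !all(is.finite(absorbance)))
    stop("spectrum values must be finite and non-missing", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    message("descending wavenumber axis reversed to ascending")
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, absorbance = x$absorbance)
}

#' @export
length.spectrum <- function(x) length(x$wavenumbers)

#' @export
plot.spectrum <- function(x, ..., xlab = expression(Wavenumber ~ (cm^-1)),
                          ylab = "Absorbance (a.u.)", type = "l") {
  graphics::plot(x$wavenumbers, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Define a spectral band region
#'
#' @param low,high Region bounds in cm\eqn{^{-1}}, \code{low < high}.
#' @param name Optional label, e.g. \code{"amide_I"}.
#' @return An object of class \code{"band_region"}.
#' @examples
#' band_region(1618, 1696, "amide_I")
#' @export
band_region <- function(low, high, name = "") {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1,
            length(high) == 1, is.finite(low), is.finite(high))
  if (low >= high) stop("band region requires low < high", call. = FALSE)
  structure(list(low = low, high = high, name = as.character(name)),
            class = "band_region")
}

#' @export
print.band_region <- function(x, ...) {
  cat(sprintf("<band_region> %s [%.1f, %.1f] cm-1\n",
              if (nzchar(x$name)) x$name else "(unnamed)", x$low, x$high))
  invisible(x)
}

#' Canonical lipid and protein band regions
#'
#' Regions routinely analysed in protein-liposome ATR-FTIR work:
#' Amide I (fit window including aggregation bands), asymmetric phosphate
#' stretch, ester carbonyl stretch, asymmetric/symmetric methylene
#' stretches, and the choline peak.
#'
#' @return Named list of \code{\link{band_region}} objects.
#' @export
default_regions <- function() {
  list(
    amide_I        = band_region(1618, 1696, "amide_I"),
    phosphate_asym = band_region(1220, 1260, "phosphate_asym"),
    carbonyl       = band_region(1700, 1760, "carbonyl"),
    ch2_asym       = band_region(2880, 2960, "ch2_asym"),
    ch2_sym        = band_region(2820, 2880, "ch2_sym"),
    choline        = band_region(945, 995, "choline")
  )
}

# Slice a spectrum to a region (inclusive); errors if the region falls
# outside the support.
subset_spectrum <- function(s, region) {
  stopifnot(inherits(s, "spectrum"), inherits(region, "band_region"))
  if (region$low < min(s$wavenumbers) || region$high > max(s$wavenumbers))
    stop(sprintf("region [%.1f, %.1f] outside spectrum support [%.1f, %.1f]",
                 region$low, region$high,
                 min(s$wavenumbers), max(s$wavenumbers)), call. = FALSE)
  idx <- s$wavenumbers >= region$low & s$wavenumbers <= region$high
  if (sum(idx) < 3) stop("region contains fewer than 3 points", call. = FALSE)
  spectrum(s$wavenumbers[idx], s$absorbance[idx])
}
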