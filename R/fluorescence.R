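#' Instrument polarization correction factor G
#'
#' G is the ratio of the horizontally excited emission intensities,
#' I_HV / I_HH, and corrects the detector's polarization bias in
#' anisotropy measurements.
#'
#' @param I_HV Intensity, horizontal excitation / vertical emission.
#' @param I_HH Intensity, horizontal excitation / horizontal emission
#'   (\code{> 0}).
#' @return The G factor (dimensionless).
#' @examples
#' g_factor(48, 40)  # 1.2
#' @export
g_factor <- function(I_HV, I_HH) {
  if (any(I_HH == 0)) stop("I_HH must be non-zero", call. = FALSE)
  I_HV / I_HH
}

#' Fluorescence anisotropy
#'
#' \deqn{r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH})}
#' with G computed from the HV/HH pair unless supplied. The physically
#' meaningful range for one-photon excitation runs from 0 (freely rotating
#' fluorophore) to 0.4 (immobile limit); values outside it trigger an
#' advisory warning, not an error.
#'
#' @param p A \code{\link{gen_polarized}} result, or any list with fields
#'   \code{I_VV}, \code{I_VH}, \code{I_HV}, \code{I_HH}.
#' @param g Optional G factor override.
#' @return Anisotropy r (dimensionless scalar).
#' @examples
#' anisotropy(list(I_VV = 100, I_VH = 50, I_HV = 40, I_HH = 40))  # 0.25
#' @export
anisotropy <- function(p, g = NULL) {
  need <- c("I_VV", "I_VH", "I_HV", "I_HH")
  if (!all(need %in% names(p)))
    stop("p must carry I_VV, I_VH, I_HV, I_HH", call. = FALSE)
  if (is.null(g)) g <- g_factor(p$I_HV, p$I_HH)
  den <- p$I_VV + 2 * g * p$I_VH
  if (den == 0) stop("zero denominator in anisotropy", call. = FALSE)
  r <- (p$I_VV - g * p$I_VH) / den
  if (r < 0 || r > 0.4)
    warning(sprintf(
      "anisotropy %.3f outside the physical one-photon range [0, 0.4]", r),
      call. = FALSE)
  r
}

#' Calcein release percentage
#'
#' Dequenching-based released fraction:
#' \deqn{CR = (I_t/I_{max,t} - I_0/I_{max,0}) \times
#'       I_{max,t}/(I_{max,t} - I_0) \times 100\%}
#' where \eqn{I_0, I_{max,0}} are the intensities immediately after
#' dilution (before/after detergent lysis) and \eqn{I_t, I_{max,t}} the
#' same pair after incubation for time t. With noisy inputs CR may fall
#' slightly below 0 or above 100; values are returned unclipped with a
#' warning, since clipping would bias replicate means.
#'
#' @param tp A data frame (rows of a \code{\link{gen_release_trace}}) or
#'   list with fields \code{I_0}, \code{I_max0}, \code{I_t}, \code{I_maxt}.
#' @return CR in percent (vector over rows).
#' @examples
#' calcein_release(list(I_0 = 10, I_max0 = 100, I_t = 55, I_maxt = 100))
#' @export
calcein_release <- function(tp) {
  need <- c("I_0", "I_max0", "I_t", "I_maxt")
  if (!all(need %in% names(tp)))
    stop("tp must carry I_0, I_max0, I_t, I_maxt", call. = FALSE)
  i0 <- tp$I_0; im0 <- tp$I_max0; it <- tp$I_t; imt <- tp$I_maxt
  if (any(im0 <= 0) || any(imt <= 0))
    stop("lysis intensities must be > 0", call. = FALSE)
  if (any(i0 < 0)) stop("I_0 must be >= 0", call. = FALSE)
  if (any(im0 <= i0))
    stop("I_max0 must exceed I_0", call. = FALSE)
  if (any(imt == i0))
    stop("I_maxt equal to I_0: zero denominator", call. = FALSE)
  cr <- (it / imt - i0 / im0) * imt / (imt - i0) * 100
  if (any(cr < 0 | cr > 100))
    warning("CR outside [0, 100] (noisy inputs); returned unclipped",
            call. = FALSE)
  cr
}

#' Dye concentration by Beer-Lambert
#'
#' \eqn{c = A / (\epsilon l)}. Defaults are for calcein quantification
#' (\eqn{\lambda_{max}} 504 nm, \eqn{\epsilon} 74,000 M\eqn{^{-1}}
#' cm\eqn{^{-1}}).
#'
#' @param absorbance Absorbance (a.u.).
#' @param epsilon Molar extinction coefficient (M\eqn{^{-1}} cm\eqn{^{-1}}),
#'   \code{> 0}.
#' @param path Optical path length (cm), \code{> 0}.
#' @return Molar concentration (M).
#' @examples
#' dye_concentration(0.74)  # 1e-5 M
#' @export
dye_concentration <- function(absorbance, epsilon = 74000, path = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (path <= 0) stop("path must be > 0", call. = FALSE)
  absorbance / (epsilon * path)
}

#' Construct an emission spectrum
#'
#' @param wavelengths Wavelengths in nm, ascending.
#' @param intensity Intensities (a.u.), same length.
#' @return Object of class \code{"emission_spectrum"}.
#' @export
emission_spectrum <- function(wavelengths, intensity) {
  wavelengths <- as.numeric(wavelengths); intensity <- as.numeric(intensity)
  if (length(wavelengths) != length(intensity))
    stop("wavelengths and intensity must have equal length", call. = FALSE)
  if (!all(is.finite(wavelengths)) || !all(is.finite(intensity)))
    stop("emission spectrum values must be finite", call. = FALSE)
  if (!all(diff(wavelengths) > 0))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  structure(list(wavelengths = wavelengths, intensity = intensity),
            class = "emission_spectrum")
}

#' Emission peak within a window
#'
#' Wavelength and intensity of the maximum within the window at grid
#' resolution; ties break toward the lower wavelength. A maximum sitting
#' on the window boundary (monotone data) and a flat window are flagged
#' with warnings.
#'
#' @param s An \code{\link{emission_spectrum}}.
#' @param window_low,window_high Window bounds (nm), inside the support.
#' @return Named numeric vector \code{c(lambda_max, intensity)}.
#' @export
emission_peak <- function(s, window_low, window_high) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (window_low >= window_high)
    stop("window_low must be < window_high", call. = FALSE)
  idx <- s$wavelengths >= window_low & s$wavelengths <= window_high
  if (!any(idx)) stop("empty window", call. = FALSE)
  wl <- s$wavelengths[idx]; iv <- s$intensity[idx]
  if (diff(range(iv)) == 0)
    warning("flat spectrum in window; returning its first grid point",
            call. = FALSE)
  i <- which.max(iv)
  if ((i == 1 || i == length(iv)) && diff(range(iv)) > 0)
    warning("maximum on the window boundary", call. = FALSE)
  c(lambda_max = wl[i], intensity = iv[i])
}
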