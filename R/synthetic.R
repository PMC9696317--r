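#' Evaluate a pseudo-Voigt band profile
#'
#' Band shape used throughout: a Gaussian, or a linear Gaussian/Lorentzian
#' combination when a pure Gaussian cannot describe the band. Both terms
#' share \code{center}, \code{fwhm} and peak \code{amplitude}.
#'
#' @param x Wavenumbers (cm\eqn{^{-1}}).
#' @param center Band center (cm\eqn{^{-1}}).
#' @param fwhm Full width at half maximum (cm\eqn{^{-1}}), \code{> 0}.
#' @param amplitude Peak height (a.u.), \code{>= 0}.
#' @param lorentz_fraction Lorentzian weight in \code{[0, 1]}; 0 = Gaussian.
#' @return Numeric vector of band absorbance at \code{x}.
#' @export
band_profile <- function(x, center, fwhm, amplitude, lorentz_fraction = 0) {
  stopifnot(fwhm > 0, amplitude >= 0,
            lorentz_fraction >= 0, lorentz_fraction <= 1)
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  if (lorentz_fraction == 0) return(amplitude * g)
  l <- 1 / (1 + 4 * u^2)
  amplitude * ((1 - lorentz_fraction) * g + lorentz_fraction * l)
}

#' Closed-form area of a pseudo-Voigt band
#'
#' Gaussian part integrates to \eqn{a\,w\sqrt{\pi / (4\ln 2)}} (equivalently
#' \eqn{a\,w\sqrt{\pi/\ln 16}}), the Lorentzian part to \eqn{a\,w\,\pi/2}.
#'
#' @inheritParams band_profile
#' @return Band area in a.u. cm\eqn{^{-1}}.
#' @export
band_area <- function(amplitude, fwhm, lorentz_fraction = 0) {
  (1 - lorentz_fraction) * amplitude * fwhm * sqrt(pi / (4 * log(2))) +
    lorentz_fraction * amplitude * fwhm * pi / 2
}

#' Build a band component table from target areas
#'
#' Convenience constructor converting integrated band areas (e.g. percent
#' compositions) into the amplitude parametrisation used by
#' \code{\link{gen_spectrum}}; all components are Gaussian.
#'
#' @param centers Band centers (cm\eqn{^{-1}}).
#' @param areas Target integrated areas (same length as \code{centers}).
#' @param fwhm Common full width at half maximum (cm\eqn{^{-1}}).
#' @return Data frame with columns \code{center}, \code{fwhm},
#'   \code{amplitude}, \code{lorentz_fraction}.
#' @examples
#' components_from_areas(c(1655, 1633, 1645), c(59.9, 23.2, 16.9), fwhm = 20)
#' @export
components_from_areas <- function(centers, areas, fwhm) {
  stopifnot(length(centers) == length(areas), all(areas >= 0), all(fwhm > 0))
  data.frame(center = centers, fwhm = fwhm,
             amplitude = areas / (fwhm * sqrt(pi / (4 * log(2)))),
             lorentz_fraction = 0)
}

#' Specify a ground-truth synthetic spectrum
#'
#' Holds everything needed to generate a labelled ATR-FTIR-like absorbance
#' spectrum: a regular wavenumber grid, true band components, a straight
#' baseline, and iid Gaussian noise on absorbance.
#'
#' The default grid covers 900-3000 cm\eqn{^{-1}} at a 1 cm\eqn{^{-1}} step.
#' The baseline is \code{baseline_offset + baseline_slope * (nu - grid_start)}.
#'
#' @param components Data frame with columns \code{center}, \code{fwhm},
#'   \code{amplitude} and optionally \code{lorentz_fraction} (default 0).
#' @param grid_start,grid_end,grid_step Wavenumber grid (cm\eqn{^{-1}}).
#' @param baseline_slope Baseline slope (absorbance per cm\eqn{^{-1}}).
#' @param baseline_offset Baseline offset (absorbance).
#' @param noise_sd Standard deviation of the additive white noise (a.u.).
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return An object of class \code{"spectrum_spec"}.
#' @export
spectrum_spec <- function(components,
                          grid_start = 900, grid_end = 3000, grid_step = 1,
                          baseline_slope = 0, baseline_offset = 0,
                          noise_sd = 0, seed = NULL) {
  components <- as.data.frame(components)
  if (nrow(components) == 0)
    stop("components must be non-empty", call. = FALSE)
  if (!all(c("center", "fwhm", "amplitude") %in% names(components)))
    stop("components needs columns center, fwhm, amplitude", call. = FALSE)
  if (is.null(components$lorentz_fraction)) components$lorentz_fraction <- 0
  num <- unlist(components[c("center", "fwhm", "amplitude",
                             "lorentz_fraction")])
  if (!all(is.finite(num)))
    stop("non-finite band parameters", call. = FALSE)
  if (any(components$fwhm <= 0) || any(components$amplitude < 0) ||
      any(components$lorentz_fraction < 0 | components$lorentz_fraction > 1))
    stop("invalid band parameters (fwhm > 0, amplitude >= 0, ",
         "lorentz_fraction in [0,1])", call. = FALSE)
  if (!is.finite(grid_start) || !is.finite(grid_end) || !is.finite(grid_step))
    stop("non-finite grid parameters", call. = FALSE)
  if (grid_start >= grid_end) stop("grid_start must be < grid_end", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(components = components, grid_start = grid_start,
                 grid_end = grid_end, grid_step = grid_step,
                 baseline_slope = baseline_slope,
                 baseline_offset = baseline_offset,
                 noise_sd = noise_sd, seed = seed),
            class = "spectrum_spec")
}

# Evaluate with a temporary, restorable RNG state so generators are
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1))
    stop("seed must be a single integer", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Generate a synthetic spectrum with known ground truth
#'
#' Absorbance on the regular grid is the sum of the true band profiles, the
#' straight baseline, and iid Gaussian noise of standard deviation
#' \code{noise_sd}. Identical spec and seed give bit-identical output.
#'
#' @param spec A \code{\link{spectrum_spec}}.
#' @return A \code{\link{spectrum}}.
#' @examples
#' sp <- spectrum_spec(components_from_areas(1655, 100, 20),
#'                     grid_start = 1580, grid_end = 1730)
#' s <- gen_spectrum(sp)
#' s$wavenumbers[which.max(s$absorbance)]  # 1655
#' @export
gen_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  x <- seq(spec$grid_start, spec$grid_end, by = spec$grid_step)
  y <- spec$baseline_offset + spec$baseline_slope * (x - spec$grid_start)
  for (i in seq_len(nrow(spec$components))) {
    cm <- spec$components[i, ]
    y <- y + band_profile(x, cm$center, cm$fwhm, cm$amplitude,
                          cm$lorentz_fraction)
  }
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed, stats::rnorm(length(x), 0, spec$noise_sd))
  spectrum(x, y)
}

#' Generate polarized fluorescence intensities for a known anisotropy
#'
#' Constructs the four polarized intensities (VV, VH, HV, HH) such that the
#' instrument correction factor G = I_HV / I_HH equals \code{g_true} and the
#' anisotropy formula r = (I_VV - G I_VH) / (I_VV + 2 G I_VH) recovers
#' \code{r_true} exactly at zero noise (round-trip contract).
#' \code{total_intensity} sets the scale I_VV + 2 G I_VH. Noise is applied
#' multiplicatively (photometric noise scales with signal).
#'
#' @param r_true True anisotropy, in (-0.5, 1).
#' @param g_true True G factor, \code{> 0}.
#' @param total_intensity Total polarized intensity scale, \code{> 0}.
#' @param noise_sd Relative (fractional) noise standard deviation.
#' @param seed Integer seed or \code{NULL}.
#' @return Object of class \code{"polarized_intensities"} with fields
#'   \code{I_VV}, \code{I_VH}, \code{I_HV}, \code{I_HH}.
#' @examples
#' p <- gen_polarized(0.13, g_true = 1.2)
#' anisotropy(p)  # 0.13
#' @export
gen_polarized <- function(r_true, g_true = 1, total_intensity = 100,
                          noise_sd = 0, seed = NULL) {
  if (!is.finite(r_true) || r_true <= -0.5 || r_true >= 1)
    stop("r_true must lie in (-0.5, 1)", call. = FALSE)
  if (!is.finite(g_true) || g_true <= 0)
    stop("g_true must be > 0", call. = FALSE)
  if (!is.finite(total_intensity) || total_intensity <= 0)
    stop("total_intensity must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  i_vv <- total_intensity * (1 + 2 * r_true) / 3
  i_vh <- total_intensity * (1 - r_true) / (3 * g_true)
  i_hh <- total_intensity / 4
  i_hv <- g_true * i_hh
  out <- c(I_VV = i_vv, I_VH = i_vh, I_HV = i_hv, I_HH = i_hh)
  if (noise_sd > 0)
    out <- with_seed(seed, out * (1 + stats::rnorm(4, 0, noise_sd)))
  if (any(out <= 0))
    stop("noise level produced non-positive intensities; lower noise_sd",
         call. = FALSE)
  structure(as.list(out), class = "polarized_intensities")
}

#' @export
print.polarized_intensities <- function(x, ...) {
  cat(sprintf("<polarized_intensities> VV=%.4g VH=%.4g HV=%.4g HH=%.4g\n",
              x$I_VV, x$I_VH, x$I_HV, x$I_HH))
  invisible(x)
}

#' Specify a ground-truth calcein-release kinetic trace
#'
#' The underlying released fraction follows first-order leakage
#' \eqn{f(t) = 1 - (1 - f_0)\exp(-k t)} with leak rate \eqn{k} per minute and
#' initial released fraction \eqn{f_0}. Encapsulated (self-quenched) dye
#' fluoresces at a residual \code{quench_factor} of its dequenched intensity;
#' detergent lysis dequenches everything.
#'
#' @param leak_rate Leak rate per minute, \code{>= 0}.
#' @param duration Trace duration in minutes.
#' @param sampling Sampling interval in minutes.
#' @param I0_fraction Initial released fraction, in \code{[0, 1)}.
#' @param noise_sd Relative (multiplicative) noise standard deviation.
#' @param seed Integer seed or \code{NULL}.
#' @param total_intensity Fully dequenched fluorescence scale.
#' @param quench_factor Residual fluorescence of encapsulated dye, in
#'   \code{[0, 1)}.
#' @return Object of class \code{"release_spec"}.
#' @export
release_spec <- function(leak_rate, duration = 60, sampling = 5,
                         I0_fraction = 0, noise_sd = 0, seed = NULL,
                         total_intensity = 1000, quench_factor = 0.1) {
  if (!is.finite(leak_rate) || leak_rate < 0)
    stop("leak_rate must be >= 0", call. = FALSE)
  if (I0_fraction < 0 || I0_fraction >= 1)
    stop("I0_fraction must lie in [0, 1)", call. = FALSE)
  if (duration <= 0 || sampling <= 0 || sampling > duration)
    stop("need 0 < sampling <= duration", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (quench_factor < 0 || quench_factor >= 1)
    stop("quench_factor must lie in [0, 1)", call. = FALSE)
  structure(list(leak_rate = leak_rate, duration = duration,
                 sampling = sampling, I0_fraction = I0_fraction,
                 noise_sd = noise_sd, seed = seed,
                 total_intensity = total_intensity,
                 quench_factor = quench_factor),
            class = "release_spec")
}

#' Generate a calcein-release kinetic trace
#'
#' Produces per-timepoint intensity tuples (I_0, I_max0, I_t, I_maxt) such
#' that applying \code{\link{calcein_release}} to noiseless timepoints
#' recovers \eqn{(f(t) - f(0)) / (1 - f(0)) \times 100} exactly, i.e. the
#' released percentage relative to what was still encapsulated at t = 0.
#'
#' @param spec A \code{\link{release_spec}}.
#' @return Data frame of class \code{"release_trace"} with columns
#'   \code{t}, \code{I_0}, \code{I_max0}, \code{I_t}, \code{I_maxt}.
#' @examples
#' tr <- gen_release_trace(release_spec(leak_rate = 0.1, duration = 10,
#'                                      sampling = 10))
#' calcein_release(tr[nrow(tr), ])  # ~63.2 (= 100 * (1 - exp(-1)))
#' @export
gen_release_trace <- function(spec) {
  stopifnot(inherits(spec, "release_spec"))
  t <- seq(0, spec$duration, by = spec$sampling)
  f <- 1 - (1 - spec$I0_fraction) * exp(-spec$leak_rate * t)
  q <- spec$quench_factor
  fmax <- spec$total_intensity
  i_t <- fmax * (f + q * (1 - f))
  i_max <- rep(fmax, length(t))
  if (spec$noise_sd > 0) {
    eps <- with_seed(spec$seed,
                     matrix(stats::rnorm(2 * length(t), 0, spec$noise_sd),
                            ncol = 2))
    i_t <- i_t * (1 + eps[, 1])
    i_max <- i_max * (1 + eps[, 2])
  }
  out <- data.frame(t = t, I_0 = i_t[1], I_max0 = i_max[1],
                    I_t = i_t, I_maxt = i_max)
  class(out) <- c("release_trace", "data.frame")
  out
}
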