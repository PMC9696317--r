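#' Baseline-correct and smooth a spectral region
#'
#' Slices \code{s} to \code{region}, subtracts a straight line anchored at
#' the region edges, and optionally applies Savitzky-Golay smoothing.
#' Each anchor is the mean absorbance over a 5 cm\eqn{^{-1}} margin at the
#' corresponding edge (placed at the margin's mean wavenumber), which makes
#' the correction robust to noise at the anchor points.
#'
#' @param s A \code{\link{spectrum}}.
#' @param region A \code{\link{band_region}} inside the spectrum support.
#' @param sg_window Savitzky-Golay window length in points (odd, greater
#'   than \code{sg_order}); \code{0} or \code{NULL} skips smoothing.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param anchor_margin Width of the edge anchor margins (cm\eqn{^{-1}}).
#' @return The corrected (and smoothed) region slice as a
#'   \code{\link{spectrum}}.
#' @examples
#' s <- gen_spectrum(spectrum_spec(components_from_areas(1655, 50, 8),
#'                                 grid_start = 1580, grid_end = 1730,
#'                                 baseline_slope = 1e-4, baseline_offset = 0.2))
#' p <- preprocess(s, band_region(1600, 1710), sg_window = 0)
#' @export
preprocess <- function(s, region, sg_window = 9, sg_order = 3,
                       anchor_margin = 5) {
  sl <- subset_spectrum(s, region)
  x <- sl$wavenumbers
  y <- sl$absorbance
  ml <- x <= region$low + anchor_margin
  mh <- x >= region$high - anchor_margin
  x1 <- mean(x[ml]); y1 <- mean(y[ml])
  x2 <- mean(x[mh]); y2 <- mean(y[mh])
  slope <- (y2 - y1) / (x2 - x1)
  y <- y - (y1 + slope * (x - x1))
  if (!is.null(sg_window) && sg_window > 0) {
    if (sg_window %% 2 == 0 || sg_window <= sg_order)
      stop("sg_window must be odd and greater than sg_order", call. = FALSE)
    if (sg_window > length(x))
      stop("sg_window larger than the region slice", call. = FALSE)
    y <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  }
  spectrum(x, y)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Second derivative with respect to wavenumber on the native grid, same
#' length as the input; edge values come from the filter's one-sided
#' polynomial fits. Overlapped bands appear as distinct negative lobes
#' (minima) even when the absorbance itself shows a single envelope.
#'
#' @param s A \code{\link{spectrum}} with at least 7 points.
#' @param sg_window Window length in points (odd). Wider windows suppress
#'   noise amplification at the cost of merging closely spaced bands.
#' @param sg_order Polynomial order (must exceed 2).
#' @return A \code{\link{spectrum}} whose absorbance slot holds
#'   d\eqn{^2}A/d\eqn{\nu^2}.
#' @export
second_derivative <- function(s, sg_window = 13, sg_order = 3) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s$wavenumbers) < 7)
    stop("need at least 7 points for a second derivative", call. = FALSE)
  if (sg_window %% 2 == 0 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order", call. = FALSE)
  if (sg_order < 2)
    stop("sg_order must be >= 2 for a second derivative", call. = FALSE)
  if (sg_window > length(s$wavenumbers))
    stop("sg_window larger than the spectrum", call. = FALSE)
  h <- mean(diff(s$wavenumbers))
  d2 <- signal::sgolayfilt(s$absorbance, p = sg_order, n = sg_window,
                           m = 2, ts = h)
  spectrum(s$wavenumbers, d2)
}

#' Pick band positions from a second-derivative spectrum
#'
#' Band centers are the local minima of the second derivative whose depth
#' (negative excursion) is at least \code{prominence_fraction} times the
#' deepest minimum. Minima with non-negative derivative values are never
#' reported. An empty result is allowed.
#'
#' @param d2 A second-derivative \code{\link{spectrum}}
#'   (see \code{\link{second_derivative}}).
#' @param prominence_fraction Depth threshold relative to the deepest
#'   minimum, in \code{[0, 1]}.
#' @param edge_exclude Number of points at each end to ignore (Savitzky-
#'   Golay edge fits can produce artefactual minima); 0 keeps everything.
#' @return Sorted numeric vector of band centers (cm\eqn{^{-1}}); possibly
#'   empty.
#' @export
pick_peaks <- function(d2, prominence_fraction = 0.05, edge_exclude = 0) {
  stopifnot(inherits(d2, "spectrum"),
            prominence_fraction >= 0, prominence_fraction <= 1)
  v <- d2$absorbance
  n <- length(v)
  i <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n]) + 1
  i <- i[v[i] < 0]
  if (edge_exclude > 0)
    i <- i[i > edge_exclude & i <= n - edge_exclude]
  if (length(i) == 0) return(numeric(0))
  depth <- -v[i]
  i <- i[depth >= prominence_fraction * max(depth)]
  sort(d2$wavenumbers[i])
}

# Noise sd estimate: residual of a light SG smooth, corrected for the
# variance absorbed by the fit (approximately (order+1)/window of it).
estimate_noise_sd <- function(s, sg_window = 9, sg_order = 3) {
  r <- s$absorbance - signal::sgolayfilt(s$absorbance, p = sg_order,
                                         n = sg_window)
  stats::sd(r) / sqrt(1 - (sg_order + 1) / sg_window)
}
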