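#' Amide I assignment table
#'
#' Correlation between secondary-structure elements of albumin-type
#' proteins and Amide I sub-band positions, with expanded alpha-helix and
#' random-coil ranges appropriate for albumin. Intermolecular beta-sheet
#' (aggregation) bands flank the window on both sides and are reported
#' separately from the four conformational elements.
#'
#' @return Data frame of class \code{"amide_assignment"} with columns
#'   \code{element}, \code{low}, \code{high}; ranges are half-open
#'   \code{[low, high)}.
#' @export
amide_assignment <- function() {
  out <- data.frame(
    element = c("beta_sheet", "random_coil", "alpha_helix", "beta_turn",
                "aggregates", "aggregates"),
    low = c(1628, 1640, 1650, 1664, 1618, 1688),
    high = c(1639, 1649, 1660, 1687, 1626, 1696))
  class(out) <- c("amide_assignment", "data.frame")
  out
}

# Assign one center to an element: direct containment in [low, high),
# otherwise the nearest range; distance ties go to the lower-wavenumber
# range (rows are scanned in ascending order of `low`).
assign_element <- function(center, table) {
  inside <- center >= table$low & center < table$high
  if (any(inside)) return(table$element[which(inside)[1]])
  d <- ifelse(center < table$low, table$low - center,
              center - table$high)
  o <- order(table$low)
  d <- d[o]
  table$element[o][which.min(d)]  # which.min takes the first (lowest) tie
}

#' Quantify secondary structure from a fitted Amide I decomposition
#'
#' Each fitted component is assigned to the structural element whose range
#' contains its center (half-open intervals; centers falling in a gap go to
#' the nearest range, ties to the lower-wavenumber range). Element
#' percentages are component areas summed per element and normalized over
#' the non-aggregate total; the aggregate percentage is reported separately
#' against the full total, so the four conformational elements always sum
#' to 100.
#'
#' @param fit A \code{\link{fit_bands}} result whose components lie in the
#'   Amide I region (1600-1700 cm\eqn{^{-1}}).
#' @param table An \code{\link{amide_assignment}} table.
#' @return Object of class \code{"secondary_structure"}: percentages
#'   \code{alpha_helix}, \code{beta_sheet}, \code{beta_turn},
#'   \code{random_coil}, their sum check, \code{sheet_plus_turn}, and
#'   \code{aggregates}; plus the per-component assignment.
#' @examples
#' tr <- components_from_areas(c(1655, 1633, 1645), c(59.9, 23.2, 16.9), 20)
#' s <- gen_spectrum(spectrum_spec(tr, grid_start = 1580, grid_end = 1730))
#' f <- fit_bands(s, band_region(1618, 1696), c(1633, 1645, 1655),
#'                width = "shared", fix_centers = TRUE)
#' assign_secondary_structure(f)
#' @export
assign_secondary_structure <- function(fit, table = amide_assignment()) {
  stopifnot(inherits(fit, "band_fit"))
  comp <- fit$components
  if (nrow(comp) == 0) stop("empty fit", call. = FALSE)
  if (any(comp$center < 1600 | comp$center > 1700))
    stop("component centers outside the Amide I region (1600-1700 cm-1)",
         call. = FALSE)
  comp$element <- vapply(comp$center, assign_element, character(1),
                         table = table)
  total <- sum(comp$area)
  agg <- sum(comp$area[comp$element == "aggregates"])
  non_agg <- total - agg
  if (non_agg <= 0)
    stop("no non-aggregate band area to normalize", call. = FALSE)
  pct <- function(el) 100 * sum(comp$area[comp$element == el]) / non_agg
  out <- list(alpha_helix = pct("alpha_helix"),
              beta_sheet = pct("beta_sheet"),
              beta_turn = pct("beta_turn"),
              random_coil = pct("random_coil"),
              aggregates = 100 * agg / total,
              components = comp)
  out$sheet_plus_turn <- out$beta_sheet + out$beta_turn
  structure(out, class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure (% of non-aggregate Amide I area)\n")
  cat(sprintf("  alpha-helix   %6.1f\n", x$alpha_helix))
  cat(sprintf("  beta-sheet    %6.1f\n", x$beta_sheet))
  cat(sprintf("  beta-turn     %6.1f\n", x$beta_turn))
  cat(sprintf("  random coil   %6.1f\n", x$random_coil))
  cat(sprintf("  (sheet+turn   %6.1f)\n", x$sheet_plus_turn))
  cat(sprintf("  aggregates    %6.1f  (%% of total area, reported apart)\n",
              x$aggregates))
  invisible(x)
}

#' @export
as.data.frame.secondary_structure <- function(x, ...) {
  data.frame(alpha_helix = x$alpha_helix, beta_sheet = x$beta_sheet,
             beta_turn = x$beta_turn, random_coil = x$random_coil,
             sheet_plus_turn = x$sheet_plus_turn, aggregates = x$aggregates)
}

#' Configuration for the Amide I analysis pipeline
#'
#' @param window Fit window (cm\eqn{^{-1}}); the default 1618-1696 includes
#'   the flanking aggregation bands.
#' @param sg_window,sg_order Savitzky-Golay smoothing used before the
#'   derivative stage.
#' @param deriv_window Savitzky-Golay window for the second derivative
#'   (wider than the smoothing window to tame noise amplification).
#' @param prominence Relative depth threshold for derivative minima.
#' @param edge_exclude Derivative points ignored at each window edge.
#' @param fwhm_init,fwhm_range Starting value and bounds for the shared
#'   component bandwidth (cm\eqn{^{-1}}).
#' @param refine Half-width (cm\eqn{^{-1}}) of the final center-release
#'   polish; 0 keeps centers fixed at their seeded positions.
#' @param deriv_pad Extra margin (cm\eqn{^{-1}}) around the fit window used
#'   for the derivative stage (clipped to the spectrum support), so that
#'   bands near the window edges are interior points for the one-sided
#'   Savitzky-Golay edge fits.
#' @param agg_deriv_window,agg_prominence Narrower derivative window and
#'   lower relative depth threshold used for the dedicated aggregation-band
#'   scan: aggregate bands are weak shoulders close to the window edges, so
#'   they need a more sensitive (but range-restricted) detection pass than
#'   the main conformational bands.
#' @param assignment An \code{\link{amide_assignment}} table.
#' @param fit_smoothed Fit the smoothed slice instead of the
#'   baseline-corrected raw slice (smoothing slightly widens bands, so the
#'   default fits raw).
#' @return List of class \code{"amide_config"}.
#' @export
amide_config <- function(window = c(1618, 1696),
                         sg_window = 9, sg_order = 3,
                         deriv_window = 13, prominence = 0.1,
                         edge_exclude = 5,
                         fwhm_init = 18, fwhm_range = c(8, 35),
                         refine = 0.5, deriv_pad = 12,
                         agg_deriv_window = 7, agg_prominence = 0.03,
                         assignment = amide_assignment(),
                         fit_smoothed = FALSE) {
  structure(list(window = window, sg_window = sg_window,
                 sg_order = sg_order, deriv_window = deriv_window,
                 prominence = prominence, edge_exclude = edge_exclude,
                 fwhm_init = fwhm_init, fwhm_range = fwhm_range,
                 refine = refine, deriv_pad = deriv_pad,
                 agg_deriv_window = agg_deriv_window,
                 agg_prominence = agg_prominence,
                 assignment = assignment,
                 fit_smoothed = fit_smoothed),
            class = "amide_config")
}

#' Full Amide I secondary-structure analysis
#'
#' Composition of the pipeline stages: baseline correction and smoothing
#' (\code{\link{preprocess}}), \code{\link{second_derivative}},
#' \code{\link{pick_peaks}}, constrained multi-component band fitting, and
#' \code{\link{assign_secondary_structure}}.
#'
#' Band positions of strongly overlapped Amide I sub-bands are not jointly
#' identifiable with their widths and amplitudes, so one component per
#' structural element is seeded at the midpoint of its assignment range
#' and held there (single shared bandwidth) during the main fit; centers
#' are then released by at most \code{refine} cm\eqn{^{-1}} in a final
#' polish. The second derivative serves to detect aggregation bands, which
#' are added as extra components only when a derivative minimum falls in an
#' aggregate range.
#'
#' @param s A \code{\link{spectrum}} covering 1600-1700 cm\eqn{^{-1}}.
#' @param config An \code{\link{amide_config}}.
#' @return A \code{\link{assign_secondary_structure}} result with the
#'   underlying \code{band_fit} attached as \code{$fit} and the derivative
#'   peak picks as \code{$picks}.
#' @export
amide_i_analysis <- function(s, config = amide_config()) {
  stopifnot(inherits(s, "spectrum"), inherits(config, "amide_config"))
  region <- band_region(config$window[1], config$window[2], "amide_I")
  raw <- preprocess(s, region, sg_window = 0)
  # derivative stage on a padded window so that bands sitting near the
  # fit-window edges are interior points for the SG edge fits
  pad_lo <- max(min(s$wavenumbers), config$window[1] - config$deriv_pad)
  pad_hi <- min(max(s$wavenumbers), config$window[2] + config$deriv_pad)
  padded <- preprocess(s, band_region(pad_lo, pad_hi),
                       sg_window = config$sg_window,
                       sg_order = config$sg_order)
  d2 <- second_derivative(padded, sg_window = config$deriv_window,
                          sg_order = config$sg_order)
  picks <- pick_peaks(d2, prominence_fraction = config$prominence,
                      edge_exclude = config$edge_exclude)
  picks <- picks[picks >= config$window[1] & picks <= config$window[2]]

  tab <- config$assignment
  elems <- tab[tab$element != "aggregates", , drop = FALSE]
  centers <- (elems$low + elems$high) / 2
  # dedicated aggregation-band scan: narrower derivative window and lower
  # threshold, accepted only inside the aggregate ranges
  d2a <- second_derivative(padded, sg_window = config$agg_deriv_window,
                           sg_order = config$sg_order)
  agg_picks <- pick_peaks(d2a, prominence_fraction = config$agg_prominence,
                          edge_exclude = config$edge_exclude)
  aggr <- tab[tab$element == "aggregates", , drop = FALSE]
  for (i in seq_len(nrow(aggr))) {
    hit <- agg_picks[agg_picks >= aggr$low[i] & agg_picks < aggr$high[i]]
    if (length(hit)) centers <- c(centers, hit[which.min(abs(hit - mean(hit)))])
  }
  centers <- sort(centers)

  target <- if (config$fit_smoothed) {
    spectrum(raw$wavenumbers,
             signal::sgolayfilt(raw$absorbance, p = config$sg_order,
                                n = config$sg_window))
  } else raw
  x <- target$wavenumbers; y <- target$absorbance
  eng <- fit_engine(x, y, centers, fix_centers = TRUE, shared_width = TRUE,
                    fwhm_init = config$fwhm_init,
                    fwhm_range = config$fwhm_range)
  if (config$refine > 0) {
    eng <- fit_engine(x, y, eng$centers, fix_centers = FALSE,
                      center_bound = config$refine, shared_width = TRUE,
                      fwhm_init = eng$fwhm[1], fwhm_range = config$fwhm_range,
                      amp_init = eng$amplitude,
                      baseline_init = unname(eng$baseline[c("slope",
                                                            "offset")]))
  }
  fit <- as_band_fit(eng, region, x, y,
                     noise = estimate_noise_sd(raw))
  out <- assign_secondary_structure(fit, tab)
  out$fit <- fit
  out$picks <- picks
  out
}
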