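# Internal Levenberg-Marquardt engine for multi-component band fits.
# Model: sum of pseudo-Voigt components plus a linear residual baseline
# offset + slope * (x - mean(x)). Options control which parameters are
# free; heavily overlapped regions need the constrained modes (fixed or
# tightly bounded centers, shared width) to stay identifiable.
fit_engine <- function(x, y, centers,
                       fix_centers = FALSE, center_bound = 5,
                       shared_width = FALSE, free_eta = FALSE,
                       fwhm_init = 15, fwhm_range = c(2, 60),
                       amp_init = NULL, eta_init = NULL,
                       baseline_init = c(0, 0),
                       maxiter = 500, ftol = 1e-10) {
  k <- length(centers)
  ord <- order(centers)
  centers <- centers[ord]
  if (is.null(amp_init)) {
    amp_init <- pmax(stats::approx(x, y, xout = centers, rule = 2)$y * 0.7,
                     1e-3)
  } else amp_init <- amp_init[ord]
  if (length(fwhm_init) == 1) fwhm_init <- rep(fwhm_init, k)
  else fwhm_init <- fwhm_init[ord]
  if (is.null(eta_init)) eta_init <- rep(0, k) else eta_init <- eta_init[ord]

  nw <- if (shared_width) 1 else k
  p0 <- lo <- hi <- numeric(0)
  idx <- list()
  if (!fix_centers) {
    idx$cen <- seq_len(k)
    p0 <- centers; lo <- centers - center_bound; hi <- centers + center_bound
  }
  idx$w <- length(p0) + seq_len(nw)
  p0 <- c(p0, if (shared_width) mean(fwhm_init) else fwhm_init)
  lo <- c(lo, rep(fwhm_range[1], nw)); hi <- c(hi, rep(fwhm_range[2], nw))
  idx$amp <- length(p0) + seq_len(k)
  p0 <- c(p0, amp_init); lo <- c(lo, rep(0, k)); hi <- c(hi, rep(Inf, k))
  if (free_eta) {
    idx$eta <- length(p0) + seq_len(k)
    p0 <- c(p0, eta_init); lo <- c(lo, rep(0, k)); hi <- c(hi, rep(1, k))
  }
  idx$bl <- length(p0) + 1:2
  p0 <- c(p0, baseline_init)
  lo <- c(lo, -Inf, -Inf); hi <- c(hi, Inf, Inf)

  if (length(p0) >= length(x))
    stop("ill-posed fit: more parameters than points", call. = FALSE)

  xm <- mean(x)
  model <- function(p, at = x) {
    cen <- if (fix_centers) centers else p[idx$cen]
    w <- p[idx$w]; if (shared_width) w <- rep(w, k)
    amp <- p[idx$amp]
    eta <- if (free_eta) p[idx$eta] else rep(0, k)
    m <- p[idx$bl[2]] + p[idx$bl[1]] * (at - xm)
    for (i in seq_len(k))
      m <- m + band_profile(at, cen[i], w[i], amp[i], eta[i])
    m
  }
  resid_fn <- function(p) model(p) - y
  ft <- minpack.lm::nls.lm(
    par = p0, lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol))
  p <- ft$par
  cen <- if (fix_centers) centers else p[idx$cen]
  w <- p[idx$w]; if (shared_width) w <- rep(w, k)
  amp <- p[idx$amp]
  eta <- if (free_eta) p[idx$eta] else rep(0, k)
  res <- resid_fn(p)
  list(centers = cen, fwhm = w, amplitude = amp, lorentz_fraction = eta,
       baseline = c(slope = unname(p[idx$bl[1]]),
                    offset = unname(p[idx$bl[2]])),
       x_center = xm, residuals = res,
       residual_rms = sqrt(mean(res^2)),
       converged = ft$info %in% 1:4, info = ft$info,
       message = ft$message, niter = ft$niter,
       model = model, par = p)
}

#' Fit overlapping spectral bands in a region
#'
#' Decomposes a (preprocessed) spectral region into pseudo-Voigt components
#' plus a linear residual baseline by bounded Levenberg-Marquardt least
#' squares. By default each component has a free center (constrained to
#' \code{center_bound} cm\eqn{^{-1}} of its initial guess), width and
#' amplitude, and is a pure Gaussian; under
#' \code{shape_policy = "gauss_lorentz"} the Lorentzian fractions are
#' released only if the Gaussian-only fit leaves residuals above the noise
#' level.
#'
#' Strongly overlapped bands (separation well below the bandwidth) make
#' free centers and widths jointly non-identifiable; for those cases set
#' \code{fix_centers = TRUE} and/or \code{width = "shared"} as
#' \code{\link{amide_i_analysis}} does.
#'
#' If the fit does not converge, or its residual RMS stays above 1.5 times
#' the estimated noise level, one retry is made with an extra component at
#' the largest residual (never exceeding \code{max_components}).
#' Non-convergence is reported via the \code{converged} flag, not an error.
#'
#' @param s A \code{\link{spectrum}} (typically from
#'   \code{\link{preprocess}}).
#' @param region A \code{\link{band_region}}.
#' @param initial_centers Numeric vector of starting band centers
#'   (cm\eqn{^{-1}}), at least one inside the region.
#' @param shape_policy \code{"gauss"} (default) or \code{"gauss_lorentz"}.
#' @param width \code{"free"} (one FWHM per component) or \code{"shared"}
#'   (single common FWHM).
#' @param fix_centers Hold centers at \code{initial_centers}.
#' @param center_bound Center box half-width (cm\eqn{^{-1}}).
#' @param fwhm_init,fwhm_range Starting value and bounds for FWHM
#'   (cm\eqn{^{-1}}).
#' @param max_components Cap on components after residual-driven retry.
#' @param maxiter,ftol Optimizer control (maximum iterations, relative
#'   cost-change tolerance).
#' @return Object of class \code{"band_fit"} with the fitted components
#'   (sorted by center, with closed-form areas), baseline parameters,
#'   residual RMS and convergence flag.
#' @examples
#' tr <- components_from_areas(1655, 60, 20)
#' s <- gen_spectrum(spectrum_spec(tr, grid_start = 1600, grid_end = 1710))
#' f <- fit_bands(s, band_region(1610, 1700), 1655)
#' coef(f)
#' @export
fit_bands <- function(s, region, initial_centers,
                      shape_policy = c("gauss", "gauss_lorentz"),
                      width = c("free", "shared"),
                      fix_centers = FALSE, center_bound = 5,
                      fwhm_init = 15, fwhm_range = c(2, 60),
                      max_components = 8, maxiter = 500, ftol = 1e-10) {
  shape_policy <- match.arg(shape_policy)
  width <- match.arg(width)
  sl <- subset_spectrum(s, region)
  x <- sl$wavenumbers; y <- sl$absorbance
  initial_centers <- sort(as.numeric(initial_centers))
  inside <- initial_centers >= region$low & initial_centers <= region$high
  if (!any(inside))
    stop("no initial center inside the region", call. = FALSE)
  initial_centers <- initial_centers[inside]

  noise <- estimate_noise_sd(sl)
  tol <- 1.5 * noise + 1e-8 * max(abs(y))
  run <- function(cen, eng_args = list()) {
    base_args <- list(
      x = x, y = y, centers = cen,
      fix_centers = fix_centers, center_bound = center_bound,
      shared_width = (width == "shared"),
      fwhm_init = fwhm_init, fwhm_range = fwhm_range,
      maxiter = maxiter, ftol = ftol)
    do.call(fit_engine, utils::modifyList(base_args, eng_args))
  }
  ft <- run(initial_centers)
  if (shape_policy == "gauss_lorentz" && ft$residual_rms > tol) {
    ft2 <- run(ft$centers, list(free_eta = TRUE, amp_init = ft$amplitude,
                                fwhm_init = ft$fwhm))
    if (ft2$residual_rms < ft$residual_rms) ft <- ft2
  }
  if ((!ft$converged || ft$residual_rms > tol) &&
      length(ft$centers) < max_components) {
    # missing absorbance is where the data most exceeds the model;
    # warm-start from the current solution so the retry cannot regress
    extra <- x[which.max(-ft$residuals)]
    ft2 <- run(c(ft$centers, extra),
               list(amp_init = c(ft$amplitude, max(-ft$residuals, 1e-3)),
                    fwhm_init = c(ft$fwhm, stats::median(ft$fwhm)),
                    eta_init = c(ft$lorentz_fraction, 0),
                    baseline_init = unname(ft$baseline)))
    if (ft2$residual_rms < ft$residual_rms) ft <- ft2
  }

  comp <- data.frame(center = ft$centers, fwhm = ft$fwhm,
                     amplitude = ft$amplitude,
                     lorentz_fraction = ft$lorentz_fraction)
  comp$area <- band_area(comp$amplitude, comp$fwhm, comp$lorentz_fraction)
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(region = region, components = comp,
                 baseline_params = ft$baseline, x_center = ft$x_center,
                 data = list(wavenumbers = x, absorbance = y),
                 fitted_values = ft$model(ft$par),
                 residual_rms = ft$residual_rms,
                 converged = ft$converged, info = ft$info,
                 niter = ft$niter, shape_policy = shape_policy,
                 noise_sd_estimate = noise,
                 call = match.call()),
            class = "band_fit")
}

# Assemble a band_fit from a fit_engine result (used by pipeline stages
# that chain constrained and refined fits).
as_band_fit <- function(eng, region, x, y, shape_policy = "gauss",
                        noise = NA_real_) {
  comp <- data.frame(center = eng$centers, fwhm = eng$fwhm,
                     amplitude = eng$amplitude,
                     lorentz_fraction = eng$lorentz_fraction)
  comp$area <- band_area(comp$amplitude, comp$fwhm, comp$lorentz_fraction)
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(region = region, components = comp,
                 baseline_params = eng$baseline, x_center = eng$x_center,
                 data = list(wavenumbers = x, absorbance = y),
                 fitted_values = eng$model(eng$par),
                 residual_rms = eng$residual_rms,
                 converged = eng$converged, info = eng$info,
                 niter = eng$niter, shape_policy = shape_policy,
                 noise_sd_estimate = noise, call = NULL),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %s: %d component(s), residual RMS %.3g%s\n",
              if (nzchar(x$region$name)) x$region$name else
                sprintf("[%.0f, %.0f]", x$region$low, x$region$high),
              nrow(x$components), x$residual_rms,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$components, 3))
  invisible(x)
}

#' @export
summary.band_fit <- function(object, ...) {
  comp <- object$components
  comp$area_fraction <- comp$area / sum(comp$area)
  out <- list(components = comp, baseline = object$baseline_params,
              residual_rms = object$residual_rms,
              noise_sd_estimate = object$noise_sd_estimate,
              converged = object$converged,
              n_points = length(object$data$wavenumbers),
              region = object$region)
  class(out) <- "summary.band_fit"
  out
}

#' @export
print.summary.band_fit <- function(x, ...) {
  cat(sprintf("Band fit over [%.1f, %.1f] cm-1 (%d points)\n",
              x$region$low, x$region$high, x$n_points))
  print(round(x$components, 4))
  cat(sprintf("baseline: slope %.3g, offset %.3g (about region midpoint)\n",
              x$baseline["slope"], x$baseline["offset"]))
  cat(sprintf("residual RMS %.4g (noise estimate %.4g); converged: %s\n",
              x$residual_rms, x$noise_sd_estimate, x$converged))
  invisible(x)
}

#' @export
coef.band_fit <- function(object, ...) {
  m <- as.matrix(object$components)
  attr(m, "baseline") <- object$baseline_params
  m
}

#' @export
fitted.band_fit <- function(object, ...) object$fitted_values

#' @export
residuals.band_fit <- function(object, ...) {
  object$data$absorbance - object$fitted_values
}

#' Evaluate a fitted band model
#'
#' @param object A \code{\link{fit_bands}} result.
#' @param newdata Optional wavenumbers (numeric vector, or data frame with
#'   a \code{wavenumber} column) at which to evaluate the model; defaults
#'   to the fitted grid.
#' @param ... Unused.
#' @return Numeric vector of model absorbance values.
#' @export
predict.band_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$wavenumbers
       else if (is.data.frame(newdata)) newdata$wavenumber
       else as.numeric(newdata)
  y <- object$baseline_params["offset"] +
    object$baseline_params["slope"] * (x - object$x_center)
  for (i in seq_len(nrow(object$components))) {
    cm <- object$components[i, ]
    y <- y + band_profile(x, cm$center, cm$fwhm, cm$amplitude,
                          cm$lorentz_fraction)
  }
  unname(y)
}

#' @export
plot.band_fit <- function(x, ...,
                          xlab = expression(Wavenumber ~ (cm^-1)),
                          ylab = "Absorbance (a.u.)") {
  w <- x$data$wavenumbers
  graphics::plot(w, x$data$absorbance, type = "p", pch = 20, cex = 0.4,
                 col = "grey40", xlab = xlab, ylab = ylab, ...)
  graphics::lines(w, x$fitted_values, col = "red3", lwd = 2)
  base <- x$baseline_params["offset"] +
    x$baseline_params["slope"] * (w - x$x_center)
  for (i in seq_len(nrow(x$components))) {
    cm <- x$components[i, ]
    graphics::lines(w, base + band_profile(w, cm$center, cm$fwhm,
                                           cm$amplitude,
                                           cm$lorentz_fraction),
                    col = "steelblue", lty = 2)
  }
  invisible(x)
}
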