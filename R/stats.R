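#' Summarize replicate measurements
#'
#' Sample mean, standard deviation (n-1 denominator) and standard error.
#' A single value yields \code{NA} for sd and se with a degenerate flag.
#'
#' @param values Numeric vector, \code{n >= 1}.
#' @return List of class \code{"sample_summary"} with \code{mean},
#'   \code{sd}, \code{se}, \code{n}, \code{degenerate}.
#' @examples
#' summarize_replicates(c(1, 2, 3))  # mean 2, sd 1, se 1/sqrt(3)
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values))
    stop("values must be non-empty and non-missing", call. = FALSE)
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  structure(list(mean = mean(values), sd = s,
                 se = if (n >= 2) s / sqrt(n) else NA_real_,
                 n = n, degenerate = n < 2),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("mean %.4g (single value; sd/se undefined)\n", x$mean))
  else
    cat(sprintf("mean %.4g +/- %.4g SD (SE %.4g, n = %d)\n",
                x$mean, x$sd, x$se, x$n))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Two-sided comparison of two independent groups at significance level
#' 0.05 with a 95 percent confidence interval for the mean difference.
#' The classical pooled-variance Student's test is the default;
#' \code{variant = "welch"} drops the equal-variance assumption.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @param conf_level Confidence level for the interval.
#' @return Object of class \code{"ttest_result"}: \code{t_statistic},
#'   \code{degrees_of_freedom}, \code{p_value}, \code{ci_95},
#'   \code{reject_at_0_05}, \code{mean_difference}, \code{variant}.
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, p ~ 0.2878
#' @export
two_sample_ttest <- function(a, b, variant = c("pooled", "welch"),
                             conf_level = 0.95) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      conf.level = conf_level)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 ci_95 = unname(tt$conf.int),
                 reject_at_0_05 = tt$p.value < 0.05,
                 mean_difference = unname(diff(rev(tt$estimate))),
                 variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "%s two-sample t-test: t = %.4f, df = %.4g, p = %.4f\n",
    if (x$variant == "pooled") "Pooled" else "Welch", x$t_statistic,
    x$degrees_of_freedom, x$p_value))
  cat(sprintf("mean difference %.4g, 95%% CI [%.4g, %.4g]; %s at 0.05\n",
              x$mean_difference, x$ci_95[1], x$ci_95[2],
              if (x$reject_at_0_05) "significant" else "insignificant"))
  invisible(x)
}
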