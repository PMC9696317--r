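#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files are two columns (wavenumber, absorbance), comma-separated
#' with dot decimals; a header line is auto-detected. JCAMP-DX support
#' covers fixed-point/AFFN \code{XYDATA=(X++(Y..Y))} blocks (the common
#' uncompressed form); SQZ/DIF/DUP-compressed files are rejected with a
#' clear message. Descending wavenumber axes (the usual FTIR export
#' order) are reversed to ascending with a note.
#'
#' @param path File path.
#' @param dialect \code{"auto"} (by extension), \code{"csv"} or
#'   \code{"jcamp"}.
#' @return A \code{\link{spectrum}}.
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("jdx", "dx", "jcm", "jcamp")) "jcamp" else "csv"
  }
  if (dialect == "csv") read_spectrum_csv(path) else read_spectrum_jcamp(path)
}

read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("wavenumber", "absorbance"))
  bad <- which(!is.finite(df$wavenumber) | !is.finite(df$absorbance))
  if (length(bad))
    stop(sprintf("non-finite value at data row %d of %s", bad[1], path),
         call. = FALSE)
  spectrum(df$wavenumber, df$absorbance)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    i <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NA_real_)
    as.numeric(sub(".*=\\s*", "", lines[i[1]]))
  }
  xfac <- grab("XFACTOR"); if (is.na(xfac)) xfac <- 1
  yfac <- grab("YFACTOR"); if (is.na(yfac)) yfac <- 1
  i0 <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(i0))
    stop("no XYDATA block found in ", path, call. = FALSE)
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", lines[i0[1]]))
    stop("only XYDATA=(X++(Y..Y)) JCAMP blocks are supported", call. = FALSE)
  iend <- grep("^##", lines)
  iend <- iend[iend > i0[1]]
  body <- lines[(i0[1] + 1):(if (length(iend)) iend[1] - 1 else length(lines))]
  body <- trimws(body[nzchar(trimws(body))])
  if (any(grepl("[A-DF-Za-df-z@%]", body)))
    stop("compressed JCAMP data (SQZ/DIF/DUP) is not supported; ",
         "export as fixed-point AFFN", call. = FALSE)
  x <- numeric(0); y <- numeric(0)
  for (ln in body) {
    v <- as.numeric(strsplit(ln, "[[:space:],]+")[[1]])
    if (anyNA(v) || length(v) < 2)
      stop("malformed XYDATA line: ", ln, call. = FALSE)
    x0 <- v[1] * xfac
    ys <- v[-1] * yfac
    # per-line abscissa: first value is the X of the first Y; subsequent
    # Ys advance by DELTAX (inferred from consecutive line starts)
    x <- c(x, x0); y <- c(y, ys[1])
    if (length(ys) > 1) {
      x <- c(x, rep(NA_real_, length(ys) - 1))
      y <- c(y, ys[-1])
    }
  }
  # fill NA abscissas by linear interpolation between line-start X values
  known <- which(!is.na(x))
  if (length(known) >= 2) {
    dx <- grab("DELTAX")
    if (is.na(dx)) dx <- (x[known[2]] - x[known[1]]) /
        (known[2] - known[1])
    x <- x[known[1]] + (seq_along(x) - 1) * dx
  }
  if (anyNA(x) || anyNA(y))
    stop("could not reconstruct the abscissa from the XYDATA block",
         call. = FALSE)
  spectrum(x, y)
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' @param s A \code{\link{spectrum}}.
#' @param path Output path.
#' @param dialect \code{"csv"} (two columns with header) or \code{"jcamp"}
#'   (AFFN \code{XYDATA=(X++(Y..Y))}).
#' @param digits Significant digits written.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("csv", "jcamp"),
                           digits = 10) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "spectrum"))
  if (dialect == "csv") {
    df <- as.data.frame(s)
    df$wavenumber <- signif(df$wavenumber, digits)
    df$absorbance <- signif(df$absorbance, digits)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    h <- mean(diff(s$wavenumbers))
    hdr <- c("##TITLE=lipospec export", "##JCAMP-DX=4.24",
             "##DATA TYPE=INFRARED SPECTRUM",
             "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
             sprintf("##FIRSTX=%.6f", s$wavenumbers[1]),
             sprintf("##LASTX=%.6f", s$wavenumbers[length(s$wavenumbers)]),
             sprintf("##DELTAX=%.6f", h),
             sprintf("##NPOINTS=%d", length(s$wavenumbers)),
             "##XFACTOR=1", "##YFACTOR=1",
             "##XYDATA=(X++(Y..Y))")
    body <- sprintf("%.6f %s", s$wavenumbers,
                    formatC(s$absorbance, format = "g", digits = digits))
    writeLines(c(hdr, body, "##END="), path)
  }
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable defaults in one serializable list: band regions, smoothing
#' and fit controls, geometry constants, the synthetic scenario (used when
#' no measured spectra are supplied), seeds and output directory. Round
#' trips losslessly through YAML via \code{\link{write_config}} /
#' \code{\link{read_config}}.
#'
#' @return Nested list of class \code{"run_config"}.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    replicates = 3,
    snr = 100,
    output_dir = "lipospec_report",
    regions = lapply(default_regions(), function(r)
      list(low = r$low, high = r$high, name = r$name)),
    sg = list(window = 9, order = 3, deriv_window = 13),
    fit = list(maxiter = 500, ftol = 1e-10, prominence = 0.1,
               refine = 0.5, fwhm_init = 18, fwhm_range = c(8, 35)),
    geometry = list(bilayer_thickness = 5, area_per_lipid = 0.71,
                    area_per_lipid_units = "nm^2",
                    protein_molar_mass = 66430),
    scenario = list(
      timepoints = c(3, 5, 10, 15, 20),
      control = list(alpha = 59.9, sheet = 23.2, coil = 16.9),
      incubated = list(alpha = 52.8, sheet = 19.1, coil = 28.0),
      amide_centers = c(1655, 1633, 1645),
      amide_fwhm = 20,
      shifts = list(
        phosphate_asym = list(before = 1230.2, after = 1233.6, fwhm = 30,
                              window = c(1180, 1300)),
        choline = list(before = 970, after = 971, fwhm = 12,
                       window = c(935, 1005)),
        ch2_asym = list(before = 2924, after = 2925, fwhm = 25,
                        window = c(2850, 3000))),
      carbonyl = list(centers = c(1714, 1731, 1738, 1742),
                      areas_before = c(0, 50, 20, 30),
                      areas_after = c(10, 40, 20, 30),
                      fwhm = 11, window = c(1695, 1765)))),
    class = "run_config")
}

#' Write a configuration to YAML
#' @param config A \code{\link{default_config}}-style list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Unspecified fields fall back to \code{\link{default_config}} values.
#'
#' @param path YAML file path.
#' @return List of class \code{"run_config"}.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_lists(unclass(default_config()), user),
            class = "run_config")
}
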