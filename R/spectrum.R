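#' Construct a spectrum
#'
#' The common currency of the package: a set of values on a strictly
#' increasing wavelength grid (nm), tagged by what the values represent.
#' Measured fluorescence `Fm`, diffuse reflectance `R`, corrected
#' fluorescence `Fc` and fluorophore basis spectra are all spectra.
#'
#' @param wavelength Numeric vector of wavelengths in nm; strictly
#'   increasing, finite, positive, length >= 2.
#' @param values Numeric vector of the same length; all finite. Units depend
#'   on `kind`: counts (raw), counts/s/mW (fluorescence after reduction),
#'   dimensionless in (0, 1] (reflectance), dimensionless (corrected, basis).
#' @param kind One of `"raw"`, `"fluorescence"`, `"reflectance"`,
#'   `"corrected"`, `"basis"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelength, values,
                     kind = c("raw", "fluorescence", "reflectance",
                              "corrected", "basis")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  values <- as.numeric(values)
  if (length(wavelength) < 2L)
    stop("wavelength grid must have length >= 2")
  if (!all(is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelengths must be finite and > 0")
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (length(values) != length(wavelength))
    stop("values length (", length(values), ") must equal grid length (",
         length(wavelength), ")")
  if (!all(is.finite(values)))
    stop("all spectrum values must be finite")
  structure(list(wavelength = wavelength, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind=%s, %d points, %.1f-%.1f nm, values [%.4g, %.4g]\n",
              x$kind, length(x$wavelength), min(x$wavelength),
              max(x$wavelength), min(x$values), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' @keywords internal
stopifnot_same_grid <- function(a, b, what_a = "first", what_b = "second") {
  if (length(a$wavelength) != length(b$wavelength) ||
      any(abs(a$wavelength - b$wavelength) > 1e-9)) {
    stop(sprintf(
      "wavelength grids differ: %s spans %.2f-%.2f nm (%d pts), %s spans %.2f-%.2f nm (%d pts)",
      what_a, min(a$wavelength), max(a$wavelength), length(a$wavelength),
      what_b, min(b$wavelength), max(b$wavelength), length(b$wavelength)))
  }
}

#' Trapezoidal integral of a spectrum over a wavelength range
#'
#' @param s A spectrum.
#' @param range Optional `c(lo, hi)` in nm; default the full grid.
#' @return Scalar integral value.
#' @export
spectrum_integral <- function(s, range = NULL) {
  stopifnot(is_spectrum(s))
  wl <- s$wavelength
  v <- s$values
  if (!is.null(range)) {
    keep <- wl >= range[1] & wl <= range[2]
    if (sum(keep) < 2L)
      stop("fewer than 2 grid points inside range [", range[1], ", ",
           range[2], "] nm")
    wl <- wl[keep]; v <- v[keep]
  }
  pracma::trapz(wl, v)
}

#' Acquisition protocol parameters
#'
#' Timing of one measurement sequence: N paired reflectance/background
#' frames followed by K repeats of the dual-excitation fluorescence block
#' (background, 375 nm, background, 405 nm), each frame integrated for
#' T seconds. Total duration is 2*N*T + 4*K*T seconds.
#'
#' @param integration_time_s Integration time T per frame in seconds.
#' @param n_reflectance N, number of reflectance frames.
#' @param n_fluor_repeats K, number of fluorescence repeat blocks.
#' @param excitation_powers Named numeric vector of laser powers in mW,
#'   names are excitation wavelengths ("375", "405").
#' @return An `"acquisition_protocol"` object with a `total_duration_s` field.
#' @export
acquisition_protocol <- function(integration_time_s = 0.2,
                                 n_reflectance = 5L,
                                 n_fluor_repeats = 5L,
                                 excitation_powers = c("375" = 5, "405" = 5)) {
  if (integration_time_s <= 0) stop("integration_time_s must be > 0")
  if (n_reflectance < 1L) stop("n_reflectance must be >= 1")
  if (n_fluor_repeats < 1L) stop("n_fluor_repeats must be >= 1")
  if (any(excitation_powers <= 0)) stop("excitation powers must be > 0")
  structure(list(
    integration_time_s = integration_time_s,
    n_reflectance = as.integer(n_reflectance),
    n_fluor_repeats = as.integer(n_fluor_repeats),
    excitation_powers = excitation_powers,
    total_duration_s = 2 * n_reflectance * integration_time_s +
      4 * n_fluor_repeats * integration_time_s),
    class = "acquisition_protocol")
}

#' Subtract a paired background frame from a signal frame
#'
#' Elementwise difference on identical grids. Negative results are allowed:
#' at this stage they reflect the detector noise floor.
#'
#' @param signal,background Spectra on identical grids.
#' @return A spectrum of the same kind as `signal`.
#' @export
subtract_background <- function(signal, background) {
  stopifnot(is_spectrum(signal), is_spectrum(background))
  stopifnot_same_grid(signal, background, "signal", "background")
  spectrum(signal$wavelength, signal$values - background$values,
           kind = signal$kind)
}

#' Average repeated frames with anomaly screening
#'
#' Frames whose integrated intensity deviates from the median integrated
#' intensity by more than `anomaly_z` robust standard deviations
#' (median/MAD) are flagged and excluded; the remaining frames are averaged
#' pointwise. This automates the visual check that no motion artifacts or
#' acquisition anomalies contaminate the repeats.
#'
#' @param frames List of spectra on a common grid (>= 1).
#' @param anomaly_z Robust z-score threshold; default 5. `Inf` disables
#'   screening.
#' @return List with `mean` (spectrum) and `flagged` (logical per frame).
#' @export
average_repeats <- function(frames, anomaly_z = 5) {
  if (length(frames) < 1L) stop("need at least one frame")
  for (f in frames) stopifnot(is_spectrum(f))
  for (f in frames[-1]) stopifnot_same_grid(frames[[1]], f, "frame 1", "frame")
  ints <- vapply(frames, spectrum_integral, numeric(1))
  med <- stats::median(ints)
  mad_ <- stats::mad(ints)  # includes the 1.4826 consistency factor
  if (mad_ < .Machine$double.eps * max(1, abs(med))) {
    # all (or most) integrals identical: anything off the median is anomalous
    z <- ifelse(abs(ints - med) <= 1e-12 * max(1, abs(med)), 0, Inf)
  } else {
    z <- abs(ints - med) / mad_
  }
  flagged <- z > anomaly_z
  if (all(flagged)) stop("no valid frames: all repeats flagged as anomalous")
  keep <- frames[!flagged]
  vals <- rowMeans(vapply(keep, function(f) f$values,
                          numeric(length(frames[[1]]$values))))
  list(mean = spectrum(frames[[1]]$wavelength, vals, kind = frames[[1]]$kind),
       flagged = flagged)
}

#' Normalize a fluorescence spectrum by excitation laser power
#'
#' Divides by the input power so intensities become counts per mW, making
#' measurements at different excitation powers comparable (fluorescence is
#' linear in excitation intensity at low power).
#'
#' @param s A spectrum.
#' @param power_mW Laser power in mW, > 0.
#' @return Spectrum with values divided by `power_mW`.
#' @export
normalize_by_power <- function(s, power_mW) {
  stopifnot(is_spectrum(s))
  if (!is.finite(power_mW) || power_mW <= 0)
    stop("power must be > 0 (got ", power_mW, ")")
  spectrum(s$wavelength, s$values / power_mW, kind = s$kind)
}

#' Calibrate reflectance against a white standard
#'
#' R(lambda) = reflectivity * sample(lambda) / standard(lambda), where both
#' inputs are background-subtracted mean frames acquired with the same
#' protocol. The result is clamped to `[r_floor, 1]` (the correction divides
#' by R^alpha, so a noise-floor R near 0 must be bounded); a warning reports
#' any clamping.
#'
#' @param sample_mean,standard_mean Background-subtracted mean spectra on
#'   the same grid; `standard_mean` must be strictly positive.
#' @param standard_reflectivity Certified reflectivity of the white
#'   standard (dimensionless, default 0.99).
#' @param r_floor Lower clamp for calibrated reflectance; default 1e-4.
#' @return A spectrum of kind `"reflectance"` with values in `[r_floor, 1]`.
#' @export
calibrate_reflectance <- function(sample_mean, standard_mean,
                                  standard_reflectivity = 0.99,
                                  r_floor = 1e-4) {
  stopifnot(is_spectrum(sample_mean), is_spectrum(standard_mean))
  stopifnot_same_grid(sample_mean, standard_mean, "sample", "standard")
  bad <- standard_mean$values <= 0
  if (any(bad))
    stop("white-standard spectrum nonpositive at wavelengths: ",
         paste(utils::head(standard_mean$wavelength[bad], 10), collapse = ", "))
  r <- standard_reflectivity * sample_mean$values / standard_mean$values
  n_clamp <- sum(r < r_floor | r > 1)
  if (n_clamp > 0)
    warning(sprintf("calibrated reflectance clamped to [%g, 1] at %d of %d wavelengths",
                    r_floor, n_clamp, length(r)))
  r <- pmin(pmax(r, r_floor), 1)
  spectrum(sample_mean$wavelength, r, kind = "reflectance")
}

#' Normalize a spectrum to unit integral
#'
#' Divides by the trapezoidal integral over `range` so the output integrates
#' to 1 there. Fitting operates on integral-normalized fluorescence, which
#' removes overall intensity and leaves only spectral shape.
#'
#' @param s A spectrum.
#' @param range Optional `c(lo, hi)` nm; default full grid.
#' @return Spectrum scaled to unit integral over `range`.
#' @export
normalize_by_integral <- function(s, range = NULL) {
  total <- spectrum_integral(s, range)
  if (!is.finite(total) || total <= 0)
    stop("integral over the normalization range is nonpositive (", total, ")")
  spectrum(s$wavelength, s$values / total, kind = s$kind)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; the target must lie inside the source span (no
#' extrapolation).
#'
#' @param s A spectrum.
#' @param target Numeric vector of target wavelengths (strictly increasing).
#' @return Spectrum on `target`.
#' @export
resample_to_grid <- function(s, target) {
  stopifnot(is_spectrum(s))
  target <- as.numeric(target)
  if (min(target) < min(s$wavelength) - 1e-9 ||
      max(target) > max(s$wavelength) + 1e-9)
    stop(sprintf("target grid [%.2f, %.2f] extends beyond source span [%.2f, %.2f] nm",
                 min(target), max(target), min(s$wavelength), max(s$wavelength)))
  v <- stats::approx(s$wavelength, s$values, xout = target, rule = 1)$y
  spectrum(target, v, kind = s$kind)
}

#' Coefficient of variation across repeated frames at one wavelength
#'
#' Sample standard deviation divided by the mean of the frame values at the
#' grid point nearest `at` (within `tol_nm`). The repeatability metric of
#' the acquisition protocol, conventionally evaluated at 510 nm.
#'
#' @param frames List of >= 2 spectra on a common grid.
#' @param at Wavelength in nm.
#' @param tol_nm Maximum distance from `at` to the nearest grid point
#'   (default 1 nm).
#' @return CoV as a fraction (not percent).
#' @export
coefficient_of_variation <- function(frames, at = 510, tol_nm = 1) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  for (f in frames[-1]) stopifnot_same_grid(frames[[1]], f, "frame 1", "frame")
  wl <- frames[[1]]$wavelength
  i <- which.min(abs(wl - at))
  if (abs(wl[i] - at) > tol_nm)
    stop(sprintf("no grid point within %g nm of %g nm (nearest: %g)",
                 tol_nm, at, wl[i]))
  v <- vapply(frames, function(f) f$values[i], numeric(1))
  m <- mean(v)
  if (m <= 0) stop("mean at ", at, " nm is nonpositive; CoV undefined")
  stats::sd(v) / m
}

#' Read a two-column spectrum file
#'
#' Format: optional '#'-prefixed header lines of the form `# key: value`
#' (recognized keys include kind, excitation_nm, integration_time_s,
#' power_mW), then two delimited columns (wavelength_nm, value).
#'
#' @param path File path.
#' @return A spectrum; header metadata is attached as attribute `"meta"`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("spectrum file '", path, "' has fewer than 2 data rows")
  parts <- strsplit(trimws(body), "[,;\t ]+")
  n_col <- lengths(parts)
  if (any(n_col < 2))
    stop("parse error in '", path, "' at data line ",
         which(n_col < 2)[1], ": expected 2 columns")
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  vv <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(wl) || anyNA(vv))
    stop("parse error in '", path, "' at data line ",
         which(is.na(wl) | is.na(vv))[1], ": non-numeric value")
  kind <- if (!is.null(meta$kind)) meta$kind else "raw"
  s <- spectrum(wl, vv, kind = kind)
  attr(s, "meta") <- meta
  s
}

#' Write a spectrum as two-column delimited text
#'
#' @param s A spectrum.
#' @param path Output path.
#' @param meta Named list of extra header entries; `kind` is always written.
#' @param sep Column delimiter (default tab; use "," for .csv outputs).
#' @export
write_spectrum <- function(s, path, meta = list(), sep = "\t") {
  stopifnot(is_spectrum(s))
  meta <- utils::modifyList(list(kind = s$kind), meta)
  hdr <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), "")
  rows <- sprintf("%.6g%s%.10g", s$wavelength, sep, s$values)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
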