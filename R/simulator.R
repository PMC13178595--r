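#' Synthetic absorber extinction spectra
#'
#' Hemoglobin-mimicking dye shapes for the liquid-phantom simulator:
#' `AR1_like` is a single broad band (center 555 nm, sigma 30 nm), like the
#' deoxyhemoglobin-shaped Acid Red 1; `AR14_like` has the oxyhemoglobin-like
#' double band (542 and 577 nm, sigma 12 and 10 nm, amplitude ratio
#' 1 : 0.9). Peak extinction is scaled to 1 a.u.; only the qualitative
#' spectral structure matters for exercising the correction.
#'
#' @param name `"AR1_like"` or `"AR14_like"`.
#' @param grid Wavelength grid (nm).
#' @return Spectrum (kind `"basis"`) of extinction in a.u. per (g/L) per cm.
#' @export
make_absorber_extinction <- function(name, grid = default_grid()) {
  grid <- as.numeric(grid)
  v <- switch(name,
    AR1_like = exp(-(grid - 555)^2 / (2 * 30^2)),
    AR14_like = {
      raw <- exp(-(grid - 542)^2 / (2 * 12^2)) +
        0.9 * exp(-(grid - 577)^2 / (2 * 10^2))
      raw / max(raw)
    },
    stop("unknown absorber '", name, "' (expected AR1_like or AR14_like)"))
  spectrum(grid, v, kind = "basis")
}

#' Reduced-scattering specification
#'
#' mu_s'(lambda) = a * (lambda / 500)^(-b), the usual scattering power law;
#' `a` is the reduced scattering coefficient at 500 nm in 1/cm.
#'
#' @param a Reduced scattering at 500 nm (> 0, default 15 /cm,
#'   tissue-like).
#' @param b Scattering power (>= 0, default 1).
#' @return A `"scattering_spec"`.
#' @export
scattering_spec <- function(a = 15, b = 1) {
  if (a <= 0) stop("a must be > 0")
  if (b < 0) stop("b must be >= 0")
  structure(list(a = a, b = b), class = "scattering_spec")
}

#' Phantom ground-truth specification
#'
#' @param id Phantom identifier.
#' @param absorbers Named numeric vector of absorber concentrations in g/L
#'   (names are extinction names, e.g. `AR1_like`).
#' @param scattering A [scattering_spec()].
#' @param true_fractions Named nonnegative fractions summing to 1, keyed to
#'   basis-library component names.
#' @param true_alpha True distortion exponent in `[0, 1]`.
#' @param noise_cv Repeat-to-repeat multiplicative noise level (fraction,
#'   default 0.02).
#' @return A `"phantom_spec"`.
#' @export
phantom_spec <- function(id, absorbers, scattering = scattering_spec(),
                         true_fractions, true_alpha, noise_cv = 0.02) {
  if (any(true_fractions < 0) || abs(sum(true_fractions) - 1) > 1e-9)
    stop("true_fractions must be nonnegative and sum to 1")
  if (true_alpha < 0 || true_alpha > 1) stop("true_alpha must be in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(id = id, absorbers = absorbers, scattering = scattering,
                 true_fractions = true_fractions, true_alpha = true_alpha,
                 noise_cv = noise_cv),
            class = "phantom_spec")
}

#' Forward-model a diffuse reflectance spectrum
#'
#' Smooth attenuation ansatz: with mu_a(lambda) = sum_k c_k * eps_k(lambda)
#' and mu_s'(lambda) = a * (lambda/500)^(-b),
#' `R = rho0 * exp(-L0 * mu_a / sqrt(1 + mu_s'/mu_a))`. R equals `rho0`
#' without absorber, decreases pointwise in every absorber concentration,
#' and increases with scattering (more scattering shortens effective photon
#' paths and returns more light). The correction method consumes R as
#' data, so only this qualitative structure matters, not radiometric
#' accuracy.
#'
#' @param phantom A [phantom_spec()].
#' @param grid Wavelength grid (nm).
#' @param rho0 Reflectance without absorber (default 0.9).
#' @param L0 Attenuation length scale (default 11, giving roughly tenfold
#'   peak attenuation at the strongest suite absorber mixes).
#' @return Spectrum of kind `"reflectance"`, values in `(0, 1]`.
#' @export
simulate_reflectance <- function(phantom, grid = default_grid(),
                                 rho0 = 0.9, L0 = 11) {
  stopifnot(inherits(phantom, "phantom_spec"))
  grid <- as.numeric(grid)
  mua <- numeric(length(grid))
  for (nm in names(phantom$absorbers)) {
    mua <- mua + phantom$absorbers[[nm]] *
      make_absorber_extinction(nm, grid)$values
  }
  mus <- phantom$scattering$a * (grid / 500)^(-phantom$scattering$b)
  att <- ifelse(mua > 0, L0 * mua / sqrt(1 + mus / pmax(mua, 1e-12)), 0)
  r <- pmin(pmax(rho0 * exp(-att), 1e-4), 1)
  spectrum(grid, r, kind = "reflectance")
}

#' Forward-model a measured fluorescence spectrum
#'
#' `Fm(lambda) = (sum_i c_i f_i(lambda)) * R(lambda)^true_alpha`, the exact
#' generative inverse of the power-law correction; a noiseless spectrum is
#' therefore exactly invertible by the adaptive fit. With `with_noise`,
#' each value is multiplied by `1 + eps(lambda)` with eps i.i.d. zero-mean
#' Gaussian of SD `noise_cv` (seeded).
#'
#' @param phantom A [phantom_spec()]; `true_fractions` names must match
#'   measured components of `library`.
#' @param library Basis library providing the emission shapes.
#' @param grid Wavelength grid.
#' @param with_noise Apply multiplicative noise (default FALSE).
#' @param seed Seed for the noise draw (required for reproducibility when
#'   `with_noise`).
#' @param scale Overall intensity scale in counts/s/mW (default 2e5, which
#'   puts single frames at typical spectrometer count levels; fractions are
#'   scale-invariant).
#' @return Spectrum of kind `"fluorescence"`.
#' @export
simulate_fluorescence <- function(phantom, library, grid = default_grid(),
                                  with_noise = FALSE, seed = NULL,
                                  scale = 2e5) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(library, "basis_library"))
  grid <- as.numeric(grid)
  nms <- vapply(library$measured, `[[`, "", "name")
  missing <- setdiff(names(phantom$true_fractions), nms)
  if (length(missing))
    stop("fraction keys not in library measured bases: ",
         paste(missing, collapse = ", "))
  model <- numeric(length(grid))
  for (nm in names(phantom$true_fractions)) {
    mb <- library$measured[[match(nm, nms)]]
    model <- model + phantom$true_fractions[[nm]] *
      resample_to_grid(mb$spectrum, grid)$values
  }
  r <- simulate_reflectance(phantom, grid)
  fm <- scale * model * r$values^phantom$true_alpha
  if (with_noise) {
    eps <- if (!is.null(seed))
      withr::with_seed(seed, stats::rnorm(length(fm), 0, phantom$noise_cv))
    else stats::rnorm(length(fm), 0, phantom$noise_cv)
    fm <- fm * (1 + eps)
  }
  spectrum(grid, pmax(fm, 0), kind = "fluorescence")
}

# study-design compositions: four FAD-suite phantoms and three NADH-suite
# phantoms with the corresponding AR1/AR14 concentration mixes (g/L) and
# TiO2 loads (mg)
.suite_compositions <- function() {
  list(
    list(id = 1L, fluor = "FAD", ar1 = 0.50, ar14 = 0.00, tio2_mg = 236),
    list(id = 2L, fluor = "FAD", ar1 = 0.50, ar14 = 0.46, tio2_mg = 214),
    list(id = 3L, fluor = "FAD", ar1 = 0.28, ar14 = 0.21, tio2_mg = 248),
    list(id = 4L, fluor = "FAD", ar1 = 0.00, ar14 = 0.42, tio2_mg = 224),
    list(id = 5L, fluor = "NADH", ar1 = 0.58, ar14 = 0.00, tio2_mg = 229),
    list(id = 6L, fluor = "NADH", ar1 = 0.28, ar14 = 0.21, tio2_mg = 244),
    list(id = 7L, fluor = "NADH", ar1 = 0.00, ar14 = 0.42, tio2_mg = 250))
}

# excitation-dependent relative brightness of the emitters: at 375 nm the
# NADH-like component is preferentially excited (~5x); at 405 nm balanced
.excitation_brightness <- function(excitation_nm) {
  if (excitation_nm == 375) c(NADH = 5, FAD = 1, TiO2 = 1)
  else c(NADH = 1, FAD = 1, TiO2 = 1)
}

#' Generate the seven-phantom synthetic suite
#'
#' Emulates the study-design template: seven phantoms, each with one
#' dominant fluorophore (FAD for phantoms 1-4, NADH for 5-7) plus the TiO2
#' emission component, hemoglobin-mimicking AR1/AR14 absorber mixes, a
#' per-phantom true distortion exponent drawn from U[0.3, 0.9], and 2%
#' multiplicative noise on both Fm and R. Each phantom is emitted at both
#' excitation tags (375-like: NADH-preferential brightness; 405-like:
#' balanced), giving 7 phantoms x 3 candidate fluorophores = 21 evaluation
#' pairs per tag.
#'
#' @param seed Integer seed; the suite is fully deterministic given it.
#' @param noise_cv Multiplicative noise level (default 0.02); 0 gives the
#'   noiseless, exactly invertible suite.
#' @param grid Wavelength grid (default [default_grid()]).
#' @param excitations Excitation tags to emit (default both 375 and 405).
#' @return List of entries `list(phantom, excitation_nm, fm, r, truth)`,
#'   where `truth` holds the tag-specific fractions and true alpha.
#' @export
generate_phantom_suite <- function(seed = 0L, noise_cv = 0.02,
                                   grid = default_grid(),
                                   excitations = c(375, 405)) {
  grid <- as.numeric(grid)
  library <- phantom_basis_library(grid)
  comps <- .suite_compositions()
  withr::with_seed(seed, {
    alphas <- stats::runif(length(comps), 0.3, 0.9)
    doms <- stats::runif(length(comps), 0.65, 0.85)
    suite <- list()
    for (i in seq_along(comps)) {
      cp <- comps[[i]]
      w <- c(NADH = 0, FAD = 0, TiO2 = 1 - doms[i])
      w[cp$fluor] <- doms[i]
      absorbers <- c(AR1_like = cp$ar1, AR14_like = cp$ar14)
      absorbers <- absorbers[absorbers > 0]
      for (ex in excitations) {
        eff <- w * .excitation_brightness(ex)[names(w)]
        fr <- eff / sum(eff)
        ph <- phantom_spec(
          id = cp$id, absorbers = absorbers,
          scattering = scattering_spec(a = 15 * cp$tio2_mg / 236),
          true_fractions = fr, true_alpha = alphas[i],
          noise_cv = noise_cv)
        r_true <- simulate_reflectance(ph, grid)
        fm <- simulate_fluorescence(ph, library, grid, with_noise = FALSE)
        if (noise_cv > 0) {
          fm <- spectrum(grid, pmax(fm$values *
            (1 + stats::rnorm(length(grid), 0, noise_cv)), 0),
            kind = "fluorescence")
          r_obs <- spectrum(grid, pmin(pmax(r_true$values *
            (1 + stats::rnorm(length(grid), 0, noise_cv)), 1e-4), 1),
            kind = "reflectance")
        } else {
          r_obs <- r_true
        }
        suite[[length(suite) + 1L]] <- list(
          phantom = ph, excitation_nm = ex, fm = fm, r = r_obs,
          truth = list(fractions = fr, alpha = alphas[i],
                       composition = list(absorbers = absorbers,
                                          tio2_mg = cp$tio2_mg)))
      }
    }
    suite
  })
}

#' Generate a raw acquisition bundle for one phantom
#'
#' Emulates the acquisition sequence: N paired reflectance/background
#' frames, N paired white-standard frames (an identical protocol on the
#' calibration standard), then K repeats of the dual-excitation
#' fluorescence block (background, 375 nm, background, 405 nm). Signal
#' frames carry multiplicative noise at the phantom's `noise_cv` plus a
#' small additive dark floor; the reduction pipeline recovers the
#' generating spectrum within the noise budget, exactly at zero noise.
#'
#' @param phantom A [phantom_spec()].
#' @param library Basis library for the emission shapes (default the
#'   phantom library on `grid`).
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @param grid Wavelength grid.
#' @param dark_level,dark_sd Additive dark floor (counts) and its noise SD;
#'   set `dark_sd = 0` together with `noise_cv = 0` for an exactly
#'   invertible bundle.
#' @return A `"raw_acquisition"` bundle with `reflectance`, `standard` and
#'   per-tag `fluorescence` frame lists, the protocol, and the generating
#'   truth.
#' @export
generate_raw_acquisition <- function(phantom, library = NULL,
                                     protocol = acquisition_protocol(),
                                     seed = 0L, grid = default_grid(),
                                     dark_level = 50, dark_sd = 1) {
  grid <- as.numeric(grid)
  if (is.null(library)) library <- phantom_basis_library(grid)
  r_true <- simulate_reflectance(phantom, grid)
  fm_true <- simulate_fluorescence(phantom, library, grid,
                                   with_noise = FALSE)
  T_ <- protocol$integration_time_s
  lamp <- 4000 * exp(-(grid - 560)^2 / (2 * 120^2))
  cv <- phantom$noise_cv
  withr::with_seed(seed, {
    dark_frame <- function() spectrum(
      grid, dark_level + stats::rnorm(length(grid), 0, dark_sd), "raw")
    noisy <- function(base) spectrum(
      grid, base * (1 + stats::rnorm(length(grid), 0, cv)) +
        dark_level + stats::rnorm(length(grid), 0, dark_sd), "raw")
    N <- protocol$n_reflectance
    refl <- list(signal = replicate(N, noisy(lamp * r_true$values / 0.99),
                                    simplify = FALSE),
                 background = replicate(N, dark_frame(), simplify = FALSE))
    std <- list(signal = replicate(N, noisy(lamp), simplify = FALSE),
                background = replicate(N, dark_frame(), simplify = FALSE))
    K <- protocol$n_fluor_repeats
    fluor <- list()
    for (tag in names(protocol$excitation_powers)) {
      power <- protocol$excitation_powers[[tag]]
      base <- fm_true$values * T_ * power
      fluor[[tag]] <- list(
        signal = replicate(K, noisy(base), simplify = FALSE),
        background = replicate(K, dark_frame(), simplify = FALSE))
    }
    structure(list(protocol = protocol, grid = grid,
                   reflectance = refl, standard = std,
                   fluorescence = fluor,
                   truth = list(fm = fm_true, r = r_true,
                                phantom = phantom)),
              class = "raw_acquisition")
  })
}

#' Reduce a raw acquisition bundle to calibrated spectra
#'
#' Applies the full reduction pipeline: paired background subtraction,
#' anomaly-screened averaging, per-second and per-mW normalization of
#' fluorescence, and white-standard calibration of reflectance. Also
#' reports the coefficient of variation at 510 nm across the fluorescence
#' repeats for each excitation tag.
#'
#' @param raw A `"raw_acquisition"` bundle.
#' @param anomaly_z Screening threshold passed to [average_repeats()].
#' @param standard_reflectivity White-standard reflectivity (default 0.99).
#' @return List with `fluorescence` (per-tag spectra in counts/s/mW),
#'   `reflectance` (calibrated spectrum), `cov_510` (per-tag fraction), and
#'   per-stage anomaly `flags`.
#' @export
reduce_acquisition <- function(raw, anomaly_z = 5,
                               standard_reflectivity = 0.99) {
  stopifnot(inherits(raw, "raw_acquisition"))
  sub_pairs <- function(block)
    mapply(subtract_background, block$signal, block$background,
           SIMPLIFY = FALSE)
  refl_frames <- sub_pairs(raw$reflectance)
  std_frames <- sub_pairs(raw$standard)
  refl_avg <- average_repeats(refl_frames, anomaly_z)
  std_avg <- average_repeats(std_frames, anomaly_z)
  reflectance <- calibrate_reflectance(refl_avg$mean, std_avg$mean,
                                       standard_reflectivity)
  T_ <- raw$protocol$integration_time_s
  fluor <- list(); cov510 <- list(); flags <- list(
    reflectance = refl_avg$flagged, standard = std_avg$flagged)
  for (tag in names(raw$fluorescence)) {
    frames <- sub_pairs(raw$fluorescence[[tag]])
    avg <- average_repeats(frames, anomaly_z)
    power <- raw$protocol$excitation_powers[[tag]]
    per_s <- spectrum(avg$mean$wavelength, avg$mean$values / T_,
                      kind = "fluorescence")
    fluor[[tag]] <- normalize_by_power(per_s, power)
    cov510[[tag]] <- coefficient_of_variation(frames, at = 510)
    flags[[paste0("fluor_", tag)]] <- avg$flagged
  }
  list(fluorescence = fluor, reflectance = reflectance,
       cov_510 = cov510, flags = flags)
}

#' Timecourse specification for perfusion monitoring simulation
#'
#' Defaults emulate an organ-preservation protocol: 120 min of hypothermic
#' oxygenated perfusion (HOPE, transparent preservation solution, mild FAD
#' drift upward), 60 min of warm ischemia (no perfusion absorber,
#' lipopigments rising 0.01 to 0.03), then 120 min of normothermic machine
#' perfusion (NMP, blood-strength absorption, FAD fraction 0.40 to 0.60
#' with NADH falling). Fractions are linearly interpolated within each
#' phase and must sum to 1 at every knot.
#'
#' @param phases List of phase definitions: `name`, `duration_min`,
#'   `fractions_start` and `fractions_end` (named, sum 1), and
#'   `absorber_regime` in `{"preservation_solution", "none", "blood"}`.
#' @param sampling_interval_min Minutes between samples (default 5).
#' @param noise_cv Multiplicative noise level (default 0.02).
#' @return A `"timecourse_spec"`.
#' @export
timecourse_spec <- function(phases = default_timecourse_phases(),
                            sampling_interval_min = 5,
                            noise_cv = 0.02) {
  for (ph in phases) {
    for (knot in list(ph$fractions_start, ph$fractions_end)) {
      if (abs(sum(knot) - 1) > 1e-9)
        stop("phase '", ph$name, "': fractions must sum to 1 at every knot")
      if (any(knot < 0)) stop("phase '", ph$name, "': negative fraction")
    }
  }
  structure(list(phases = phases,
                 sampling_interval_min = sampling_interval_min,
                 noise_cv = noise_cv),
            class = "timecourse_spec")
}

#' @rdname timecourse_spec
#' @export
default_timecourse_phases <- function() {
  list(
    list(name = "HOPE", duration_min = 120,
         fractions_start = c(NADH = 0.45, FAD = 0.38, FMN_bound = 0.16,
                             lipopigments = 0.01),
         fractions_end = c(NADH = 0.41, FAD = 0.44, FMN_bound = 0.14,
                           lipopigments = 0.01),
         absorber_regime = "preservation_solution"),
    list(name = "warm_ischemia", duration_min = 60,
         fractions_start = c(NADH = 0.40, FAD = 0.45, FMN_bound = 0.14,
                             lipopigments = 0.01),
         fractions_end = c(NADH = 0.32, FAD = 0.52, FMN_bound = 0.13,
                           lipopigments = 0.03),
         absorber_regime = "none"),
    list(name = "NMP", duration_min = 120,
         fractions_start = c(NADH = 0.47, FAD = 0.40, FMN_bound = 0.11,
                             lipopigments = 0.02),
         fractions_end = c(NADH = 0.30, FAD = 0.60, FMN_bound = 0.08,
                           lipopigments = 0.02),
         absorber_regime = "blood"))
}

# absorber concentrations (g/L) and true distortion exponent per regime
.regime_params <- function(regime) {
  switch(regime,
    preservation_solution = list(absorbers = c(AR1_like = 0.04,
                                               AR14_like = 0.04),
                                 alpha = 0.45),
    none = list(absorbers = c(AR1_like = 0.01), alpha = 0.40),
    blood = list(absorbers = c(AR1_like = 0.35, AR14_like = 0.30),
                 alpha = 0.80),
    stop("unknown absorber regime '", regime, "'"))
}

#' Basis library for the simulated perfusion timecourse
#'
#' Four measured-type synthetic emission shapes (NADH-like, FAD-like,
#' protein-bound-FMN-like at 495/15 nm, lipopigment-like at 590/10 nm) on
#' the liver fit range 480-645 nm. The generator and the fits share these
#' shapes, so monitoring tests probe the correction and trend analysis,
#' not basis mismatch.
#'
#' @param grid Wavelength grid.
#' @param fit_range Default `c(480, 645)`.
#' @return A basis library.
#' @export
timecourse_basis_library <- function(grid = default_grid(),
                                     fit_range = c(480, 645)) {
  basis_library(
    measured = list(
      .synthetic_measured("NADH", grid),
      .synthetic_measured("FAD", grid),
      measured_basis("FMN_bound", gaussian_component(grid, 495, 15)),
      measured_basis("lipopigments", gaussian_component(grid, 590, 10))),
    gaussian = list(),
    fit_range = fit_range)
}

#' Simulate a monitored perfusion timecourse
#'
#' Samples fluorescence/reflectance pairs along the phase protocol of a
#' [timecourse_spec()]: fractions interpolate linearly within each phase,
#' the absorber regime switches the reflectance-generating parameters at
#' phase boundaries, and every sample records its ground truth.
#'
#' @param spec A [timecourse_spec()].
#' @param library Basis library (default [timecourse_basis_library()] on
#'   `grid`).
#' @param grid Wavelength grid.
#' @param seed Integer seed for the noise draws.
#' @return List with `samples` (each `time_min`, `phase`, `fm`, `r`,
#'   `truth_fractions`, `truth_alpha`) and `phases` (data.frame of windows
#'   for [phase_trends()]).
#' @export
generate_timecourse <- function(spec = timecourse_spec(), library = NULL,
                                grid = default_grid(), seed = 0L) {
  stopifnot(inherits(spec, "timecourse_spec"))
  grid <- as.numeric(grid)
  if (is.null(library)) library <- timecourse_basis_library(grid)
  starts <- cumsum(c(0, vapply(spec$phases, `[[`, numeric(1),
                               "duration_min")))
  windows <- data.frame(
    phase = vapply(spec$phases, `[[`, "", "name"),
    start = starts[-length(starts)],
    end = starts[-1], stringsAsFactors = FALSE)
  samples <- list()
  withr::with_seed(seed, {
    for (i in seq_along(spec$phases)) {
      ph <- spec$phases[[i]]
      rp <- .regime_params(ph$absorber_regime)
      times <- seq(windows$start[i], windows$end[i],
                   by = spec$sampling_interval_min)
      if (i < length(spec$phases)) times <- times[times < windows$end[i]]
      for (t in times) {
        u <- (t - windows$start[i]) / ph$duration_min
        fr <- (1 - u) * ph$fractions_start + u * ph$fractions_end
        fr <- fr / sum(fr)
        pspec <- phantom_spec(
          id = sprintf("%s_t%03d", ph$name, round(t)),
          absorbers = rp$absorbers,
          true_fractions = fr, true_alpha = rp$alpha,
          noise_cv = spec$noise_cv)
        r_true <- simulate_reflectance(pspec, grid)
        fm <- simulate_fluorescence(pspec, library, grid,
                                    with_noise = FALSE)
        if (spec$noise_cv > 0) {
          fm <- spectrum(grid, pmax(fm$values *
            (1 + stats::rnorm(length(grid), 0, spec$noise_cv)), 0),
            "fluorescence")
          r_obs <- spectrum(grid, pmin(pmax(r_true$values *
            (1 + stats::rnorm(length(grid), 0, spec$noise_cv)), 1e-4), 1),
            "reflectance")
        } else r_obs <- r_true
        samples[[length(samples) + 1L]] <- list(
          time_min = t, phase = ph$name, fm = fm, r = r_obs,
          truth_fractions = fr, truth_alpha = rp$alpha)
      }
    }
  })
  list(samples = samples, phases = windows)
}
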