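#' Default emission wavelength grid
#'
#' 480-650 nm at 1 nm steps: covers the phantom fit range (480-620 nm) and
#' the liver fit range (480-645 nm) with margin for resampling.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(480, 650, by = 1)

#' Normalized Gaussian emission component
#'
#' g(lambda; mu, sigma) = 1/(sigma*sqrt(2*pi)) * exp(-(lambda-mu)^2/(2*sigma^2)),
#' the analytic line shape used for fluorophores whose emission cannot be
#' measured in phantoms (protein-bound FMN, lipopigments, PpIX).
#'
#' @param grid Numeric wavelength vector (nm).
#' @param mu Center (nm).
#' @param sigma Width (nm), > 0.
#' @return Spectrum of kind `"basis"`.
#' @export
gaussian_component <- function(grid, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  grid <- as.numeric(grid)
  v <- stats::dnorm(grid, mean = mu, sd = sigma)
  spectrum(grid, v, kind = "basis")
}

#' Box constraint for a Gaussian emission component
#'
#' The fitted center and width are confined to
#' `[mu0 - mu_tol, mu0 + mu_tol] x [sigma0 - sigma_tol, sigma0 + sigma_tol]`,
#' which stabilizes the joint fit and prevents a free Gaussian from
#' absorbing unrelated spectral structure.
#'
#' @param name Fluorophore id.
#' @param mu0,mu_tol Center and half-width of the center box (nm).
#' @param sigma0,sigma_tol Width and half-width of the width box (nm);
#'   `sigma0 - sigma_tol` must stay positive.
#' @return A `"gaussian_spec"` object.
#' @export
gaussian_spec <- function(name, mu0, mu_tol, sigma0, sigma_tol) {
  if (sigma0 - sigma_tol <= 0)
    stop("sigma box must stay positive: sigma0 - sigma_tol = ",
         sigma0 - sigma_tol)
  structure(list(name = name, mu0 = mu0, mu_tol = mu_tol,
                 sigma0 = sigma0, sigma_tol = sigma_tol),
            class = "gaussian_spec")
}

#' Measured emission basis spectrum
#'
#' A fixed, nonnegative emission shape measured for one fluorophore at one
#' excitation wavelength (in this package's libraries, NADH- and FAD-like
#' shapes plus the broad TiO2 component of the phantom suite).
#'
#' @param name Fluorophore id.
#' @param s Spectrum (nonnegative, not identically zero).
#' @param excitation_nm Excitation line (375 or 405), or NA.
#' @return A `"measured_basis"` object.
#' @export
measured_basis <- function(name, s, excitation_nm = NA_real_) {
  stopifnot(is_spectrum(s))
  if (any(s$values < 0)) stop("measured basis '", name, "' has negative values")
  if (all(s$values == 0)) stop("measured basis '", name, "' is identically zero")
  structure(list(name = name, excitation_nm = excitation_nm,
                 spectrum = spectrum(s$wavelength, s$values, kind = "basis")),
            class = "measured_basis")
}

#' Assemble a basis library
#'
#' Houses the unmixing model: fixed measured bases first, then
#' box-constrained Gaussian components, plus the wavelength fit range.
#' Measured bases are stored normalized to unit trapezoidal integral over
#' the fit range so that amplitudes are comparable across components and
#' relative fractions `c_i = C_i / sum(C_i)` are well defined.
#'
#' @param measured List of [measured_basis()] objects (may be empty).
#' @param gaussian List of [gaussian_spec()] objects (may be empty).
#' @param fit_range `c(lo, hi)` nm over which spectra are fitted.
#' @return A `"basis_library"` object.
#' @export
basis_library <- function(measured = list(), gaussian = list(),
                          fit_range = c(480, 620)) {
  if (length(measured) + length(gaussian) < 1L)
    stop("basis library needs at least one component")
  nms <- c(vapply(measured, `[[`, "", "name"),
           vapply(gaussian, `[[`, "", "name"))
  if (anyDuplicated(nms))
    stop("duplicate component names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (fit_range[2] <= fit_range[1]) stop("fit_range must be increasing")
  measured <- lapply(measured, function(mb) {
    tot <- spectrum_integral(mb$spectrum, fit_range)
    if (tot <= 0)
      stop("measured basis '", mb$name, "' is zero on the fit range")
    mb$spectrum <- spectrum(mb$spectrum$wavelength, mb$spectrum$values / tot,
                            kind = "basis")
    mb
  })
  structure(list(measured = measured, gaussian = gaussian,
                 fit_range = as.numeric(fit_range)),
            class = "basis_library")
}

#' Component names of a library, measured bases first
#' @param library A basis library.
#' @return Character vector in design-matrix column order.
#' @export
component_names <- function(library) {
  stopifnot(inherits(library, "basis_library"))
  c(vapply(library$measured, `[[`, "", "name"),
    vapply(library$gaussian, `[[`, "", "name"))
}

#' @export
print.basis_library <- function(x, ...) {
  cat(sprintf("<basis_library> %d measured + %d gaussian components, fit range %g-%g nm\n",
              length(x$measured), length(x$gaussian),
              x$fit_range[1], x$fit_range[2]))
  cat("  components:", paste(component_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Build the unmixing design matrix
#'
#' One column per component on the given grid: measured bases (fixed
#' shapes, linearly resampled) first, then Gaussian components evaluated at
#' the supplied `(mu, sigma)` parameters, which must lie inside each
#' component's constraint box.
#'
#' @param library A basis library.
#' @param grid Numeric wavelength vector.
#' @param gaussian_params Matrix with one row per Gaussian component (in
#'   library order) and columns `mu`, `sigma`; NULL means the box centers.
#' @return Numeric matrix `[length(grid) x n_components]` with named columns.
#' @export
build_design_matrix <- function(library, grid, gaussian_params = NULL) {
  stopifnot(inherits(library, "basis_library"))
  grid <- as.numeric(grid)
  cols <- lapply(library$measured, function(mb)
    resample_to_grid(mb$spectrum, grid)$values)
  ng <- length(library$gaussian)
  if (ng > 0) {
    if (is.null(gaussian_params)) {
      gaussian_params <- cbind(
        mu = vapply(library$gaussian, `[[`, numeric(1), "mu0"),
        sigma = vapply(library$gaussian, `[[`, numeric(1), "sigma0"))
    }
    gaussian_params <- matrix(as.numeric(gaussian_params), ncol = 2,
                              dimnames = list(NULL, c("mu", "sigma")))
    if (nrow(gaussian_params) != ng)
      stop("gaussian_params must have one row per Gaussian component")
    for (i in seq_len(ng)) {
      gs <- library$gaussian[[i]]
      mu <- gaussian_params[i, "mu"]; sg <- gaussian_params[i, "sigma"]
      if (mu < gs$mu0 - gs$mu_tol - 1e-9 || mu > gs$mu0 + gs$mu_tol + 1e-9)
        stop(sprintf("component '%s': mu=%.3f outside box [%g, %g]",
                     gs$name, mu, gs$mu0 - gs$mu_tol, gs$mu0 + gs$mu_tol))
      if (sg < gs$sigma0 - gs$sigma_tol - 1e-9 ||
          sg > gs$sigma0 + gs$sigma_tol + 1e-9)
        stop(sprintf("component '%s': sigma=%.3f outside box [%g, %g]",
                     gs$name, sg, gs$sigma0 - gs$sigma_tol,
                     gs$sigma0 + gs$sigma_tol))
      cols <- c(cols, list(gaussian_component(grid, mu, sg)$values))
    }
  }
  A <- do.call(cbind, cols)
  colnames(A) <- component_names(library)
  A
}

#' Gaussian constraint defaults for the liver fluorophore set
#'
#' Center and width boxes for the components whose emission is modeled
#' analytically: protein-bound FMN, lipopigments and the two PpIX emission
#' peaks near 620 and 636 nm. Read from the packaged constraint file
#' `extdata/liver_gaussian_constraints.json`.
#'
#' @return data.frame with columns name, mu0, mu_tol, sigma0, sigma_tol (nm).
#' @export
liver_gaussian_defaults <- function() {
  path <- system.file("extdata", "liver_gaussian_constraints.json",
                      package = "fluorcorrect", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)$fluorophores
}

# synthetic emission shapes used by the simulator and packaged libraries;
# broad overlapping bands qualitatively like NADH/FAD/TiO2 emission
.synthetic_basis_shapes <- function() {
  list(NADH = c(mu = 470, sigma = 38),
       FAD = c(mu = 528, sigma = 33),
       TiO2 = c(mu = 500, sigma = 60))
}

.synthetic_measured <- function(name, grid, excitation_nm = NA_real_) {
  p <- .synthetic_basis_shapes()[[name]]
  if (is.null(p)) stop("no synthetic shape for '", name, "'")
  measured_basis(name, gaussian_component(grid, p["mu"], p["sigma"]),
                 excitation_nm = excitation_nm)
}

#' Phantom-suite basis library (synthetic shapes)
#'
#' Three measured-type components - NADH-like, FAD-like and the broad TiO2
#' emission - with no Gaussian components, on the phantom fit range
#' 480-620 nm. The shapes are synthetic stand-ins generated by the package
#' (broad overlapping Gaussians); every phantom test uses the generator's
#' own bases, so only their overlap structure matters.
#'
#' @param grid Wavelength grid; default [default_grid()].
#' @param fit_range Fit range, default `c(480, 620)`.
#' @return A basis library with components NADH, FAD, TiO2.
#' @export
phantom_basis_library <- function(grid = default_grid(),
                                  fit_range = c(480, 620)) {
  basis_library(
    measured = lapply(c("NADH", "FAD", "TiO2"), .synthetic_measured,
                      grid = grid),
    gaussian = list(),
    fit_range = fit_range)
}

#' Liver basis library (synthetic measured bases + constrained Gaussians)
#'
#' The six-fluorophore unmixing model for liver tissue: measured-type NADH
#' and FAD bases (synthetic stand-in shapes) plus box-constrained Gaussian
#' components for protein-bound FMN, lipopigments and the two PpIX peaks,
#' on the liver fit range 480-645 nm.
#'
#' @param grid Wavelength grid; default [default_grid()].
#' @param fit_range Fit range, default `c(480, 645)`.
#' @return A basis library with components NADH, FAD, FMN_bound,
#'   lipopigments, PpIX_636, PpIX_620.
#' @export
liver_basis_library <- function(grid = default_grid(),
                                fit_range = c(480, 645)) {
  g <- liver_gaussian_defaults()
  basis_library(
    measured = lapply(c("NADH", "FAD"), .synthetic_measured, grid = grid),
    gaussian = lapply(seq_len(nrow(g)), function(i)
      gaussian_spec(g$name[i], g$mu0[i], g$mu_tol[i], g$sigma0[i],
                    g$sigma_tol[i])),
    fit_range = fit_range)
}

#' Save / load a basis library as JSON
#'
#' Measured bases are stored inline (wavelength and value arrays); Gaussian
#' components store their constraint boxes. Round-trips exactly up to
#' numeric printing precision.
#'
#' @param library A basis library.
#' @param path JSON file path.
#' @return `load_basis_library` returns the library; `save_basis_library`
#'   returns `path` invisibly.
#' @export
save_basis_library <- function(library, path) {
  stopifnot(inherits(library, "basis_library"))
  obj <- list(
    fit_range = library$fit_range,
    measured = lapply(library$measured, function(mb) list(
      name = mb$name, excitation_nm = mb$excitation_nm,
      wavelength = mb$spectrum$wavelength, values = mb$spectrum$values)),
    gaussian = lapply(library$gaussian, function(gs)
      gs[c("name", "mu0", "mu_tol", "sigma0", "sigma_tol")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_basis_library
#' @export
load_basis_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  measured <- list()
  if (!is.null(obj$measured) && length(obj$measured)) {
    md <- obj$measured
    measured <- lapply(seq_along(md$name), function(i)
      measured_basis(md$name[i],
                     spectrum(md$wavelength[[i]], md$values[[i]], "basis"),
                     excitation_nm = md$excitation_nm[i]))
  }
  gaussian <- list()
  if (!is.null(obj$gaussian) && length(obj$gaussian)) {
    gd <- obj$gaussian
    gaussian <- lapply(seq_along(gd$name), function(i)
      gaussian_spec(gd$name[i], gd$mu0[i], gd$mu_tol[i], gd$sigma0[i],
                    gd$sigma_tol[i]))
  }
  basis_library(measured = measured, gaussian = gaussian,
                fit_range = as.numeric(obj$fit_range))
}
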