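test_that("power correction has the stated exact identities", {
  grid <- c(500, 510)
  fm <- spectrum(grid, c(1, 1), "fluorescence")
  r <- spectrum(grid, c(0.25, 1.0), "reflectance")
  expect_equal(correct_power(fm, r, 0)$values, fm$values)       # alpha = 0
  ones <- spectrum(grid, c(1, 1), "reflectance")
  expect_equal(correct_power(fm, ones, 0.73)$values, fm$values) # R == 1
  expect_equal(correct_power(fm, r, 0.5)$values, c(2, 1))       # 1/sqrt(.25)
  expect_equal(correct_power(fm, r, 1)$values, fm$values / r$values)
  expect_error(correct_power(fm, spectrum(c(500, 520), c(1, 1)), 1),
               "grids differ")
  expect_error(correct_power(fm, r, NA), "finite")
})

test_that("fixed-alpha fit recovers an exact basis combination", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  A <- build_design_matrix(lib, grid)
  fm <- spectrum(grid, as.numeric(A %*% c(0, 0.7, 0.3)), "fluorescence")
  ones <- spectrum(grid, rep(1, length(grid)), "reflectance")
  res <- fit_fixed_alpha(fm, ones, 1, lib)
  expect_equal(unname(res$fractions), c(0, 0.7, 0.3), tolerance = 1e-8)
  expect_lt(res$mse, 1e-16)
})

test_that("Kim correction exactly inverts a distortion generated with alpha 1", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  ph <- test_phantom(fractions = c(FAD = 0.5, TiO2 = 0.5), alpha = 1)
  pair <- test_pair(ph, lib, grid)
  res <- fit_fixed_alpha(pair$fm, pair$r, 1, lib)
  expect_equal(unname(res$fractions), c(0, 0.5, 0.5), tolerance = 1e-6)
  expect_lt(res$mse, 1e-12)
  # ignoring the distortion (alpha = 0) must fit strictly worse
  res0 <- fit_fixed_alpha(pair$fm, pair$r, 0, lib)
  expect_gt(res0$mse, 100 * res$mse + 1e-12)
})

test_that("adaptive fit recovers the generating exponent and fractions", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  ph <- test_phantom(fractions = c(FAD = 0.7, TiO2 = 0.3), alpha = 0.5)
  pair <- test_pair(ph, lib, grid)
  res <- fit_adaptive(pair$fm, pair$r, lib)
  expect_equal(res$alpha, 0.5, tolerance = 0.01)
  expect_equal(res$fractions[["FAD"]], 0.7, tolerance = 0.01)
  expect_equal(res$fractions[["TiO2"]], 0.3, tolerance = 0.01)
  expect_lt(res$fractions[["NADH"]], 0.01)
  expect_true(res$alpha_identifiable)
  expect_true(res$converged)
  # recovered corrected spectrum equals the undistorted model up to scale
  model_true <- as.numeric(build_design_matrix(lib, res$corrected$wavelength)
                           %*% c(0, 0.7, 0.3))
  model_true <- model_true / pracma::trapz(res$corrected$wavelength, model_true)
  corr <- normalize_by_integral(res$corrected)$values
  expect_lt(max(abs(corr - model_true)) / max(model_true), 1e-6)
})

test_that("constant reflectance makes alpha unidentifiable, fractions fall back to the plain fit", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  A <- build_design_matrix(lib, grid)
  fm <- spectrum(grid, as.numeric(A %*% c(0.2, 0.5, 0.3)), "fluorescence")
  r_const <- spectrum(grid, rep(0.8, length(grid)), "reflectance")
  res <- fit_adaptive(fm, r_const, lib)
  expect_false(res$alpha_identifiable)
  expect_equal(res$alpha, 0)
  plain <- fit_fixed_alpha(fm, spectrum(grid, rep(1, length(grid)),
                                        "reflectance"), 0, lib)
  expect_equal(res$fractions, plain$fractions, tolerance = 1e-9)
})

test_that("alpha and fractions are invariant to rescaling the fluorescence", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  pair <- test_pair(test_phantom(alpha = 0.62), lib, grid)
  res1 <- fit_adaptive(pair$fm, pair$r, lib)
  fm_k <- spectrum(grid, 37.5 * pair$fm$values, "fluorescence")
  res2 <- fit_adaptive(fm_k, pair$r, lib)
  expect_equal(res2$alpha, res1$alpha, tolerance = 1e-9)
  expect_equal(res2$fractions, res1$fractions, tolerance = 1e-9)
})

test_that("fixed-alpha overcorrection misattributes fractions that the adaptive fit does not", {
  # NADH-suite phantom with strong absorber: freezing alpha at 1 assigns a
  # spurious > 5% fraction to an absent fluorophore; the adaptive fit stays
  # below the 1% detection level
  grid <- default_grid()
  lib <- phantom_basis_library(grid)
  ph <- test_phantom(id = 6, absorbers = c(AR1_like = 0.28, AR14_like = 0.21),
                     fractions = c(NADH = 0.92, TiO2 = 0.08),
                     alpha = 0.42, noise = 0.02)
  pair <- test_pair(ph, lib, grid, seed = 1)
  kim <- fit_fixed_alpha(pair$fm, pair$r, 1, lib)
  new <- fit_adaptive(pair$fm, pair$r, lib)
  expect_gt(kim$fractions[["FAD"]], 0.05)
  expect_lt(new$fractions[["FAD"]], 0.01)
})

test_that("shared-alpha calibration recovers a common generating exponent", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  pairs <- lapply(1:4, function(i) {
    ph <- test_phantom(id = i, absorbers = c(AR1_like = 0.2 + 0.1 * i),
                       fractions = c(FAD = 0.5 + 0.05 * i,
                                     TiO2 = 0.5 - 0.05 * i),
                       alpha = 0.55)
    test_pair(ph, lib, grid)
  })
  cal <- calibrate_valdes_alpha(pairs, 375, lib)
  expect_equal(cal$alpha, 0.55, tolerance = 0.02)
  expect_equal(cal$n_pairs, 4)
  expect_error(calibrate_valdes_alpha(list(), 375, lib), "at least one")
  # single pair: calibration and adaptive fit share the same objective
  single <- calibrate_valdes_alpha(pairs[1], 375, lib)
  ad <- fit_adaptive(pairs[[1]]$fm, pairs[[1]]$r, lib)
  expect_equal(single$alpha, ad$alpha, tolerance = 1e-3)
})

test_that("brute-force alpha profile locates the generating exponent", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  pair <- test_pair(test_phantom(alpha = 0.5), lib, grid)
  oracle <- alpha_profile_oracle(pair$fm, pair$r, lib, grid_step = 0.01)
  expect_equal(oracle$alpha_star, 0.5, tolerance = 0.01 + 1e-12)
  # the profile at alpha = 1 is the Kim-model residual
  kim <- fit_fixed_alpha(pair$fm, pair$r, 1, lib)
  expect_equal(oracle$rss[length(oracle$rss)], kim$rss, tolerance = 1e-10)
  expect_error(alpha_profile_oracle(pair$fm, pair$r, lib, 0.5), "grid_step")
})

test_that("adaptive mse never exceeds any fixed-alpha mse (feasibility dominance)", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  withr::with_seed(21, {
    for (i in 1:8) {
      ph <- test_phantom(
        id = i, absorbers = c(AR1_like = runif(1, 0.1, 0.6)),
        fractions = local({
          w <- c(NADH = runif(1), FAD = runif(1), TiO2 = runif(1))
          w / sum(w)
        }),
        alpha = runif(1), noise = 0.02)
      pair <- test_pair(ph, lib, grid, seed = i)
      ad <- fit_adaptive(pair$fm, pair$r, lib)
      for (a in c(0, runif(1), 1)) {
        fx <- fit_fixed_alpha(pair$fm, pair$r, a, lib)
        expect_lte(ad$mse, fx$mse + 1e-8)
      }
    }
  })
})

test_that("random initializations converge to one solution on a well-posed instance", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  pair <- test_pair(test_phantom(alpha = 0.5), lib, grid)
  ms <- multistart_robustness(pair$fm, pair$r, lib, n_starts = 20, seed = 9)
  expect_equal(ms$n_converged, 20)
  expect_lt(ms$alpha_dispersion, 1e-3)
  expect_lt(max(ms$fraction_dispersion), 1e-3)
  # single start: zero dispersion by definition
  one <- multistart_robustness(pair$fm, pair$r, lib, n_starts = 1, seed = 9)
  expect_equal(one$alpha_dispersion, 0)
  # constant R: alpha dispersion reported as not applicable
  r_const <- spectrum(grid, rep(0.8, length(grid)), "reflectance")
  flat <- multistart_robustness(pair$fm, r_const, lib, n_starts = 5, seed = 1)
  expect_false(flat$alpha_applicable)
  expect_true(is.na(flat$alpha_dispersion))
})

test_that("joint Gaussian fit recovers shape parameters inside their boxes", {
  grid <- default_grid()
  lib <- liver_basis_library(grid)
  true_g <- cbind(mu = c(495.5, 590.5, 637, 619),
                  sigma = c(15.5, 10.3, 6.25, 8.25))
  A <- build_design_matrix(lib, grid, true_g)
  Ctrue <- c(NADH = 0.4, FAD = 0.45, FMN_bound = 0.05,
             lipopigments = 0.08, PpIX_636 = 0.02, PpIX_620 = 0)
  ph <- test_phantom(absorbers = c(AR1_like = 0.35, AR14_like = 0.3),
                     fractions = c(NADH = 1), alpha = 0.7)
  r <- simulate_reflectance(ph, grid)
  fm <- spectrum(grid, as.numeric(A %*% Ctrue) * r$values^0.7,
                 "fluorescence")
  res <- fit_adaptive(fm, r, lib, fit_options(seed = 1, n_starts = 4))
  expect_equal(res$alpha, 0.7, tolerance = 0.01)
  expect_equal(unname(res$fractions), unname(Ctrue / sum(Ctrue)),
               tolerance = 0.01)
  g <- res$gaussian_fit
  expect_equal(g$mu[g$name == "lipopigments"], 590.5, tolerance = 0.3)
  for (i in seq_along(lib$gaussian)) {
    gs <- lib$gaussian[[i]]
    row <- g[g$name == gs$name, ]
    expect_gte(row$mu, gs$mu0 - gs$mu_tol - 1e-9)
    expect_lte(row$mu, gs$mu0 + gs$mu_tol + 1e-9)
    expect_gte(row$sigma, gs$sigma0 - gs$sigma_tol - 1e-9)
    expect_lte(row$sigma, gs$sigma0 + gs$sigma_tol + 1e-9)
  }
})

test_that("unmix results satisfy the fraction and bound invariants", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  withr::with_seed(31, {
    for (i in 1:5) {
      ph <- test_phantom(id = i, alpha = runif(1), noise = 0.02,
                         fractions = c(FAD = 0.6, TiO2 = 0.4))
      pair <- test_pair(ph, lib, grid, seed = 100 + i)
      res <- fit_adaptive(pair$fm, pair$r, lib)
      expect_true(all(res$amplitudes >= 0))
      expect_gte(res$alpha, 0); expect_lte(res$alpha, 1)
      expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
      expect_true(all(res$fractions >= 0 & res$fractions <= 1))
    }
  })
})
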