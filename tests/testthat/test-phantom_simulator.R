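test_that("absorber extinction shapes match their design", {
  grid <- seq(480, 650, by = 1)
  ar1 <- make_absorber_extinction("AR1_like", grid)
  expect_equal(grid[which.max(ar1$values)], 555)
  expect_equal(max(ar1$values), 1)
  ar14 <- make_absorber_extinction("AR14_like", grid)
  # exactly two local maxima on the 1 nm grid
  v <- ar14$values
  n_max <- sum(diff(sign(diff(v))) == -2)
  expect_equal(n_max, 2)
  # 50:50 mixture extinction is the mean of the two curves (linearity)
  mix <- 0.5 * ar1$values + 0.5 * ar14$values
  expect_equal(mix, (ar1$values + ar14$values) / 2)
  expect_error(make_absorber_extinction("hemoglobin", grid), "unknown")
})

test_that("reflectance forward model has the right monotonic structure", {
  grid <- coarse_grid()
  clear <- phantom_spec(1, c(AR1_like = 0), scattering_spec(),
                        c(FAD = 1), 0.5)
  r0 <- simulate_reflectance(clear, grid)
  expect_equal(r0$values, rep(0.9, length(grid)))  # no absorber -> rho0
  ph1 <- phantom_spec(1, c(AR1_like = 0.3), scattering_spec(), c(FAD = 1), 0.5)
  ph2 <- phantom_spec(1, c(AR1_like = 0.6), scattering_spec(), c(FAD = 1), 0.5)
  r1 <- simulate_reflectance(ph1, grid)
  r2 <- simulate_reflectance(ph2, grid)
  eps_pos <- make_absorber_extinction("AR1_like", grid)$values > 1e-6
  expect_true(all(r2$values[eps_pos] < r1$values[eps_pos]))
  expect_true(all(r1$values > 0 & r1$values <= 1))
  # higher scattering returns more light
  hi_scat <- phantom_spec(1, c(AR1_like = 0.3), scattering_spec(a = 30),
                          c(FAD = 1), 0.5)
  r3 <- simulate_reflectance(hi_scat, grid)
  expect_true(all(r3$values[eps_pos] > r1$values[eps_pos]))
})

test_that("fluorescence forward model is the exact generative inverse", {
  grid <- coarse_grid()
  lib <- phantom_basis_library(grid)
  # alpha 0: Fm proportional to the basis mixture regardless of R
  ph0 <- test_phantom(alpha = 0)
  fm0 <- simulate_fluorescence(ph0, lib, grid)
  A <- build_design_matrix(lib, grid)
  model <- as.numeric(A %*% c(0, 0.7, 0.3))
  expect_equal(fm0$values / max(fm0$values), model / max(model),
               tolerance = 1e-12)
  # seeding contract
  ph <- test_phantom(alpha = 0.5, noise = 0.02)
  n1 <- simulate_fluorescence(ph, lib, grid, with_noise = TRUE, seed = 7)
  n2 <- simulate_fluorescence(ph, lib, grid, with_noise = TRUE, seed = 7)
  n3 <- simulate_fluorescence(ph, lib, grid, with_noise = TRUE, seed = 8)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_error(
    simulate_fluorescence(test_phantom(fractions = c(PpIX = 1)), lib, grid),
    "not in library")
})

test_that("the generated suite follows the seven-phantom template", {
  suite <- generate_phantom_suite(seed = 4, noise_cv = 0.02)
  expect_length(suite, 14)  # 7 phantoms x 2 excitation tags
  at375 <- Filter(function(e) e$excitation_nm == 375, suite)
  expect_length(at375, 7)
  # 7 phantoms x 3 candidate fluorophores = 21 evaluation pairs
  expect_equal(sum(vapply(at375, function(e) length(component_names(
    phantom_basis_library())), integer(1))), 21)
  for (e in suite) {
    expect_equal(sum(e$truth$fractions), 1, tolerance = 1e-12)
    expect_gte(e$truth$alpha, 0.3); expect_lte(e$truth$alpha, 0.9)
    # two true components per phantom: one of NADH/FAD plus TiO2
    expect_equal(sum(e$truth$fractions > 0), 2)
  }
  # phantom 4 analog contains only the AR14-like absorber
  p4 <- Filter(function(e) e$phantom$id == 4, suite)[[1]]
  expect_equal(names(p4$truth$composition$absorbers), "AR14_like")
  # FAD suite has zero NADH, NADH suite zero FAD
  for (e in at375) {
    if (e$phantom$id <= 4) expect_equal(e$truth$fractions[["NADH"]], 0)
    else expect_equal(e$truth$fractions[["FAD"]], 0)
  }
  # determinism: same seed, same suite
  again <- generate_phantom_suite(seed = 4, noise_cv = 0.02)
  expect_identical(suite[[3]]$fm$values, again[[3]]$fm$values)
})

test_that("NADH-preferential excitation boosts the NADH fraction", {
  suite <- generate_phantom_suite(seed = 2, noise_cv = 0)
  for (id in 5:7) {
    f375 <- Filter(function(e) e$phantom$id == id &&
                     e$excitation_nm == 375, suite)[[1]]$truth$fractions
    f405 <- Filter(function(e) e$phantom$id == id &&
                     e$excitation_nm == 405, suite)[[1]]$truth$fractions
    expect_gt(f375[["NADH"]], f405[["NADH"]])
    expect_gt(f375[["NADH"]], 0.9)  # almost entirely NADH at 375
  }
})

test_that("raw bundles follow the acquisition sequence and reduce correctly", {
  ph <- test_phantom(noise = 0.02)
  raw <- generate_raw_acquisition(ph, seed = 3)
  # N = K = 5: 10 reflectance-phase frames, 20 fluorescence-phase frames
  expect_length(raw$reflectance$signal, 5)
  expect_length(raw$reflectance$background, 5)
  n_fluor <- sum(vapply(raw$fluorescence, function(tag)
    length(tag$signal) + length(tag$background), integer(1)))
  expect_equal(n_fluor, 20)
  # zero noise settings reduce to the generating spectra exactly
  ph0 <- test_phantom(noise = 0)
  raw0 <- generate_raw_acquisition(ph0, seed = 3, dark_sd = 0)
  red0 <- reduce_acquisition(raw0)
  expect_equal(red0$reflectance$values, raw0$truth$r$values,
               tolerance = 1e-12)
  expect_equal(red0$fluorescence[["405"]]$values, raw0$truth$fm$values,
               tolerance = 1e-12)
  # identical seeds give bit-identical bundles
  raw2 <- generate_raw_acquisition(ph, seed = 3)
  expect_identical(raw$fluorescence[["375"]]$signal[[2]]$values,
                   raw2$fluorescence[["375"]]$signal[[2]]$values)
})

test_that("noiseless suite phantoms are exactly invertible by the adaptive fit", {
  suite <- generate_phantom_suite(seed = 6, noise_cv = 0)
  lib <- phantom_basis_library()
  for (e in suite[seq(1, 14, by = 3)]) {
    res <- fit_adaptive(e$fm, e$r, lib)
    expect_equal(res$alpha, e$truth$alpha, tolerance = 0.01)
    expect_equal(res$fractions, e$truth$fractions, tolerance = 0.01)
  }
})

test_that("timecourse truth follows the phase protocol", {
  tc <- generate_timecourse(timecourse_spec(sampling_interval_min = 10),
                            seed = 1)
  expect_equal(tc$phases$phase, c("HOPE", "warm_ischemia", "NMP"))
  expect_equal(tc$phases$end - tc$phases$start, c(120, 60, 120))
  for (sm in tc$samples)
    expect_equal(sum(sm$truth_fractions), 1, tolerance = 1e-12)
  nmp <- Filter(function(s) s$phase == "NMP", tc$samples)
  expect_equal(nmp[[1]]$truth_fractions[["FAD"]], 0.40, tolerance = 1e-9)
  expect_equal(nmp[[length(nmp)]]$truth_fractions[["FAD"]], 0.60,
               tolerance = 1e-9)
  wi <- Filter(function(s) s$phase == "warm_ischemia", tc$samples)
  expect_equal(wi[[1]]$truth_fractions[["lipopigments"]], 0.01,
               tolerance = 1e-9)
  expect_gt(wi[[length(wi)]]$truth_fractions[["lipopigments"]], 0.025)
  # knot validation
  bad <- list(list(name = "x", duration_min = 10,
                   fractions_start = c(NADH = 0.5, FAD = 0.4),
                   fractions_end = c(NADH = 0.5, FAD = 0.5),
                   absorber_regime = "none"))
  expect_error(timecourse_spec(phases = bad), "sum to 1")
})
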