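# shared in-code fixtures: everything is generated at test time

coarse_grid <- function() seq(480, 650, by = 2)

test_phantom <- function(id = 1, absorbers = c(AR1_like = 0.4),
                         fractions = c(FAD = 0.7, TiO2 = 0.3),
                         alpha = 0.5, noise = 0) {
  phantom_spec(id, absorbers, scattering_spec(), fractions, alpha, noise)
}

# paired (Fm, R) forward-simulated from a phantom on a grid
test_pair <- function(phantom, lib, grid = coarse_grid(), seed = NULL) {
  list(fm = simulate_fluorescence(phantom, lib, grid,
                                  with_noise = phantom$noise_cv > 0,
                                  seed = seed),
       r = simulate_reflectance(phantom, grid))
}

flat_spectrum <- function(values, grid = c(500, 510, 520), kind = "raw") {
  spectrum(grid, rep(values, length.out = length(grid)), kind)
}
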