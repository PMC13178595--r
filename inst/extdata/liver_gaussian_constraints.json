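{
  "comment": "Constraint boxes for the Gaussian-modeled liver fluorophores: center mu and width sigma in nm with +/- tolerances.",
  "fluorophores": [
    {"name": "FMN_bound", "mu0": 495, "mu_tol": 1, "sigma0": 15, "sigma_tol": 1},
    {"name": "lipopigments", "mu0": 590, "mu_tol": 1, "sigma0": 10, "sigma_tol": 1},
    {"name": "PpIX_636", "mu0": 637, "mu_tol": 1, "sigma0": 6.25, "sigma_tol": 0.75},
    {"name": "PpIX_620", "mu0": 619, "mu_tol": 1, "sigma0": 8.25, "sigma_tol": 0.75}
  ]
}
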