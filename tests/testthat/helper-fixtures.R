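# Shared, lazily computed Monte Carlo fixtures. Runs are cached for the
# duration of the test session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# paired with/without-aperture run at BP 50 mm, ASD 50 mm
fixture_pair <- function(radius, material = "tungsten", n = 4e4,
                         bp_depth = 50) {
  key <- sprintf("pair_%s_%s_%s_%s", material, radius, n, bp_depth)
  fixture(key, {
    cfg <- ssa_config(material = material, bore_radius_mm = radius,
                      asd_mm = 50, bp_depth_mm = bp_depth, n_histories = n)
    simulate_configuration(cfg, seed = 42)
  })
}

# extended-range-shifter comparator
fixture_ers <- function(bp_depth = 50, n = 4e4) {
  key <- sprintf("ers_%s_%s", bp_depth, n)
  fixture(key, {
    simulate_comparator("ers", bp_depth, sweep_spec(n_histories = n, seed = 42))
  })
}

# hand-built dose grid with an exact 3D Gaussian lateral profile and a
# synthetic depth curve; used by the dosimetry unit tests
synthetic_gaussian_grid <- function(sigma = 4, nx = 61, nz = 20,
                                    peak_bin = 15) {
  x <- seq(-(nx - 1) / 2, (nx - 1) / 2)
  depth_weight <- exp(-0.5 * ((seq_len(nz) - peak_bin) / 3)^2) + 0.2
  lat <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  dose <- array(0, c(nx, nx, nz))
  for (iz in seq_len(nz)) dose[, , iz] <- lat * depth_weight[iz]
  structure(list(dose = dose, let_num = array(0, c(nx, nx, nz)),
                 let_den = array(0, c(nx, nx, nz)), voxel_mm = 1,
                 origin = c(-nx / 2, -nx / 2, 0)),
            class = "dose_grid")
}
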