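test_that("bore membership uses a strict radius inequality", {
  ap <- aperture_spec("tungsten", bore_radius_mm = 3)
  expect_true(in_bore(c(0, 0), ap))
  expect_false(in_bore(c(3, 0), ap))   # exactly at the radius is outside
  expect_true(in_bore(c(2.999, 0), ap))
  ap_off <- aperture_spec("tungsten", bore_radius_mm = 1,
                          offset_mm = c(1.5, 0))
  expect_false(in_bore(c(0, 0), ap_off))
  expect_true(in_bore(c(1.5, 0), ap_off))
})

test_that("single steps reproduce the stopping-power and Highland oracles", {
  n <- 1e5
  st <- sample_beamlet(beam_model(), 150, n, seed = 4, infinitesimal = TRUE)
  set.seed(101)
  out <- step_proton(st, "water", 1)
  de <- 150 - out[, "energy"]
  # mean loss = density x mass stopping power x 1 mm, within 1%
  expect_equal(mean(de), linear_stopping_power("water", 150),
               tolerance = 0.01)
  # RMS projected scattering angle matches the closed-form Highland sigma
  th0 <- ssadose:::.highland_theta0(150, 0.1 * 1.0, 36.08)
  expect_equal(stats::sd(out[, "tx"]), th0, tolerance = 0.03)
  expect_equal(stats::sd(out[, "ty"]), th0, tolerance = 0.03)
  # mean loss over 1 mm of air is bounded by the density ratio
  set.seed(102)
  out_air <- step_proton(st, "air", 1)
  expect_lt(mean(150 - out_air[, "energy"]), 0.001)
})

test_that("an open infinitesimal beamlet peaks at its CSDA range", {
  bm <- beam_model(source_to_iso_mm = 60)  # short air column for the oracle
  src <- sample_beamlet(bm, 160, 3e4, seed = 2, infinitesimal = TRUE)
  geom <- geometry_stack(range_shifter = NULL, aperture = NULL, asd_mm = 0,
                         phantom_depth_mm = 200, source_to_iso_mm = 60)
  res <- transport_beamlet(src, geom, seed = 3)
  expect_lt(abs(bragg_peak_depth(idd(res)) - csda_range("water", 160)), 2)
  # energy bookkeeping closes exactly
  expect_equal(sum(res$edep), res$e_initial, tolerance = 1e-9)
})

test_that("lateral spread follows the Fermi-Eyges prediction in water", {
  bm <- beam_model(source_to_iso_mm = 60)
  src <- sample_beamlet(bm, 160, 3e4, seed = 2, infinitesimal = TRUE)
  geom <- geometry_stack(range_shifter = NULL, aperture = NULL, asd_mm = 0,
                         phantom_depth_mm = 200, source_to_iso_mm = 60)
  res <- transport_beamlet(src, geom, seed = 3)
  depths <- c(60, 100, 140, 165)
  fe <- fermi_eyges_sigma(160, depths)
  for (i in seq_along(depths)) {
    mc_raw <- as.numeric(spot_sigma(res, depths[i]))
    mc <- sqrt(mc_raw^2 - 1 / 12)  # remove the 1 mm voxel binning variance
    expect_equal(mc, fe[i], tolerance = 0.05)
  }
})

test_that("transport is bit-reproducible under a fixed seed", {
  cfg <- ssa_config(bore_radius_mm = 2, n_histories = 2000)
  a <- simulate_configuration(cfg, seed = 7)
  b <- simulate_configuration(cfg, seed = 7)
  expect_identical(a$with$dose_grid$dose, b$with$dose_grid$dose)
  expect_identical(a$with$dose_grid$let_num, b$with$dose_grid$let_num)
  expect_identical(a$without$dose_grid$dose, b$without$dose_grid$dose)
  expect_identical(a$with$exit_states, b$with$exit_states)
})

test_that("collimation removes fluence and shares the source between runs", {
  pair <- fixture_pair(2)
  expect_identical(pair$with$n_primaries, pair$without$n_primaries)
  expect_lt(sum(pair$with$dose_grid$dose), sum(pair$without$dose_grid$dose))
  expect_equal(sum(pair$with$edep), pair$with$e_initial, tolerance = 1e-9)
  expect_equal(sum(pair$without$edep), pair$without$e_initial,
               tolerance = 1e-9)
})

test_that("a very large bore reproduces the no-aperture limit", {
  cfg <- ssa_config(bore_radius_mm = 45, n_histories = 2e4)
  pair <- simulate_configuration(cfg, seed = 5)
  expect_gt(transmission(pair$with, pair$without), 0.995)
})

test_that("overlapping geometries are rejected before transport", {
  expect_error(
    geometry_stack(rs_exit_to_surface_mm = 480, aperture = NULL,
                   source_to_iso_mm = 500),
    "geometry overlap")
  expect_error(
    geometry_stack(rs_exit_to_surface_mm = 40,
                   aperture = aperture_spec("tungsten", 3), asd_mm = 50),
    "geometry overlap")
})

test_that("metal apertures create a low-energy slit-scattered tail", {
  p1 <- fixture_pair(1)
  p3 <- fixture_pair(3)
  sp_no <- exit_spectrum(p3$without$exit_states)
  mode_e <- sp_no$energy[which.max(sp_no$fraction)]
  # no-aperture exit spectrum is a single quasi-Gaussian straggling peak
  expect_gt(sum(sp_no$fraction[abs(sp_no$energy - mode_e) <= 3]), 0.9)
  tail_frac <- function(pair) {
    sp <- exit_spectrum(pair$with$exit_states)
    sum(sp$fraction[sp$energy < mode_e - 10])
  }
  expect_gt(tail_frac(p3), 0)          # the tail exists
  expect_gt(tail_frac(p1), tail_frac(p3))  # and grows as the bore shrinks
})

test_that("the infinitesimal beamlet bounds the finite-source spot size", {
  sp <- sweep_spec(n_histories = 2e4, seed = 13)
  inf <- simulate_comparator("infinitesimal", 150, sp)
  open <- simulate_comparator("open", 150, sp)
  s_inf <- ssadose:::.sigma_at_own_bp(inf)
  s_open <- ssadose:::.sigma_at_own_bp(open)
  expect_lt(s_inf[["sigma"]], s_open[["sigma"]])
})
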