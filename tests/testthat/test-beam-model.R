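test_that("in-air sigma interpolates between the machine anchors", {
  bm <- beam_model()
  expect_equal(sigma_air(bm, 70), 6.0)
  expect_equal(sigma_air(bm, 230), 2.0)
  s150 <- sigma_air(bm, 150)
  expect_gt(s150, 2.0)
  expect_lt(s150, 6.0)
  # monotone non-increasing in energy
  e <- seq(70, 230, by = 10)
  expect_true(all(diff(sigma_air(bm, e)) <= 0))
  expect_error(sigma_air(bm, 60), "outside machine range")
})

test_that("beamlet sampling honors the emittance contract", {
  bm <- beam_model()
  inf <- sample_beamlet(bm, 160, 100, seed = 1, infinitesimal = TRUE)
  expect_true(all(inf[, c("x", "y", "tx", "ty")] == 0))
  expect_true(all(inf[, "energy"] == 160))
  expect_equal(nrow(sample_beamlet(bm, 160, 0)), 0)

  s1 <- sample_beamlet(bm, 100, 5000, seed = 9)
  s2 <- sample_beamlet(bm, 100, 5000, seed = 9)
  expect_identical(s1, s2)

  # with zero divergence, the sigma at isocenter equals the source sigma
  big <- sample_beamlet(bm, 100, 1e5, seed = 3)
  expect_equal(stats::sd(big[, "x"]), sigma_air(bm, 100), tolerance = 0.02)
  expect_equal(stats::sd(big[, "y"]), sigma_air(bm, 100), tolerance = 0.02)
})

test_that("energy selection for a Bragg-peak depth respects the machine window", {
  # target at the surface behind a 45 mm WET range shifter: ~74 MeV
  e0 <- energy_for_bp_depth(0, 45)
  expect_equal(csda_range("water", e0), 45, tolerance = 1e-6)
  expect_gt(e0, 70)
  expect_lt(e0, 76)
  e100 <- energy_for_bp_depth(100, 45)
  expect_equal(csda_range("water", e100), 145, tolerance = 1e-6)
  # monotone increasing in target depth
  depths <- seq(0, 100, by = 20)
  ee <- vapply(depths, energy_for_bp_depth, 0, upstream_wet_mm = 45)
  expect_true(all(diff(ee) > 0))
  # 50 mm without a range shifter is deliverable (~78 MeV)...
  expect_equal(csda_range("water", energy_for_bp_depth(50, 0)), 50,
               tolerance = 1e-6)
  # ...but 30 mm would need < 70 MeV: rejected
  expect_error(energy_for_bp_depth(30, 0), "below the machine minimum")
  expect_error(energy_for_bp_depth(300, 45), "exceeds the machine maximum")
})

test_that("synthetic plans satisfy their construction contracts", {
  plans <- generate_synthetic_plan(
    4, depth_profile = list(min_range = c(30, 30), max_range = c(90, 90)),
    seed = 11)
  # forced depth bounds make every field pass the eligibility filter
  expect_true(all(vapply(plans, field_eligible, TRUE)))
  expect_true(all(vapply(plans, function(f) all(f$spots$protons > 0), TRUE)))

  # spot count equals the brute-force recount of grid points in each ellipse
  f <- plans[[1]]
  recount <- sum(apply(f$layers, 1, function(ly) {
    a <- ly[["semi_axis_a_mm"]]; b <- ly[["semi_axis_b_mm"]]
    sp <- f$spot_spacing_mm
    g <- expand.grid(x = seq(-ceiling(a / sp), ceiling(a / sp)) * sp,
                     y = seq(-ceiling(b / sp), ceiling(b / sp)) * sp)
    sum((g$x / a)^2 + (g$y / b)^2 <= 1)
  }))
  expect_equal(nrow(f$spots), recount)

  # reproducibility
  again <- generate_synthetic_plan(
    4, depth_profile = list(min_range = c(30, 30), max_range = c(90, 90)),
    seed = 11)
  expect_identical(plans, again)
  expect_error(generate_synthetic_plan(1, semi_axis_range_mm = c(0, 0)),
               "degenerate target")
})

test_that("treatment fields round-trip through JSON", {
  plans <- generate_synthetic_plan(2, seed = 5)
  path <- tempfile(fileext = ".json")
  write_plan_json(plans, path)
  back <- read_plan_json(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$field_id, plans[[1]]$field_id)
  expect_equal(back[[1]]$wet_depth_min, plans[[1]]$wet_depth_min)
  expect_equal(back[[2]]$spots$protons, plans[[2]]$spots$protons)
})
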