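test_that("the default sweep defines the standard study grids", {
  sp <- sweep_spec()
  expect_equal(sp$radii_mm, 1:4)
  expect_equal(sp$asds_mm, c(1, 50, 100))
  expect_equal(sp$bp_depths_mm, seq(0, 100, by = 12.5))
  expect_equal(range(sp$gaps_mm), c(0, 300))
  expect_setequal(sp$materials, c("tungsten", "nickel"))
  expect_equal(sp$rs_wet_mm, 45)
})

test_that("sweep specifications round-trip through YAML exactly", {
  sp <- sweep_spec(n_histories = 12345, seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_sweep_config(sp, path)
  back <- read_sweep_config(path)
  for (field in c("materials", "radii_mm", "asds_mm", "gaps_mm",
                  "bp_depths_mm", "comparators", "n_histories", "seed",
                  "rs_wet_mm", "nuclear")) {
    expect_equal(back[[field]], sp[[field]], info = field)
  }
})

test_that("the gap study normalizes to its zero-gap configuration", {
  sp <- sweep_spec(n_histories = 3e4, gaps_mm = c(0, 300), seed = 21)
  g <- run_gap_study(sp)
  expect_equal(g$rel_sigma[1], 1)
  expect_equal(g$rel_transmission[1], 1)
  # both curves non-increasing with the gap (sigma within MC noise)
  expect_lte(g$rel_transmission[2], g$rel_transmission[1])
  expect_lte(g$rel_sigma[2], 1.03)
  # transmission falls much faster than the spot size
  expect_gt(1 - g$rel_transmission[2], 2 * (1 - g$rel_sigma[2]))
})

test_that("the spot-size study table covers comparators and configurations", {
  sp <- sweep_spec(materials = "tungsten", radii_mm = 2, asds_mm = 50,
                   bp_depths_mm = 50, comparators = c("ers", "moveable_rs"),
                   n_histories = 1.5e4, seed = 8)
  tab <- run_spot_size_study(sp)
  expect_setequal(unique(tab$comparator), c("ers", "moveable_rs", "ssa"))
  s_ssa <- tab$sigma_mm[tab$comparator == "ssa"]
  expect_lt(s_ssa, tab$sigma_mm[tab$comparator == "ers"])
  expect_lt(s_ssa, tab$sigma_mm[tab$comparator == "moveable_rs"])
})

test_that("transmission study reports aligned and offset columns", {
  sp <- sweep_spec(materials = "tungsten", radii_mm = c(1, 3),
                   bp_depths_mm = 50, n_histories = 1.5e4, seed = 31)
  tab <- run_transmission_study(sp, offset_mm = 1)
  expect_equal(nrow(tab), 2)
  t1 <- tab$transmission[tab$radius_mm == 1]
  t3 <- tab$transmission[tab$radius_mm == 3]
  expect_lt(t1, t3)  # transmission grows with the radius
  expect_true(all(abs(tab$transmission - tab$transmission_offset) < 0.02))
})

test_that("plan study scores only eligible fields and matches the oracle", {
  plans <- generate_synthetic_plan(
    3, depth_profile = list(min_range = c(25, 35), max_range = c(70, 90)),
    seed = 17)
  ineligible <- plans[[1]]
  ineligible$field_id <- "too_deep"
  ineligible$wet_depth_max <- 150
  tb <- data.frame(energy_MeV = c(70, 160), transmission = c(0.1, 0.5))
  tabs <- list(tungsten_3 = tb, tungsten_4 = transform(tb, transmission = c(0.2, 0.6)),
               nickel_3 = tb, nickel_4 = transform(tb, transmission = c(0.2, 0.6)))
  out <- run_plan_study(c(plans, list(ineligible)), tabs)
  expect_false("too_deep" %in% out$field_id)
  expect_equal(sort(unique(out$field_id)),
               sort(vapply(plans, function(f) f$field_id, "")))
  # radius 3 produces more neutron dose than radius 4 (lower transmission)
  for (f in unique(out$field_id)) {
    for (m in c("tungsten", "nickel")) {
      d3 <- out$integral_neutron_dose_Gy[out$field_id == f &
                                           out$material == m &
                                           out$radius_mm == 3]
      d4 <- out$integral_neutron_dose_Gy[out$field_id == f &
                                           out$material == m &
                                           out$radius_mm == 4]
      expect_gt(d3, d4)
    }
  }
  # spot-by-spot oracle for one row
  f <- plans[[2]]
  lookup <- transmission_lookup_from_table(tb)
  expect_equal(
    out$integral_neutron_dose_Gy[out$field_id == f$field_id &
                                   out$material == "tungsten" &
                                   out$radius_mm == 3][1],
    integral_neutron_dose(f, "tungsten", lookup))
  expect_equal(out$t_add_s[1], out$n_spots[1] * 5 / 500)
})
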