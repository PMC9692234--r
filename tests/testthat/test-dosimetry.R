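test_that("IDD normalization and conservation hold", {
  g <- synthetic_gaussian_grid()
  curve <- idd(g, normalize = TRUE)
  expect_equal(curve$value[1], 1.0)
  raw <- idd(g)
  expect_equal(sum(raw$value), sum(g$dose))
  empty <- g
  empty$dose[] <- 0
  expect_error(idd(empty), "empty")
  zero_front <- g
  zero_front$dose[, , 1] <- 0
  expect_error(idd(zero_front, normalize = TRUE), "zero entrance")
})

test_that("Bragg-peak depth refinement recovers analytic vertices", {
  # discrete maximum exactly at a bin with symmetric neighbors
  curve <- structure(data.frame(z = seq(0.5, 19.5), value = 1),
                     class = c("depth_curve", "data.frame"))
  curve$value[10] <- 5
  expect_equal(bragg_peak_depth(curve), curve$z[10])
  # sampled parabola: vertex recovered to 0.01 mm
  vertex <- 12.34
  par <- curve
  par$value <- 50 - (par$z - vertex)^2
  expect_equal(bragg_peak_depth(par), vertex, tolerance = 1e-6)
  flat <- curve
  flat$value <- 1
  expect_error(bragg_peak_depth(flat), "flat")
})

test_that("spot sigma recovers constructed Gaussian widths", {
  g <- synthetic_gaussian_grid(sigma = 4)
  s <- spot_sigma(g, 15)
  expect_equal(as.numeric(s), 4.0, tolerance = 0.05)
  expect_lt(abs(attr(s, "center")), 0.1)  # symmetric profile centers on axis
  expect_equal(as.numeric(spot_sigma(g, 15, method = "rms")), 4.0,
               tolerance = 0.1)
  empty <- g
  empty$dose[] <- 0
  expect_error(spot_sigma(empty, 15), "all-zero")
  expect_error(spot_sigma(g, 500), "outside the phantom")
})

test_that("peak-to-entrance equals the maximum of a normalized curve", {
  g <- synthetic_gaussian_grid()
  curve <- idd(g, normalize = TRUE)
  expect_equal(peak_to_entrance(curve), max(curve$value))
})

test_that("transmission obeys its identity, blockage and error contracts", {
  g <- synthetic_gaussian_grid()
  expect_equal(transmission(g, g), 1.0)
  zero <- g
  zero$dose[] <- 0
  expect_equal(transmission(zero, g), 0.0)
  expect_error(transmission(g, zero), "zero total dose")
  small <- synthetic_gaussian_grid(nx = 31)
  expect_error(transmission(small, g), "mismatched")
  bigger <- g
  bigger$dose <- g$dose * 2
  expect_error(transmission(bigger, g), "> 1")
})

test_that("dose-averaged LET reduces to the stopping power for a single deposit", {
  g <- synthetic_gaussian_grid(nx = 11, nz = 5)
  g$let_den[6, 6, ] <- 1
  s_ref <- linear_stopping_power("water", 80)
  g$let_num[6, 6, ] <- s_ref
  curve <- ild(g)
  expect_equal(curve$value, rep(s_ref, 5))
  g$let_num[] <- 0
  g$let_den[] <- 0
  expect_error(ild(g), "empty")
})

test_that("exit spectra are normalized histograms", {
  states <- structure(cbind(x = 0, y = 0, tx = 0, ty = 0,
                            energy = c(50, 51, 60, 80), weight = c(1, 1, 2, 1)),
                      class = c("proton_states", "matrix", "array"))
  sp <- exit_spectrum(states, bin_width_mev = 1)
  expect_equal(sum(sp$fraction), 1)
  expect_error(exit_spectrum(states[0, , drop = FALSE]), "empty")
})

test_that("pristine beamlets show the Bragg LET rise along depth", {
  pair <- fixture_pair(2)
  curve <- ild(pair$without)
  bp <- bragg_peak_depth(idd(pair$without))
  at <- function(z) curve$value[which.min(abs(curve$z - z))]
  expect_gt(at(bp), at(1))
})

test_that("radius monotonicity: transmission, sigma and peak-to-entrance", {
  pairs <- lapply(c(1, 2, 3, 4), fixture_pair)
  tr <- vapply(pairs, function(p) transmission(p$with, p$without), 0)
  expect_true(all(diff(tr) > 0))  # transmission grows with the opening
  sg <- vapply(pairs, function(p) {
    as.numeric(spot_sigma(p$with, bragg_peak_depth(idd(p$with))))
  }, 0)
  expect_true(all(diff(sg) > 0))  # spots shrink as the bore closes
  pe <- vapply(pairs, function(p) peak_to_entrance(idd(p$with, TRUE)), 0)
  expect_true(all(diff(pe) > 0))  # slit scattering degrades small bores most
})

test_that("collimated spots beat the extended range shifter and materials order", {
  ers <- fixture_ers()
  s_ers <- ssadose:::.sigma_at_own_bp(ers)
  p2 <- fixture_pair(2)
  s_ssa <- ssadose:::.sigma_at_own_bp(p2$with)
  expect_lt(s_ssa[["sigma"]], s_ers[["sigma"]])
  # thinner tungsten keeps a higher peak-to-entrance ratio than nickel
  p3w <- fixture_pair(3, n = 1e5)
  p3n <- fixture_pair(3, material = "nickel", n = 1e5)
  expect_gte(peak_to_entrance(idd(p3w$with, TRUE)),
             peak_to_entrance(idd(p3n$with, TRUE)))
  # slit-scattered protons raise the entrance LET of either collimated beam
  # above the uncollimated beam's entrance LET
  for (p in list(p3w, p3n)) {
    expect_gt(ild(p$with)$value[1], ild(p$without)$value[1])
  }
})
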