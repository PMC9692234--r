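# Simplified secondary-neutron dose model.
#
# Neutrons are not transported microscopically. A thick-target yield
# parameterization Y(E, material) (neutrons per stopped proton; power law in
# energy, amplitudes per material) is combined with a two-component
# (isotropic + forward-peaked) point kernel to give the physical dose (Gy)
# to a downstream cylindrical water phantom. The parameterization is a
# calibrated synthetic fixture (see data-raw/): amplitudes and exponents are
# chosen once so that nickel yields 60-70% of the tungsten phantom dose at
# equal maximum treatment depth (70% at 230 MeV), with lead and brass
# ordered between them. Relative results are meaningful; absolute doses are
# order-of-magnitude.

.neutron_fixture <- function(name) {
  key <- paste0("neutron_", name)
  if (is.null(.ssadose[[key]])) {
    path <- system.file("extdata", "neutron", paste0(name, ".csv"),
                        package = "ssadose", mustWork = TRUE)
    .ssadose[[key]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .ssadose[[key]]
}

#' The default neutron yield model
#'
#' @return A `neutron_yield_model`: the thick-target yield table (material,
#'   energy, neutrons per stopped proton), the dose-kernel constants, and a
#'   calibration provenance tag.
#' @export
neutron_yield_model <- function() {
  yt <- .neutron_fixture("thick_target_yield")
  kern <- .neutron_fixture("dose_kernel")
  kernel <- as.list(stats::setNames(kern$value, kern$parameter))
  structure(list(yield_table = yt, kernel = kernel,
                 calibration = "synthetic power-law fixture, nickel/tungsten 0.62-0.70"),
            class = "neutron_yield_model")
}

#' Thick-target neutron yield per stopped proton
#'
#' Log-log interpolation in the yield fixture.
#'
#' @param material Material (name or `proton_material`); must be one of the
#'   aperture candidates in the fixture (tungsten, lead, brass, nickel).
#' @param energy Incident proton kinetic energy, MeV (vectorized).
#' @param model A [neutron_yield_model()].
#' @return Neutrons per stopped proton.
#' @export
neutron_yield <- function(material, energy, model = neutron_yield_model()) {
  nm <- .as_material(material)$name
  tb <- model$yield_table[model$yield_table$material == nm, ]
  if (!nrow(tb)) {
    stop("no neutron yield data for material '", nm, "'; available: ",
         paste(unique(model$yield_table$material), collapse = ", "))
  }
  if (any(energy < min(tb$energy_MeV) | energy > max(tb$energy_MeV))) {
    stop("energy outside the neutron yield table range")
  }
  exp(stats::approx(log(tb$energy_MeV), log(tb$neutrons_per_proton),
                    xout = log(energy))$y)
}

# mean neutron fluence (cm^-2 per emitted neutron) over the phantom front
# disc, from the two-component kernel
.mean_disc_fluence <- function(kernel) {
  d_cm <- kernel$block_to_phantom_mm / 10
  r_cm <- kernel$phantom_radius_mm / 10
  nexp <- kernel$forward_cos_exponent
  r <- seq(0, r_cm, length.out = 400)
  rr2 <- d_cm^2 + r^2
  cost <- d_cm / sqrt(rr2)
  phi <- (kernel$isotropic_fraction / (4 * pi) +
          kernel$forward_fraction * (nexp + 1) / (2 * pi) * cost^nexp) / rr2
  integ <- phi * 2 * pi * r
  tot <- sum(diff(r) * (utils::head(integ, -1) + utils::tail(integ, -1)) / 2)
  tot / (pi * r_cm^2)
}

#' Neutron dose to the downstream phantom from a stopping block
#'
#' A proton beamlet is fully stopped in a block of the aperture material of
#' its minimum stopping thickness; the emitted neutrons deposit dose in a
#' downstream cylindrical water phantom (20 cm diameter by default).
#'
#' @param material Block (aperture) material.
#' @param energy Incident proton energy, MeV (<= 230, the maximum the yield
#'   calibration covers).
#' @param n_protons Number of incident protons.
#' @param model A [neutron_yield_model()].
#' @return A `neutron_result`: list with `material`, `proton_energy`,
#'   `block_thickness` (mm, the stopping-thickness criterion),
#'   `phantom_dose_Gy` and the calibration tag.
#' @export
neutron_dose <- function(material, energy, n_protons = 1e6,
                         model = neutron_yield_model()) {
  mat <- .as_material(material)
  stopifnot(length(energy) == 1, n_protons >= 0)
  if (energy > 230) stop("energy above 230 MeV is outside the calibrated model")
  y <- neutron_yield(mat, energy, model)
  fl <- .mean_disc_fluence(model$kernel)
  dose <- n_protons * y * fl * model$kernel$fluence_to_dose_Gy_cm2
  structure(list(material = mat$name, proton_energy = energy,
                 block_thickness = min_stopping_thickness(mat, energy),
                 phantom_dose_Gy = dose, calibration = model$calibration),
            class = "neutron_result")
}

#' Neutron dose of one aperture material relative to another
#'
#' Both materials are evaluated at the same proton energy, i.e. at equal
#' maximum treatment depth in water (each block has its own stopping
#' thickness).
#'
#' @param material Material under test.
#' @param reference Reference material (conventionally tungsten).
#' @param energy Proton energy, MeV.
#' @param model A [neutron_yield_model()].
#' @return Percentage (100 = equal dose).
#' @export
relative_neutron_dose <- function(material, reference = "tungsten", energy,
                                  model = neutron_yield_model()) {
  d1 <- neutron_dose(material, energy, n_protons = 1e6, model = model)
  d0 <- neutron_dose(reference, energy, n_protons = 1e6, model = model)
  if (d0$phantom_dose_Gy <= 0) stop("zero reference neutron dose")
  100 * d1$phantom_dose_Gy / d0$phantom_dose_Gy
}

#' Is a treatment field eligible for aperture-based delivery?
#'
#' Shallow-field criterion: water-equivalent treatment depth minimum below
#' 40 mm and maximum below 100 mm.
#'
#' @param field A `treatment_field`.
#' @return Logical.
#' @export
field_eligible <- function(field) {
  field$wet_depth_min < 40 && field$wet_depth_max < 100
}

#' Integral neutron dose of a treatment field delivered through an aperture
#'
#' Per spot with planned protons P and beamlet transmission T, the delivered
#' fluence is rescaled to P/T so that the protons passing the aperture match
#' the plan; the absorbed protons P(1/T - 1) produce neutrons according to
#' the yield model at the spot's aperture-incident energy (nominal energy
#' degraded by the range-shifter WET).
#'
#' @param field An eligible `treatment_field`.
#' @param material Aperture material.
#' @param transmission_lookup Function `(energy_MeV) -> fraction` giving the
#'   beamlet transmission of this aperture configuration at each spot
#'   energy (build one with [transmission_lookup_from_table()]).
#' @param rs_wet_mm Range-shifter WET used to degrade the nominal energy.
#' @param model A [neutron_yield_model()].
#' @return Integral neutron dose in Gy.
#' @export
integral_neutron_dose <- function(field, material, transmission_lookup,
                                  rs_wet_mm = 45,
                                  model = neutron_yield_model()) {
  if (!field_eligible(field)) {
    stop("field ", field$field_id, " is not eligible (depth bounds exceeded)")
  }
  spots <- field$spots
  tvals <- vapply(spots$energy_MeV, transmission_lookup, 0)
  if (any(!is.finite(tvals)) || any(tvals <= 0)) {
    stop("zero or undefined transmission for at least one spot: undeliverable")
  }
  absorbed <- spots$protons * (1 / tvals - 1)
  e_ap <- vapply(spots$energy_MeV, function(e) {
    resid <- csda_range("water", e) - rs_wet_mm
    if (resid <= 0.5) stop("spot energy fully absorbed in the range shifter")
    energy_from_range("water", resid)
  }, 0)
  fl <- .mean_disc_fluence(model$kernel)
  sum(absorbed * neutron_yield(material, e_ap, model) * fl *
        model$kernel$fluence_to_dose_Gy_cm2)
}

#' Build a transmission lookup from a study results table
#'
#' Linear interpolation of transmission versus spot energy for one
#' (material, radius) configuration, constant beyond the table ends.
#'
#' @param table Data frame with columns `energy_MeV` and `transmission`.
#' @return A function `(energy_MeV) -> fraction`.
#' @export
transmission_lookup_from_table <- function(table) {
  stopifnot(all(c("energy_MeV", "transmission") %in% names(table)))
  table <- table[order(table$energy_MeV), ]
  function(energy) {
    stats::approx(table$energy_MeV, table$transmission, xout = energy,
                  rule = 2)$y
  }
}
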