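# Material definitions and proton stopping-power / range services.
#
# Reference data are computed Bethe-theory tables (see data-raw/) shipped as
# CSV under inst/extdata/stopping/: columns energy_MeV,
# mass_stopping_power_MeV_cm2_g, csda_range_g_cm2, one file per material,
# plus a sidecar of densities, Z/A, radiation lengths. Interpolation is
# log-log linear, so every table row is reproduced exactly.

.ssadose <- new.env(parent = emptyenv())

.material_cache <- function() {
  if (is.null(.ssadose$materials)) .ssadose$materials <- new.env(parent = emptyenv())
  .ssadose$materials
}

.material_properties <- function() {
  if (is.null(.ssadose$props)) {
    path <- system.file("extdata", "stopping", "material_properties.csv",
                        package = "ssadose", mustWork = TRUE)
    .ssadose$props <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .ssadose$props
}

#' Names of the supported materials
#'
#' @return Character vector of material identifiers accepted by
#'   [get_material()].
#' @export
supported_materials <- function() sort(.material_properties()$name)

#' Retrieve a material with its embedded reference data
#'
#' Looks up a material by name (case-insensitive) and returns its density,
#' effective Z/A, radiation length and the proton electronic mass
#' stopping-power / CSDA-range table used by all range and transport
#' computations.
#'
#' @param name Material identifier; one of [supported_materials()].
#' @return An object of class `proton_material`: a list with elements `name`,
#'   `density` (g/cm^3), `z_over_a`, `radiation_length` (g/cm^2), `is_metal`,
#'   and `table` (data frame with `energy_MeV`,
#'   `mass_stopping_power_MeV_cm2_g`, `csda_range_g_cm2`).
#' @examples
#' w <- get_material("tungsten")
#' w$density
#' @export
get_material <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  key <- tolower(trimws(name))
  cache <- .material_cache()
  if (!is.null(cache[[key]])) return(cache[[key]])
  props <- .material_properties()
  row <- props[props$name == key, ]
  if (nrow(row) != 1) {
    stop("unsupported material '", name, "'; supported materials are: ",
         paste(supported_materials(), collapse = ", "))
  }
  path <- system.file("extdata", "stopping", paste0(key, ".csv"),
                      package = "ssadose", mustWork = TRUE)
  tab <- utils::read.csv(path)
  mat <- structure(
    list(name = key,
         density = row$density_g_cm3,
         z_over_a = row$z_over_a,
         radiation_length = row$radiation_length_g_cm2,
         is_metal = row$is_metal,
         table = tab,
         log_e = log(tab$energy_MeV),
         log_s = log(tab$mass_stopping_power_MeV_cm2_g),
         log_r = log(tab$csda_range_g_cm2)),
    class = "proton_material")
  cache[[key]] <- mat
  mat
}

#' @export
print.proton_material <- function(x, ...) {
  cat(sprintf("<proton_material> %s: density %.4g g/cm^3, X0 %.4g g/cm^2, %s\n",
              x$name, x$density, x$radiation_length,
              if (x$is_metal) "metal" else "non-metal"))
  cat(sprintf("  stopping table: %d rows, %.4g-%.4g MeV\n",
              nrow(x$table), min(x$table$energy_MeV), max(x$table$energy_MeV)))
  invisible(x)
}

.as_material <- function(material) {
  if (inherits(material, "proton_material")) material else get_material(material)
}

.check_energy_range <- function(material, energy, lo = NULL) {
  rng <- range(material$table$energy_MeV)
  if (!is.null(lo)) rng[1] <- max(rng[1], lo)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop(sprintf("energy out of table range [%g, %g] MeV for %s",
                 rng[1], rng[2], material$name))
  }
}

#' Electronic mass stopping power of protons
#'
#' Log-log linear interpolation in the material's embedded reference table.
#'
#' @param material A `proton_material` or a material name.
#' @param energy Proton kinetic energy in MeV (vectorized); must lie in
#'   \[1, 250\] MeV.
#' @return Mass stopping power in MeV cm^2/g.
#' @examples
#' mass_stopping_power("water", 100)  # ~7.29
#' @export
mass_stopping_power <- function(material, energy) {
  material <- .as_material(material)
  .check_energy_range(material, energy, lo = 1)
  exp(stats::approx(material$log_e, material$log_s, xout = log(energy))$y)
}

#' Linear stopping power in MeV/mm
#'
#' Convenience wrapper: density times mass stopping power, converted to
#' MeV/mm (numerically equal to keV/um, the conventional LET unit).
#'
#' @inheritParams mass_stopping_power
#' @return Linear stopping power in MeV/mm.
#' @export
linear_stopping_power <- function(material, energy) {
  material <- .as_material(material)
  material$density * mass_stopping_power(material, energy) / 10
}

#' CSDA range of protons in a material
#'
#' Continuous-slowing-down-approximation range, interpolated (log-log) from
#' the embedded reference table and converted to physical depth.
#'
#' @inheritParams mass_stopping_power
#' @return Range in mm (vectorized over `energy`).
#' @examples
#' csda_range("water", 70)  # ~40.8 mm
#' @export
csda_range <- function(material, energy) {
  material <- .as_material(material)
  .check_energy_range(material, energy)
  r_gcm2 <- exp(stats::approx(material$log_e, material$log_r, xout = log(energy))$y)
  r_gcm2 / material$density * 10
}

#' Energy whose CSDA range equals a given depth
#'
#' Monotone root finding on [csda_range()]; the returned energy reproduces
#' the requested range to better than 0.01 MeV.
#'
#' @param material A `proton_material` or a material name.
#' @param range_mm Target CSDA range in mm.
#' @return Kinetic energy in MeV.
#' @examples
#' energy_from_range("water", 40.8)  # ~70 MeV
#' @export
energy_from_range <- function(material, range_mm) {
  material <- .as_material(material)
  stopifnot(length(range_mm) == 1, range_mm > 0)
  e_rng <- range(material$table$energy_MeV)
  r_rng <- csda_range(material, e_rng)
  if (range_mm < r_rng[1] || range_mm > r_rng[2]) {
    stop(sprintf("range %g mm not achievable in %s within the table (%.3g-%.4g mm)",
                 range_mm, material$name, r_rng[1], r_rng[2]))
  }
  f <- function(e) csda_range(material, e) - range_mm
  stats::uniroot(f, interval = e_rng, tol = 1e-4)$root
}

#' Relative (to water) stopping power at a given energy
#'
#' @inheritParams mass_stopping_power
#' @return Dimensionless ratio of linear stopping powers, material over water.
#' @export
relative_stopping_power <- function(material, energy) {
  material <- .as_material(material)
  water <- get_material("water")
  (material$density * mass_stopping_power(material, energy)) /
    (water$density * mass_stopping_power(water, energy))
}

#' Water-equivalent thickness of a material slab
#'
#' Physical thickness scaled by the relative stopping power at the given
#' energy; identity for water.
#'
#' @param material A `proton_material` or a material name.
#' @param physical_thickness Slab thickness in mm (>= 0).
#' @param energy Proton kinetic energy in MeV at which the relative stopping
#'   power is evaluated.
#' @return Water-equivalent thickness in mm.
#' @export
wet_thickness <- function(material, physical_thickness, energy) {
  if (any(physical_thickness < 0)) stop("physical_thickness must be >= 0")
  physical_thickness * relative_stopping_power(material, energy)
}

#' Physical slab thickness realizing a given water-equivalent thickness
#'
#' @inheritParams wet_thickness
#' @param wet_mm Target water-equivalent thickness in mm.
#' @return Physical thickness in mm.
#' @export
thickness_for_wet <- function(material, wet_mm, energy) {
  if (any(wet_mm < 0)) stop("wet_mm must be >= 0")
  wet_mm / relative_stopping_power(material, energy)
}

# Bohr energy-loss straggling parameter per unit depth, MeV^2/mm, with the
# standard relativistic correction.
.bohr_kappa <- function(material, energy) {
  gamma <- 1 + energy / 938.27209
  beta2 <- 1 - 1 / gamma^2
  0.1569 * material$density * material$z_over_a / 10 *
    (1 - beta2 / 2) / (1 - beta2)
}

# Gaussian range-straggling sigma (mm) for protons of the given energy
# stopping in the material: sigma_R^2 = int_0^E kappa(E') / S_lin(E')^3 dE'.
.range_straggling_sigma <- function(material, energy) {
  e <- seq(1, energy, length.out = 400)
  s_lin <- linear_stopping_power(material, e)
  integrand <- .bohr_kappa(material, e) / s_lin^3
  sqrt(sum(diff(e) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2))
}

# Depth in a material at which a range-straggling-convolved CSDA depth-dose
# curve falls to 0.1% of its Bragg-peak value.
.dose_falloff_depth <- function(material, energy) {
  material <- .as_material(material)
  stopifnot(length(energy) == 1)
  .check_energy_range(material, energy)
  r <- csda_range(material, energy)
  sigma <- .range_straggling_sigma(material, energy)
  dz <- min(0.05, r / 500)
  z <- seq(0, r + 8 * sigma + 20 * dz, by = dz)
  # CSDA depth dose: local stopping power at the energy of residual range r-z
  resid <- pmax(r - z, 0)
  res_gcm2 <- pmax(resid * material$density / 10, 1e-12)
  e_of_r <- exp(stats::approx(material$log_r, material$log_e,
                              xout = log(res_gcm2), rule = 2)$y)
  d0 <- ifelse(resid > 0, linear_stopping_power(material, pmax(e_of_r, 1)), 0)
  # convolve with the Gaussian range-straggling kernel
  half <- ceiling(4 * sigma / dz)
  kern <- stats::dnorm(seq(-half, half) * dz, sd = max(sigma, dz / 10))
  kern <- kern / sum(kern)
  d <- stats::filter(c(rep(d0[1], half), d0, rep(0, half)), kern, sides = 2)
  d <- as.numeric(d)[half + seq_along(d0)]
  peak <- max(d, na.rm = TRUE)
  thr <- 1e-3 * peak
  beyond <- which(z > z[which.max(d)] & d < thr)
  if (!length(beyond)) stop("falloff point beyond computed grid")
  i <- beyond[1]
  # linear interpolation of the crossing
  z[i - 1] + (z[i] - z[i - 1]) * (d[i - 1] - thr) / (d[i - 1] - d[i])
}

#' Minimum material thickness that stops a proton beam
#'
#' The "maximum treatment depth in water" is the depth at which a
#' range-straggling-convolved depth-dose curve in water falls to 0.1% of its
#' Bragg-peak value; the stopping thickness is 5% more than that depth,
#' converted into the given material through the range tables. This is the
#' collimator-thickness criterion: thick enough that essentially no primary
#' protons emerge, with a 5% safety margin.
#'
#' @inheritParams mass_stopping_power
#' @return Thickness in mm.
#' @examples
#' e100 <- energy_from_range("water", 100)
#' min_stopping_thickness("tungsten", e100)  # about 11.2 mm
#' @export
min_stopping_thickness <- function(material, energy) {
  material <- .as_material(material)
  d_w <- .dose_falloff_depth(get_material("water"), energy)
  e_equiv <- energy_from_range("water", 1.05 * d_w)
  csda_range(material, e_equiv)
}
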