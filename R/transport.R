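# Geometry construction and Monte Carlo transport wrappers.
#
# Coordinates: z along the beam axis, z = 0 at the phantom surface, beam
# travels towards +z; isocenter sits at z = +isocenter_depth_mm. The lateral
# grid is centered on the beam axis; voxel ownership is half-open
# [lower, upper). The aperture is modeled as a laterally infinite slab with
# a single cylindrical bore; a proton is inside the bore iff its distance
# from the (possibly offset) bore axis is strictly less than the radius.

# simplified nuclear removal mean free paths, g/cm^2 (primaries only)
.NUCLEAR_LAMBDA <- c(water = 120, air = 125, polycarbonate = 125,
                     nickel = 160, brass = 162, tungsten = 210, lead = 218)

.nuclear_lambda_gcm2 <- function(name) {
  if (name %in% names(.NUCLEAR_LAMBDA)) unname(.NUCLEAR_LAMBDA[name]) else 140
}

# Highland logarithmic correction factor, evaluated at the radiative
# thickness of a whole slab (clamped for ultrathin slabs)
.highland_factor <- function(t_gcm2, x0_gcm2) {
  if (t_gcm2 <= 0) return(1)
  max(1 + log10(t_gcm2 / x0_gcm2) / 9, 0.25)
}

# Highland angular sigma (radians) for a slab traversal at energy e
.highland_theta0 <- function(e_mev, t_gcm2, x0_gcm2, f = NULL) {
  pv <- e_mev * (e_mev + 2 * 938.27209) / (e_mev + 938.27209)
  if (is.null(f)) f <- .highland_factor(t_gcm2, x0_gcm2)
  14.1 / pv * sqrt(t_gcm2 / x0_gcm2) * f
}

#' Aperture (collimator) specification
#'
#' @param material Aperture material name; typically `"tungsten"` or
#'   `"nickel"`.
#' @param bore_radius_mm Radius of the cylindrical opening, mm (> 0).
#' @param thickness_mm Physical thickness, mm. Defaults to the study values
#'   11.1 mm (tungsten) and 18.5 mm (nickel); for other materials the
#'   stopping-thickness criterion for a 100 mm residual water range is used.
#' @param offset_mm Length-2 lateral misalignment (dx, dy) of the bore axis
#'   relative to the beamlet axis, mm.
#' @return An object of class `aperture`.
#' @export
aperture_spec <- function(material = "tungsten", bore_radius_mm = 3,
                          thickness_mm = NULL, offset_mm = c(0, 0)) {
  mat <- .as_material(material)
  stopifnot(bore_radius_mm > 0, length(offset_mm) == 2)
  if (is.null(thickness_mm)) {
    thickness_mm <- switch(mat$name,
      tungsten = 11.1,
      nickel = 18.5,
      min_stopping_thickness(mat, energy_from_range("water", 100)))
  }
  stopifnot(thickness_mm > 0)
  structure(list(material = mat, thickness_mm = thickness_mm,
                 bore_radius_mm = bore_radius_mm, offset_mm = offset_mm),
            class = "aperture")
}

#' Is a lateral position inside the aperture bore?
#'
#' Strict inequality: a point at exactly the bore radius is outside.
#'
#' @param xy Numeric length-2 (x, y) in mm, or an n x 2 matrix.
#' @param aperture An [aperture_spec()].
#' @return Logical (vectorized over rows).
#' @export
in_bore <- function(xy, aperture) {
  stopifnot(inherits(aperture, "aperture"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  dx <- xy[, 1] - aperture$offset_mm[1]
  dy <- xy[, 2] - aperture$offset_mm[2]
  sqrt(dx^2 + dy^2) < aperture$bore_radius_mm
}

#' Axial geometry stack for beamlet transport
#'
#' Orders the elements upstream to downstream: air from the source plane,
#' optional range shifter, air gap, optional aperture, air (the
#' aperture-to-surface distance, ASD), then the voxelized water phantom.
#'
#' @param range_shifter `NULL`, or a list with `material` (default
#'   polycarbonate) and `wet_mm` (water-equivalent thickness, mm).
#' @param rs_exit_to_surface_mm Distance from the range shifter's downstream
#'   face to the phantom surface, mm. `NULL` (default) abuts the range
#'   shifter to the aperture (separated by `gap_mm`); use e.g. 250 with an
#'   isocenter depth of 50 mm for an extended range shifter 300 mm upstream
#'   of isocenter.
#' @param gap_mm Range-shifter-to-aperture gap along the axis, mm.
#' @param aperture `NULL` or an [aperture_spec()].
#' @param asd_mm Aperture downstream face to phantom surface distance, mm.
#' @param isocenter_depth_mm Isocenter depth in the phantom, mm.
#' @param phantom_depth_mm Phantom (scoring grid) depth, mm.
#' @param phantom_halfwidth_mm Lateral half-width of the scoring grid, mm.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param source_to_iso_mm Source plane distance upstream of isocenter, mm.
#' @param rs_energy_mev Energy at which the WET-to-physical-thickness
#'   conversion of the range shifter is evaluated.
#' @return An object of class `geometry_stack`.
#' @export
geometry_stack <- function(range_shifter = list(material = "polycarbonate",
                                                wet_mm = 45),
                           rs_exit_to_surface_mm = NULL,
                           gap_mm = 0, aperture = NULL, asd_mm = 50,
                           isocenter_depth_mm = 50, phantom_depth_mm = 130,
                           phantom_halfwidth_mm = 50, voxel_mm = 1,
                           source_to_iso_mm = 500, rs_energy_mev = 100) {
  stopifnot(gap_mm >= 0, asd_mm >= 0, voxel_mm > 0, phantom_depth_mm > 0)
  if (!is.null(aperture) && !inherits(aperture, "aperture")) {
    stop("aperture must be NULL or an aperture_spec()")
  }
  rs <- NULL
  if (!is.null(range_shifter) && range_shifter$wet_mm > 0) {
    rs_mat <- .as_material(range_shifter$material %||% "polycarbonate")
    rs <- list(material = rs_mat, wet_mm = range_shifter$wet_mm,
               thickness_mm = thickness_for_wet(rs_mat, range_shifter$wet_mm,
                                                rs_energy_mev))
  }
  ap_thick <- if (is.null(aperture)) 0 else aperture$thickness_mm
  ap_exit <- -asd_mm
  rs_exit <- if (!is.null(rs_exit_to_surface_mm)) {
    -rs_exit_to_surface_mm
  } else {
    ap_exit - ap_thick - gap_mm
  }
  z_source <- isocenter_depth_mm - source_to_iso_mm
  if (!is.null(rs)) {
    if (!is.null(rs_exit_to_surface_mm) && !is.null(aperture) &&
        rs_exit > ap_exit - ap_thick + 1e-9) {
      stop("geometry overlap: range shifter extends into the aperture")
    }
    if (rs_exit - rs$thickness_mm < z_source + 1e-9) {
      stop("geometry overlap: range shifter extends upstream of the source plane")
    }
  }
  if (!is.null(aperture) && ap_exit - ap_thick < z_source + 1e-9) {
    stop("geometry overlap: aperture extends upstream of the source plane")
  }
  structure(list(range_shifter = rs, rs_exit_z = rs_exit, gap_mm = gap_mm,
                 aperture = aperture, asd_mm = asd_mm,
                 isocenter_depth_mm = isocenter_depth_mm,
                 phantom_depth_mm = phantom_depth_mm,
                 phantom_halfwidth_mm = phantom_halfwidth_mm,
                 voxel_mm = voxel_mm, source_to_iso_mm = source_to_iso_mm,
                 z_source = z_source),
            class = "geometry_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replace the aperture of a geometry by air
#'
#' Used for paired with/without-aperture runs: the slab structure (and the
#' range-shifter position) is kept identical, only the aperture wall
#' material becomes air.
#'
#' @param geometry A [geometry_stack()].
#' @return A `geometry_stack` with the aperture disabled.
#' @export
remove_aperture <- function(geometry) {
  stopifnot(inherits(geometry, "geometry_stack"))
  geometry$aperture_disabled <- TRUE
  geometry
}

# build the C-level slab/material description
.build_slabs <- function(geometry) {
  mat_names <- c("air", "water")
  if (!is.null(geometry$range_shifter)) {
    mat_names <- c(mat_names, geometry$range_shifter$material$name)
  }
  ap <- geometry$aperture
  disabled <- isTRUE(geometry$aperture_disabled)
  if (!is.null(ap) && !disabled) mat_names <- c(mat_names, ap$material$name)
  mat_names <- unique(mat_names)
  mats <- lapply(mat_names, function(nm) {
    m <- get_material(nm)
    list(density = m$density, zova = m$z_over_a, x0 = m$radiation_length,
         lambda_mm = .nuclear_lambda_gcm2(nm) / m$density * 10,
         log_e = m$log_e, log_s = m$log_s)
  })
  midx <- function(nm) match(nm, mat_names) - 1L
  air <- get_material("air")

  slabs <- list()
  add_air <- function(z0, z1) {
    if (z1 - z0 <= 1e-9) return()
    t_g <- (z1 - z0) / 10 * air$density
    slabs[[length(slabs) + 1]] <<- list(
      z0 = z0, z1 = z1, type = 0L, mat = midx("air"), mat_in = midx("air"),
      f_ms = .highland_factor(t_g, air$radiation_length), f_ms_in = 1,
      max_step = 10.0, max_step_in = 10.0, region = 0L,
      bore_r = 0, dx = 0, dy = 0)
  }
  z <- geometry$z_source
  ap_thick <- if (is.null(ap)) 0 else ap$thickness_mm
  ap_exit <- -geometry$asd_mm
  ap_entry <- ap_exit - ap_thick

  if (!is.null(geometry$range_shifter)) {
    rs <- geometry$range_shifter
    rs_entry <- geometry$rs_exit_z - rs$thickness_mm
    add_air(z, rs_entry)
    t_g <- rs$thickness_mm / 10 * rs$material$density
    slabs[[length(slabs) + 1]] <- list(
      z0 = rs_entry, z1 = geometry$rs_exit_z, type = 0L,
      mat = midx(rs$material$name), mat_in = midx(rs$material$name),
      f_ms = .highland_factor(t_g, rs$material$radiation_length), f_ms_in = 1,
      max_step = if (rs$material$is_metal) 0.2 else 1.0,
      max_step_in = 1.0, region = 1L, bore_r = 0, dx = 0, dy = 0)
    z <- geometry$rs_exit_z
  }
  if (!is.null(ap)) {
    add_air(z, ap_entry)
    if (disabled) {
      add_air(ap_entry, ap_exit)
    } else {
      t_wall <- ap$thickness_mm / 10 * ap$material$density
      t_bore <- ap$thickness_mm / 10 * air$density
      slabs[[length(slabs) + 1]] <- list(
        z0 = ap_entry, z1 = ap_exit, type = 1L,
        mat = midx(ap$material$name), mat_in = midx("air"),
        f_ms = .highland_factor(t_wall, ap$material$radiation_length),
        f_ms_in = .highland_factor(t_bore, air$radiation_length),
        max_step = if (ap$material$is_metal) 0.2 else 1.0, max_step_in = 0.2,
        region = 2L, bore_r = ap$bore_radius_mm,
        dx = ap$offset_mm[1], dy = ap$offset_mm[2])
    }
    z <- ap_exit
  }
  add_air(z, 0)
  water <- get_material("water")
  t_g <- geometry$phantom_depth_mm / 10 * water$density
  slabs[[length(slabs) + 1]] <- list(
    z0 = 0, z1 = geometry$phantom_depth_mm, type = 0L,
    mat = midx("water"), mat_in = midx("water"),
    f_ms = .highland_factor(t_g, water$radiation_length), f_ms_in = 1,
    max_step = 1.0, max_step_in = 1.0, region = 3L, bore_r = 0, dx = 0, dy = 0)

  record_z <- -geometry$asd_mm
  record_slab <- -1L
  for (i in seq_along(slabs)) {
    if (abs(slabs[[i]]$z1 - record_z) < 1e-6) record_slab <- i - 1L
  }
  list(slabs = slabs, mats = mats, record_slab = record_slab)
}

.grid_spec <- function(geometry) {
  v <- geometry$voxel_mm
  nhalf <- floor(geometry$phantom_halfwidth_mm / v)
  nx <- 2L * nhalf + 1L
  nz <- as.integer(round(geometry$phantom_depth_mm / v))
  list(nx = nx, ny = nx, nz = nz, voxel = v,
       x0 = -nx * v / 2, y0 = -nx * v / 2, z0 = 0)
}

#' Transport a beamlet through a geometry stack
#'
#' Runs the condensed-history Monte Carlo kernel for every proton state in
#' `source`, scoring dose and dose-averaged-LET accumulators in the phantom
#' voxel grid and recording the surviving phase space at the aperture exit
#' plane. Fully reproducible: each primary owns an RNG stream derived from
#' `(seed, primary index)`.
#'
#' @param source A `proton_states` matrix from [sample_beamlet()].
#' @param geometry A [geometry_stack()].
#' @param seed Integer seed for the transport streams.
#' @param nuclear Enable the simplified nuclear-removal model.
#' @param cutoff_mev Kinetic-energy cutoff; below it the residual energy is
#'   deposited locally.
#' @param local_frac Fraction of a nuclearly removed proton's energy
#'   deposited locally (the remainder is booked as escaped).
#' @return A `transport_result`: list with `dose_grid` (class `dose_grid`),
#'   `exit_states`, `n_primaries`, `seed`, `edep` (named energy bookkeeping,
#'   MeV) and `e_initial` (total injected kinetic energy, MeV).
#' @export
transport_beamlet <- function(source, geometry, seed = 1, nuclear = TRUE,
                              cutoff_mev = 1, local_frac = 0.6) {
  stopifnot(inherits(geometry, "geometry_stack"), nrow(source) > 0)
  built <- .build_slabs(geometry)
  grid <- .grid_spec(geometry)
  out <- cpp_transport(unclass(source), geometry$z_source, built$slabs,
                       built$mats, grid,
                       list(seed = as.numeric(seed), cutoff = cutoff_mev,
                            nuclear = nuclear, local_frac = local_frac,
                            e_nuc_min = 20, record_slab = built$record_slab,
                            max_steps = 50000L))
  edep <- out$edep
  names(edep) <- c("air", "range_shifter", "aperture", "phantom", "escaped")
  exit <- out$exit_states
  colnames(exit) <- c("x", "y", "tx", "ty", "energy", "weight")
  dg <- structure(list(dose = out$dose, let_num = out$let_num,
                       let_den = out$let_den, voxel_mm = grid$voxel,
                       origin = c(grid$x0, grid$y0, grid$z0)),
                  class = "dose_grid")
  structure(list(dose_grid = dg,
                 exit_states = structure(exit, class = c("proton_states",
                                                         "matrix", "array")),
                 n_primaries = nrow(source), seed = seed,
                 edep = edep, e_initial = out$e_initial,
                 geometry = geometry),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %d primaries, seed %s\n", x$n_primaries,
              format(x$seed)))
  cat("  energy bookkeeping (MeV):\n")
  print(round(x$edep, 1))
  invisible(x)
}

#' Experiment configuration for paired aperture runs
#'
#' @param material Aperture material.
#' @param bore_radius_mm Aperture opening radius, mm.
#' @param asd_mm Aperture-to-surface distance, mm.
#' @param gap_mm Range-shifter-to-aperture gap, mm.
#' @param rs_wet_mm Range-shifter water-equivalent thickness, mm.
#' @param bp_depth_mm Target Bragg-peak depth in the phantom, mm.
#' @param n_histories Number of primaries.
#' @param offset_mm Aperture lateral misalignment (dx, dy), mm.
#' @param thickness_mm Aperture thickness override, mm.
#' @param nuclear Enable the nuclear-removal model.
#' @param beam A [beam_model()].
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(material = "tungsten", bore_radius_mm = 3, asd_mm = 50,
                       gap_mm = 0, rs_wet_mm = 45, bp_depth_mm = 50,
                       n_histories = 2e5, offset_mm = c(0, 0),
                       thickness_mm = NULL, nuclear = TRUE,
                       beam = beam_model()) {
  structure(list(material = material, bore_radius_mm = bore_radius_mm,
                 asd_mm = asd_mm, gap_mm = gap_mm, rs_wet_mm = rs_wet_mm,
                 bp_depth_mm = bp_depth_mm, n_histories = n_histories,
                 offset_mm = offset_mm, thickness_mm = thickness_mm,
                 nuclear = nuclear, beam = beam), class = "ssa_config")
}

#' Run a configuration with and without its aperture
#'
#' Both runs share the same source phase space (same source seed); the
#' without-aperture run replaces the aperture wall by air and keeps every
#' other element identical, which is the denominator geometry of the
#' dose-ratio beamlet-transmission definition.
#'
#' @param config An [ssa_config()].
#' @param seed Integer seed (source sampling and transport).
#' @return List with elements `with`, `without` (both `transport_result`),
#'   `energy` (nominal MeV) and `config`.
#' @export
simulate_configuration <- function(config, seed = 1) {
  stopifnot(inherits(config, "ssa_config"))
  energy <- energy_for_bp_depth(config$bp_depth_mm, config$rs_wet_mm)
  src <- sample_beamlet(config$beam, energy, config$n_histories, seed = seed)
  ap <- aperture_spec(config$material, config$bore_radius_mm,
                      thickness_mm = config$thickness_mm,
                      offset_mm = config$offset_mm)
  geom <- geometry_stack(
    range_shifter = list(material = "polycarbonate", wet_mm = config$rs_wet_mm),
    gap_mm = config$gap_mm, aperture = ap, asd_mm = config$asd_mm,
    phantom_depth_mm = max(60, config$bp_depth_mm + 30),
    source_to_iso_mm = config$beam$source_to_iso_mm,
    rs_energy_mev = energy)
  with_ap <- transport_beamlet(src, geom, seed = seed, nuclear = config$nuclear)
  without_ap <- transport_beamlet(src, remove_aperture(geom), seed = seed,
                                  nuclear = config$nuclear)
  list(with = with_ap, without = without_ap, energy = energy, config = config)
}

#' Single condensed-history step (reference implementation)
#'
#' Advances proton states by one step in a homogeneous medium using the same
#' physics as the transport kernel (mean Bethe loss, Bohr straggling,
#' Highland scattering with correlated displacement), drawing from R's RNG.
#' Intended for physics validation at the single-step level; the full stack
#' transport uses the compiled kernel.
#'
#' @param states A `proton_states` matrix (columns x, y, tx, ty, energy,
#'   weight).
#' @param material Medium (a `proton_material` or name).
#' @param step_length_mm Step length along z, mm (> 0).
#' @param cutoff_mev Kill-and-deposit threshold, MeV.
#' @return Updated `proton_states`; attribute `deposited_mev` holds the
#'   per-proton energy deposited in this step, and column `energy` is 0 with
#'   `weight` unchanged for killed protons (attribute `alive` is a logical
#'   vector).
#' @export
step_proton <- function(states, material, step_length_mm, cutoff_mev = 1) {
  stopifnot(step_length_mm > 0)
  material <- .as_material(material)
  n <- nrow(states)
  e <- states[, "energy"]
  alive <- e >= cutoff_mev
  slin <- material$density * mass_stopping_power(material, pmax(e, 1)) / 10
  spath <- step_length_mm * sqrt(1 + states[, "tx"]^2 + states[, "ty"]^2)
  om2 <- .bohr_kappa(material, pmax(e, 1)) * spath
  de_mean <- slin * spath
  # straggling only where the Gaussian model is valid (sigma <= mean loss)
  de <- de_mean + ifelse(sqrt(om2) <= de_mean, sqrt(om2), 0) * stats::rnorm(n)
  de <- pmin(pmax(de, 0), e)
  emid <- pmax(e - de / 2, 1)
  t_g <- spath / 10 * material$density
  f <- .highland_factor(step_length_mm / 10 * material$density,
                        material$radiation_length)
  th0 <- .highland_theta0(emid, t_g, material$radiation_length, f = f)
  z2x <- stats::rnorm(n); z1x <- stats::rnorm(n)
  z2y <- stats::rnorm(n); z1y <- stats::rnorm(n)
  out <- states
  dz <- step_length_mm
  out[, "x"] <- states[, "x"] + states[, "tx"] * dz +
    dz * th0 * (z1x / sqrt(12) + z2x / 2)
  out[, "y"] <- states[, "y"] + states[, "ty"] * dz +
    dz * th0 * (z1y / sqrt(12) + z2y / 2)
  out[, "tx"] <- states[, "tx"] + th0 * z2x
  out[, "ty"] <- states[, "ty"] + th0 * z2y
  enew <- e - de
  dep <- de
  died <- alive & (enew < cutoff_mev)
  dep[died] <- dep[died] + enew[died]
  enew[died] <- 0
  out[, "energy"] <- ifelse(alive, enew, e)
  dep[!alive] <- 0
  attr(out, "deposited_mev") <- dep
  attr(out, "alive") <- alive & !died
  out
}

#' Analytic Fermi-Eyges lateral sigma of an infinitesimal beamlet
#'
#' Integrates the Highland-consistent scattering power of a homogeneous
#' medium to give the lateral spread sigma(z) of an initially point-like,
#' parallel beamlet, for cross-checking the Monte Carlo kernel.
#'
#' @param energy Initial kinetic energy, MeV.
#' @param z_mm Depths at which to evaluate sigma, mm.
#' @param material Medium (default water).
#' @return Numeric vector of sigma values, mm.
#' @export
fermi_eyges_sigma <- function(energy, z_mm, material = "water") {
  material <- .as_material(material)
  r0 <- csda_range(material, energy)
  zmax <- min(max(z_mm), r0 * 0.999)
  u <- seq(0, zmax, length.out = 2000)
  resid <- pmax(r0 - u, 1e-6)
  res_gcm2 <- resid * material$density / 10
  e_u <- pmax(exp(stats::approx(material$log_r, material$log_e,
                                xout = log(res_gcm2), rule = 2)$y), 1)
  f <- .highland_factor(r0 / 10 * material$density, material$radiation_length)
  pv <- e_u * (e_u + 2 * 938.27209) / (e_u + 938.27209)
  t_power <- (14.1 / pv)^2 * material$density / (10 * material$radiation_length) * f^2
  vapply(z_mm, function(z) {
    sel <- u <= z
    if (sum(sel) < 2) return(0)
    uu <- u[sel]; tt <- t_power[sel] * (z - uu)^2
    sqrt(sum(diff(uu) * (utils::head(tt, -1) + utils::tail(tt, -1)) / 2))
  }, 0)
}
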