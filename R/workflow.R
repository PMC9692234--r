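# End-to-end parameter-sweep studies: spot sizes versus comparators,
# beamlet transmission (with misalignment), range-shifter-to-aperture gap
# tradeoff, neutron doses per material, and per-field plan scoring.

#' Sweep specification for the aperture studies
#'
#' The defaults define the standard study conditions: tungsten and nickel
#' apertures, opening radii 1-4 mm, aperture-to-surface distances 1/50/100
#' mm, range-shifter gaps 0-300 mm, nine Bragg-peak depths spanning
#' 0-100 mm, and 2e5 histories per configuration.
#'
#' @param materials Aperture materials.
#' @param radii_mm Opening radii, mm.
#' @param asds_mm Aperture-to-surface distances, mm.
#' @param gaps_mm Range-shifter-to-aperture gaps, mm.
#' @param bp_depths_mm Target Bragg-peak depths, mm.
#' @param comparators Comparator beams for the spot-size study: any of
#'   `"open"`, `"ers"`, `"moveable_rs"`, `"infinitesimal"`.
#' @param n_histories Primaries per configuration.
#' @param seed Base seed.
#' @param rs_wet_mm Range-shifter WET, mm.
#' @param nuclear Enable the nuclear-removal model.
#' @param beam A [beam_model()].
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(materials = c("tungsten", "nickel"), radii_mm = 1:4,
                       asds_mm = c(1, 50, 100), gaps_mm = seq(0, 300, by = 50),
                       bp_depths_mm = seq(0, 100, length.out = 9),
                       comparators = c("open", "ers", "moveable_rs",
                                       "infinitesimal"),
                       n_histories = 2e5, seed = 1, rs_wet_mm = 45,
                       nuclear = TRUE, beam = beam_model()) {
  stopifnot(length(materials) > 0, length(radii_mm) > 0, length(asds_mm) > 0,
            length(bp_depths_mm) > 0, n_histories > 0)
  structure(list(materials = materials, radii_mm = radii_mm,
                 asds_mm = asds_mm, gaps_mm = gaps_mm,
                 bp_depths_mm = bp_depths_mm, comparators = comparators,
                 n_histories = n_histories, seed = seed,
                 rs_wet_mm = rs_wet_mm, nuclear = nuclear, beam = beam),
            class = "sweep_spec")
}

#' Simulate a comparator beam (no aperture)
#'
#' Comparators: `"open"` (no device), `"infinitesimal"` (point-like parallel
#' beamlet, the theoretical lower spot-size limit), `"ers"` (extended range
#' shifter, 300 mm upstream of isocenter), `"moveable_rs"` (range shifter at
#' the device position, `asd_mm` from the surface).
#'
#' @param type Comparator name.
#' @param bp_depth_mm Target Bragg-peak depth, mm.
#' @param spec A [sweep_spec()] supplying beam, histories, WET and seed.
#' @param asd_mm Device position for `"moveable_rs"`.
#' @param seed Override seed.
#' @return A `transport_result`.
#' @export
simulate_comparator <- function(type, bp_depth_mm, spec = sweep_spec(),
                                asd_mm = 50, seed = spec$seed) {
  type <- match.arg(type, c("open", "infinitesimal", "ers", "moveable_rs"))
  beam <- spec$beam
  phantom_depth <- max(60, bp_depth_mm + 30)
  if (type %in% c("open", "infinitesimal")) {
    energy <- energy_for_bp_depth(bp_depth_mm, 0)
    src <- sample_beamlet(beam, energy, spec$n_histories, seed = seed,
                          infinitesimal = (type == "infinitesimal"))
    geom <- geometry_stack(range_shifter = NULL, aperture = NULL,
                           asd_mm = 0, phantom_depth_mm = phantom_depth,
                           source_to_iso_mm = beam$source_to_iso_mm)
  } else {
    energy <- energy_for_bp_depth(bp_depth_mm, spec$rs_wet_mm)
    src <- sample_beamlet(beam, energy, spec$n_histories, seed = seed)
    rs_exit <- if (type == "ers") 300 - 50 else asd_mm
    geom <- geometry_stack(
      range_shifter = list(material = "polycarbonate", wet_mm = spec$rs_wet_mm),
      rs_exit_to_surface_mm = rs_exit, aperture = NULL, asd_mm = asd_mm,
      phantom_depth_mm = phantom_depth,
      source_to_iso_mm = beam$source_to_iso_mm, rs_energy_mev = energy)
  }
  transport_beamlet(src, geom, seed = seed, nuclear = spec$nuclear)
}

.sigma_at_own_bp <- function(result) {
  curve <- idd(result)
  bp <- bragg_peak_depth(curve)
  c(bp = bp, sigma = as.numeric(spot_sigma(result, bp)))
}

#' Spot-size study: aperture configurations versus comparator beams
#'
#' One row per (configuration or comparator, Bragg-peak depth) with the spot
#' sigma evaluated at the run's own Bragg-peak depth.
#'
#' @param spec A [sweep_spec()].
#' @return Data frame with columns `comparator`, `material`, `radius_mm`,
#'   `asd_mm`, `bp_target_mm`, `bp_depth_mm`, `sigma_mm`, `energy_MeV`,
#'   `n_histories`, `seed`.
#' @export
run_spot_size_study <- function(spec = sweep_spec()) {
  rows <- list()
  push <- function(comparator, material, radius, asd, target, res, energy) {
    s <- .sigma_at_own_bp(res)
    rows[[length(rows) + 1]] <<- data.frame(
      comparator = comparator, material = material, radius_mm = radius,
      asd_mm = asd, bp_target_mm = target, bp_depth_mm = s[["bp"]],
      sigma_mm = s[["sigma"]], energy_MeV = energy,
      n_histories = spec$n_histories, seed = spec$seed)
  }
  for (depth in spec$bp_depths_mm) {
    for (cmp in spec$comparators) {
      asds <- if (cmp == "moveable_rs") spec$asds_mm else 0
      for (asd in asds) {
        wet <- if (cmp %in% c("ers", "moveable_rs")) spec$rs_wet_mm else 0
        energy <- tryCatch(energy_for_bp_depth(depth, wet),
                           error = function(e) NA_real_)
        if (is.na(energy)) next  # unreachable without a range shifter
        res <- simulate_comparator(cmp, depth, spec, asd_mm = asd)
        push(cmp, NA_character_, NA_real_, asd, depth, res, energy)
      }
    }
    for (mat in spec$materials) {
      for (r in spec$radii_mm) {
        for (asd in spec$asds_mm) {
          cfg <- ssa_config(material = mat, bore_radius_mm = r, asd_mm = asd,
                            rs_wet_mm = spec$rs_wet_mm, bp_depth_mm = depth,
                            n_histories = spec$n_histories,
                            nuclear = spec$nuclear, beam = spec$beam)
          energy <- energy_for_bp_depth(depth, spec$rs_wet_mm)
          src <- sample_beamlet(spec$beam, energy, spec$n_histories,
                                seed = spec$seed)
          geom <- geometry_stack(
            range_shifter = list(material = "polycarbonate",
                                 wet_mm = spec$rs_wet_mm),
            aperture = aperture_spec(mat, r), asd_mm = asd,
            phantom_depth_mm = max(60, depth + 30),
            source_to_iso_mm = spec$beam$source_to_iso_mm,
            rs_energy_mev = energy)
          res <- transport_beamlet(src, geom, seed = spec$seed,
                                   nuclear = spec$nuclear)
          push("ssa", mat, r, asd, depth, res, energy)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Beamlet-transmission study with optional misalignment
#'
#' For each (material, radius, depth) runs the paired with/without-aperture
#' simulation at the given ASD, aligned and with the aperture laterally
#' offset.
#'
#' @param spec A [sweep_spec()].
#' @param offset_mm Misalignment magnitude, mm (applied along x).
#' @param asd_mm Aperture-to-surface distance, mm.
#' @return Data frame with `material`, `radius_mm`, `bp_target_mm`,
#'   `energy_MeV`, `transmission`, `transmission_offset`.
#' @export
run_transmission_study <- function(spec = sweep_spec(), offset_mm = 1,
                                   asd_mm = 50) {
  stopifnot(offset_mm >= 0)
  rows <- list()
  for (mat in spec$materials) {
    for (r in spec$radii_mm) {
      for (depth in spec$bp_depths_mm) {
        cfg <- ssa_config(material = mat, bore_radius_mm = r, asd_mm = asd_mm,
                          rs_wet_mm = spec$rs_wet_mm, bp_depth_mm = depth,
                          n_histories = spec$n_histories,
                          nuclear = spec$nuclear, beam = spec$beam)
        pair <- simulate_configuration(cfg, seed = spec$seed)
        t0 <- transmission(pair$with, pair$without)
        t1 <- NA_real_
        if (offset_mm > 0) {
          cfg_off <- cfg
          cfg_off$offset_mm <- c(offset_mm, 0)
          src <- sample_beamlet(spec$beam, pair$energy, spec$n_histories,
                                seed = spec$seed)
          geom_off <- pair$with$geometry
          geom_off$aperture$offset_mm <- c(offset_mm, 0)
          res_off <- transport_beamlet(src, geom_off, seed = spec$seed,
                                       nuclear = spec$nuclear)
          t1 <- transmission(res_off, pair$without)
        }
        rows[[length(rows) + 1]] <- data.frame(
          material = mat, radius_mm = r, bp_target_mm = depth,
          energy_MeV = pair$energy, transmission = t0,
          transmission_offset = t1, n_histories = spec$n_histories,
          seed = spec$seed)
      }
    }
  }
  do.call(rbind, rows)
}

#' Range-shifter-to-aperture gap study
#'
#' Tungsten aperture, 3 mm radius, 50 mm ASD, Bragg peak at 50 mm: spot
#' sigma and transmission versus the gap, normalized to the gap-0 values.
#'
#' @param spec A [sweep_spec()] (its `gaps_mm`, histories and seed are used).
#' @param material,radius_mm,asd_mm,bp_depth_mm Study configuration.
#' @return Data frame with `gap_mm`, `sigma_mm`, `transmission`,
#'   `rel_sigma`, `rel_transmission`.
#' @export
run_gap_study <- function(spec = sweep_spec(), material = "tungsten",
                          radius_mm = 3, asd_mm = 50, bp_depth_mm = 50) {
  rows <- lapply(spec$gaps_mm, function(gap) {
    cfg <- ssa_config(material = material, bore_radius_mm = radius_mm,
                      asd_mm = asd_mm, gap_mm = gap,
                      rs_wet_mm = spec$rs_wet_mm, bp_depth_mm = bp_depth_mm,
                      n_histories = spec$n_histories, nuclear = spec$nuclear,
                      beam = spec$beam)
    pair <- simulate_configuration(cfg, seed = spec$seed)
    m <- spot_metrics(pair)
    data.frame(gap_mm = gap, sigma_mm = m$sigma_mm,
               transmission = m$transmission)
  })
  out <- do.call(rbind, rows)
  out$rel_sigma <- out$sigma_mm / out$sigma_mm[1]
  out$rel_transmission <- out$transmission / out$transmission[1]
  out
}

#' Neutron-dose study over materials and maximum treatment depths
#'
#' @param materials Aperture candidate materials.
#' @param max_depths_mm Maximum treatment depths in water, mm; each is
#'   converted to the proton energy with that water range (capped at
#'   230 MeV).
#' @param n_protons Protons per beamlet.
#' @return Data frame with `material`, `max_depth_mm`, `energy_MeV`,
#'   `block_thickness_mm`, `dose_Gy`, `relative_to_tungsten_pct`.
#' @export
run_neutron_study <- function(materials = c("tungsten", "lead", "brass",
                                            "nickel"),
                              max_depths_mm = seq(25, 325, by = 50),
                              n_protons = 1e6) {
  model <- neutron_yield_model()
  rows <- list()
  for (depth in max_depths_mm) {
    energy <- min(energy_from_range("water", depth), 230)
    ref <- neutron_dose("tungsten", energy, n_protons, model)
    for (mat in materials) {
      nd <- neutron_dose(mat, energy, n_protons, model)
      rows[[length(rows) + 1]] <- data.frame(
        material = mat, max_depth_mm = depth, energy_MeV = energy,
        block_thickness_mm = nd$block_thickness, dose_Gy = nd$phantom_dose_Gy,
        relative_to_tungsten_pct = 100 * nd$phantom_dose_Gy / ref$phantom_dose_Gy)
    }
  }
  do.call(rbind, rows)
}

#' Score synthetic treatment fields: integral neutron dose and added time
#'
#' Eligibility-filtered fields are scored for every (material, radius)
#' configuration using the supplied transmission tables.
#'
#' @param plans List of `treatment_field`s.
#' @param transmission_tables Named list (names `"<material>_<radius>"`) of
#'   data frames with `energy_MeV` and `transmission`.
#' @param configs Data frame with columns `material` and `radius_mm`.
#' @param rs_wet_mm Range-shifter WET, mm.
#' @param spot_spacing_mm,motor_speed_mm_s Delivery-time parameters.
#' @return Data frame: one row per eligible field and configuration with
#'   `field_id`, `material`, `radius_mm`, `n_spots`,
#'   `integral_neutron_dose_Gy`, `t_add_s`.
#' @export
run_plan_study <- function(plans, transmission_tables,
                           configs = expand.grid(
                             material = c("tungsten", "nickel"),
                             radius_mm = c(3, 4),
                             stringsAsFactors = FALSE),
                           rs_wet_mm = 45, spot_spacing_mm = 5,
                           motor_speed_mm_s = 500) {
  eligible <- Filter(field_eligible, plans)
  model <- neutron_yield_model()
  rows <- list()
  for (f in eligible) {
    for (i in seq_len(nrow(configs))) {
      mat <- configs$material[i]
      r <- configs$radius_mm[i]
      tb <- transmission_tables[[paste0(mat, "_", r)]]
      if (is.null(tb)) stop("missing transmission table for ", mat, "_", r)
      lookup <- transmission_lookup_from_table(tb)
      rows[[length(rows) + 1]] <- data.frame(
        field_id = f$field_id, material = mat, radius_mm = r,
        n_spots = nrow(f$spots),
        integral_neutron_dose_Gy = integral_neutron_dose(
          f, mat, lookup, rs_wet_mm = rs_wet_mm, model = model),
        t_add_s = additional_time(f, spot_spacing_mm, motor_speed_mm_s))
    }
  }
  do.call(rbind, rows)
}

#' Write a sweep specification to YAML
#'
#' @param spec A [sweep_spec()].
#' @param path Output path.
#' @export
write_sweep_config <- function(spec, path) {
  payload <- spec[c("materials", "radii_mm", "asds_mm", "gaps_mm",
                    "bp_depths_mm", "comparators", "n_histories", "seed",
                    "rs_wet_mm", "nuclear")]
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read a sweep specification from YAML
#'
#' @param path File written by [write_sweep_config()].
#' @return A [sweep_spec()].
#' @export
read_sweep_config <- function(path) {
  p <- yaml::read_yaml(path)
  do.call(sweep_spec, p)
}
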