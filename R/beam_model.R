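# Synthetic machine beam model and treatment-plan generator.
#
# The beam model emulates a modern PBS machine: in-air spot sigma at
# isocenter of about 6 mm at the lowest deliverable energy (70 MeV) and
# 2 mm at the highest (230 MeV), interpolated monotonically in 1/E between
# those anchors. Divergence defaults to zero (parallel Gaussian beam) since
# the comparative quantities studied here are dominated by range-shifter
# scattering close to the patient.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct a synthetic PBS machine beam model
#'
#' @param e_low,e_high Lowest and highest nominal machine energies (MeV).
#' @param sigma_low,sigma_high In-air spot sigma at isocenter (mm) at `e_low`
#'   and `e_high`.
#' @param n_energies Number of discrete nominal energies.
#' @param source_to_iso_mm Distance from the source (nozzle-exit) plane to
#'   isocenter, mm.
#' @param divergence_sigma_mrad Angular sigma of the beamlet at the source
#'   plane (mrad); default 0 (parallel beam).
#' @param sigma_table Optional override: data frame with columns `energy_MeV`
#'   and `sigma_mm` used instead of the two-anchor 1/E interpolation.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(e_low = 70, e_high = 230, sigma_low = 6, sigma_high = 2,
                       n_energies = 17, source_to_iso_mm = 500,
                       divergence_sigma_mrad = 0, sigma_table = NULL) {
  stopifnot(e_high > e_low, sigma_low >= sigma_high, source_to_iso_mm > 0)
  structure(list(
    energies = seq(e_low, e_high, length.out = n_energies),
    e_low = e_low, e_high = e_high,
    sigma_low = sigma_low, sigma_high = sigma_high,
    source_to_iso_mm = source_to_iso_mm,
    divergence_sigma_mrad = divergence_sigma_mrad,
    sigma_table = sigma_table), class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(paste0("<beam_model> %d energies %g-%g MeV, sigma at iso ",
                     "%g mm (low E) to %g mm (high E), source %g mm upstream\n"),
              length(x$energies), x$e_low, x$e_high,
              x$sigma_low, x$sigma_high, x$source_to_iso_mm))
  invisible(x)
}

#' In-air spot sigma at isocenter
#'
#' Interpolated in 1/E between the model's low- and high-energy anchors
#' (or from the model's override table), so sigma is monotone non-increasing
#' with energy.
#'
#' @param model A [beam_model()].
#' @param energy Proton kinetic energy in MeV (vectorized); must lie within
#'   the machine energy range.
#' @return Sigma in mm.
#' @export
sigma_air <- function(model, energy) {
  stopifnot(inherits(model, "beam_model"))
  if (any(energy < model$e_low - 1e-9 | energy > model$e_high + 1e-9)) {
    stop(sprintf("energy outside machine range [%g, %g] MeV",
                 model$e_low, model$e_high))
  }
  if (!is.null(model$sigma_table)) {
    tb <- model$sigma_table
    return(stats::approx(1 / tb$energy_MeV, tb$sigma_mm, xout = 1 / energy)$y)
  }
  b <- (model$sigma_low - model$sigma_high) / (1 / model$e_low - 1 / model$e_high)
  a <- model$sigma_high - b / model$e_high
  a + b / energy
}

#' Sample a beamlet phase space at the source plane
#'
#' Returns `n` proton states at the nozzle-exit plane, directed along +z.
#' With `infinitesimal = TRUE` all protons sit exactly on the beam axis with
#' zero divergence (the theoretical lower-limit beamlet). Otherwise lateral
#' positions (and angles, if the model has divergence) are Gaussian, chosen
#' so that the free-drift sigma at the isocenter plane equals
#' [sigma_air()] at this energy.
#'
#' @param model A [beam_model()].
#' @param energy Nominal kinetic energy, MeV.
#' @param n Number of primaries.
#' @param seed Integer seed; the same seed reproduces the same collection.
#' @param infinitesimal If `TRUE`, zero emittance.
#' @return A `proton_states` matrix with columns
#'   `x, y, tx, ty, energy, weight` (positions mm, slopes dimensionless) and
#'   attribute `source_to_iso_mm`.
#' @export
sample_beamlet <- function(model, energy, n, seed = 1, infinitesimal = FALSE) {
  stopifnot(inherits(model, "beam_model"), n >= 0, length(energy) == 1)
  m <- matrix(0, nrow = n, ncol = 6,
              dimnames = list(NULL, c("x", "y", "tx", "ty", "energy", "weight")))
  m[, "energy"] <- energy
  m[, "weight"] <- 1
  if (!infinitesimal && n > 0) {
    sig_iso <- sigma_air(model, energy)
    div <- model$divergence_sigma_mrad / 1000
    sig_drift <- div * model$source_to_iso_mm
    if (sig_drift >= sig_iso) {
      stop("divergence alone exceeds the configured sigma at isocenter")
    }
    sig_src <- sqrt(sig_iso^2 - sig_drift^2)
    .with_seed(seed, {
      m[, "x"] <- stats::rnorm(n, 0, sig_src)
      m[, "y"] <- stats::rnorm(n, 0, sig_src)
      if (div > 0) {
        m[, "tx"] <- stats::rnorm(n, 0, div)
        m[, "ty"] <- stats::rnorm(n, 0, div)
      }
    })
  }
  structure(m, class = c("proton_states", "matrix", "array"),
            source_to_iso_mm = model$source_to_iso_mm)
}

#' Nominal energy reaching a given Bragg-peak depth behind upstream material
#'
#' Finds the energy whose water CSDA range equals the target depth plus the
#' upstream water-equivalent thickness (range shifter etc.). Energies below
#' the machine minimum are rejected: shallow depths must be reached with a
#' range shifter, as on clinical machines.
#'
#' @param target_depth_mm Desired Bragg-peak depth in water, mm.
#' @param upstream_wet_mm Water-equivalent thickness of material upstream of
#'   the phantom, mm.
#' @param e_min,e_max Deliverable machine energy window, MeV.
#' @return Kinetic energy in MeV.
#' @export
energy_for_bp_depth <- function(target_depth_mm, upstream_wet_mm = 0,
                                e_min = 70, e_max = 230) {
  stopifnot(target_depth_mm >= 0, upstream_wet_mm >= 0)
  e <- energy_from_range("water", target_depth_mm + upstream_wet_mm)
  if (e < e_min) {
    stop(sprintf(paste0("required energy %.2f MeV is below the machine minimum ",
                        "(%g MeV); add upstream range-shifter WET to reach ",
                        "a %g mm depth"), e, e_min, target_depth_mm))
  }
  if (e > e_max) {
    stop(sprintf("required energy %.2f MeV exceeds the machine maximum (%g MeV)",
                 e, e_max))
  }
  e
}

#' Generate synthetic PBS treatment fields
#'
#' Stand-in generator for clinical head-and-neck-like fields: each field has
#' layers spaced in water-equivalent depth, a randomized elliptical target
#' cross-section per layer, spots on a square grid inside the ellipse, and
#' log-normal planned protons per spot (median 1e7, sigma one decade at two
#' sigma). Spot machine energies assume a fixed upstream range-shifter WET.
#'
#' @param n_fields Number of fields (>= 1).
#' @param depth_profile List with `min_range` and `max_range`, each a
#'   length-2 numeric giving the sampling interval (mm WET) for the field's
#'   minimum and maximum treatment depth.
#' @param spot_spacing_mm Lateral spot grid spacing, mm (> 0).
#' @param layer_spacing_mm WET spacing between energy layers, mm.
#' @param semi_axis_range_mm Sampling interval for the ellipse semi-axes, mm.
#' @param protons_per_spot List with `meanlog` and `sdlog` of the log-normal
#'   planned-protons distribution.
#' @param rs_wet_mm Assumed range-shifter WET used to convert layer depth to
#'   machine energy.
#' @param seed Integer seed; plans are reproducible.
#' @return A list of `treatment_field` objects, each a list with `field_id`,
#'   `wet_depth_min`, `wet_depth_max` (mm) and `spots` (data frame with
#'   `energy_MeV`, `x_mm`, `y_mm`, `protons`).
#' @export
generate_synthetic_plan <- function(n_fields,
                                    depth_profile = list(min_range = c(15, 38),
                                                         max_range = c(55, 95)),
                                    spot_spacing_mm = 5,
                                    layer_spacing_mm = 5,
                                    semi_axis_range_mm = c(10, 30),
                                    protons_per_spot = list(meanlog = log(1e7),
                                                            sdlog = log(10) / 2),
                                    rs_wet_mm = 45,
                                    seed = 1) {
  stopifnot(n_fields >= 1, spot_spacing_mm > 0, layer_spacing_mm > 0)
  if (diff(range(semi_axis_range_mm)) < 0 || min(semi_axis_range_mm) <= 0) {
    stop("degenerate target: ellipse semi-axes must be positive")
  }
  .with_seed(seed, {
    lapply(seq_len(n_fields), function(fi) {
      dmin <- stats::runif(1, depth_profile$min_range[1], depth_profile$min_range[2])
      dmax <- stats::runif(1, max(dmin + layer_spacing_mm, depth_profile$max_range[1]),
                           max(dmin + layer_spacing_mm, depth_profile$max_range[2]))
      depths <- seq(dmin, dmax, by = layer_spacing_mm)
      layers <- list()
      spots <- do.call(rbind, lapply(depths, function(d) {
        a <- stats::runif(1, semi_axis_range_mm[1], semi_axis_range_mm[2])
        b <- stats::runif(1, semi_axis_range_mm[1], semi_axis_range_mm[2])
        gx <- seq(-ceiling(a / spot_spacing_mm), ceiling(a / spot_spacing_mm)) *
          spot_spacing_mm
        gy <- seq(-ceiling(b / spot_spacing_mm), ceiling(b / spot_spacing_mm)) *
          spot_spacing_mm
        g <- expand.grid(x_mm = gx, y_mm = gy)
        g <- g[(g$x_mm / a)^2 + (g$y_mm / b)^2 <= 1, , drop = FALSE]
        if (!nrow(g)) stop("degenerate target: layer ellipse contains no spots")
        e <- energy_for_bp_depth(d, rs_wet_mm)
        layers[[length(layers) + 1]] <<- data.frame(
          depth_mm = d, semi_axis_a_mm = a, semi_axis_b_mm = b,
          n_spots = nrow(g))
        data.frame(energy_MeV = e, x_mm = g$x_mm, y_mm = g$y_mm,
                   protons = stats::rlnorm(nrow(g), protons_per_spot$meanlog,
                                           protons_per_spot$sdlog))
      }))
      structure(list(field_id = sprintf("field_%03d", fi),
                     wet_depth_min = dmin, wet_depth_max = dmax,
                     spots = spots, layers = do.call(rbind, layers),
                     spot_spacing_mm = spot_spacing_mm),
                class = "treatment_field")
    })
  })
}

#' @export
print.treatment_field <- function(x, ...) {
  cat(sprintf("<treatment_field> %s: %d spots, WET depth %.1f-%.1f mm\n",
              x$field_id, nrow(x$spots), x$wet_depth_min, x$wet_depth_max))
  invisible(x)
}

#' Write treatment fields to JSON
#'
#' @param fields List of `treatment_field` objects.
#' @param path Output file path.
#' @export
write_plan_json <- function(fields, path) {
  payload <- lapply(fields, function(f) {
    list(field_id = f$field_id, wet_depth_min_mm = f$wet_depth_min,
         wet_depth_max_mm = f$wet_depth_max, spots = f$spots)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read treatment fields from JSON
#'
#' @param path File written by [write_plan_json()].
#' @return List of `treatment_field` objects.
#' @export
read_plan_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    structure(list(field_id = payload$field_id[i],
                   wet_depth_min = payload$wet_depth_min_mm[i],
                   wet_depth_max = payload$wet_depth_max_mm[i],
                   spots = payload$spots[[i]]), class = "treatment_field")
  })
}
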