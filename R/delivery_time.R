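# Additional treatment-time model for a device that must physically move to
# every spot position: constant-speed motion over the spot spacing, summed
# over spots. Acceleration and deceleration are deliberately ignored.

#' Timing parameters for the delivery-time overhead model
#'
#' @param n_spots Number of spots (>= 0).
#' @param spot_spacing_mm Lateral spot spacing, mm (> 0).
#' @param motor_speed_mm_s Device motor speed, mm/s (> 0).
#' @return A list of class `timing_params`.
#' @export
timing_params <- function(n_spots, spot_spacing_mm, motor_speed_mm_s) {
  if (spot_spacing_mm <= 0) stop("spot_spacing_mm must be > 0")
  if (motor_speed_mm_s <= 0) stop("motor_speed_mm_s must be > 0")
  if (n_spots < 0) stop("n_spots must be >= 0")
  structure(list(n_spots = n_spots, spot_spacing_mm = spot_spacing_mm,
                 motor_speed_mm_s = motor_speed_mm_s),
            class = "timing_params")
}

#' Additional delivery time from per-spot device motion
#'
#' `t_add = N * x / v` with N spots, spacing x and motor speed v: e.g. 10 s
#' per 1000 spots at 5 mm spacing and 500 mm/s.
#'
#' @param params A [timing_params()], or a `treatment_field` (then
#'   `spot_spacing_mm` and `motor_speed_mm_s` must be supplied).
#' @param spot_spacing_mm,motor_speed_mm_s Used when `params` is a
#'   `treatment_field`.
#' @return Seconds.
#' @examples
#' additional_time(timing_params(1000, 5, 500))  # 10 s
#' @export
additional_time <- function(params, spot_spacing_mm = 5,
                            motor_speed_mm_s = 500) {
  if (inherits(params, "treatment_field")) {
    params <- timing_params(nrow(params$spots), spot_spacing_mm,
                            motor_speed_mm_s)
  }
  stopifnot(inherits(params, "timing_params"))
  params$n_spots * params$spot_spacing_mm / params$motor_speed_mm_s
}
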