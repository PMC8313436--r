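#' Machine delivery dynamics model
#'
#' @param rotation_rpm gantry rotation speed, rotations per minute.
#' @param spot_switch_s dead time between successive spots, seconds.
#' @param layer_switch_s energy-layer switching time, seconds.
#' @param s_per_mu beam-on time per MU, seconds (0 by default: beam-on time
#'   is negligible against the switching overheads at clinical dose rates).
#' @param setup_s setup time between static IMPT fields, seconds.
#' @return an object of class `delivery_model`.
#' @export
delivery_model <- function(rotation_rpm = 1, spot_switch_s = 0.002,
                           layer_switch_s = 0.6, s_per_mu = 0,
                           setup_s = 0) {
  stopifnot(rotation_rpm > 0, spot_switch_s >= 0, layer_switch_s >= 0,
            s_per_mu >= 0, setup_s >= 0)
  structure(list(rotation_rpm = rotation_rpm, spot_switch_s = spot_switch_s,
                 layer_switch_s = layer_switch_s, s_per_mu = s_per_mu,
                 setup_s = setup_s),
            class = "delivery_model")
}

#' Delivery time of one control point
#'
#' `spots x spot switching time + (layers - 1) x layer switching time +
#' MU x beam-on rate`, counting only spots with positive weight.
#'
#' @param spots spot table of a single control point (columns `energy`,
#'   `weight`).
#' @param model a [delivery_model()].
#' @return seconds. An empty control point returns 0 with a warning.
#' @export
beam_delivery_time <- function(spots, model = delivery_model()) {
  live <- spots[spots$weight > 0, , drop = FALSE]
  if (nrow(live) == 0) {
    warning("empty control point: delivery time 0")
    return(0)
  }
  nlay <- length(unique(live$energy))
  nrow(live) * model$spot_switch_s + (nlay - 1) * model$layer_switch_s +
    sum(live$weight) * model$s_per_mu
}

#' Simulate total plan delivery time
#'
#' IMPT plans sum the per-beam delivery times plus inter-field setup times.
#' SPArc plans model a continuously rotating gantry that slows only when
#' spot delivery is the bottleneck: the time for each inter-control-point
#' interval is the maximum of the gantry travel time at the rotation speed
#' and the delivery time of the arriving control point, plus the final coast
#' to the arc stop. The SPArc total is therefore never below
#' span / rotation speed.
#'
#' @param plan a deliverable `proton_plan`.
#' @param model a [delivery_model()].
#' @return list with `total_s` and a per-control-point `breakdown` data
#'   frame (`cp`, `angle`, `travel_s`, `beam_s`, `interval_s`).
#' @export
plan_delivery_time <- function(plan, model = delivery_model()) {
  w <- plan$spots$weight
  if (any(w > 0 & w < plan$min_mu - 1e-12))
    stop("contract violation: plan has nonzero weights below the minimum MU")
  cps <- plan$control_points
  beam_s <- vapply(cps$cp, function(k) {
    sub <- plan$spots[plan$spots$cp == k, , drop = FALSE]
    if (!any(sub$weight > 0)) 0 else beam_delivery_time(sub, model)
  }, 0)
  deg_per_s <- 6 * model$rotation_rpm

  if (plan$mode == "impt") {
    total <- sum(beam_s) + model$setup_s * max(0, nrow(cps) - 1)
    breakdown <- data.frame(cp = cps$cp, angle = cps$angle,
                            travel_s = 0, beam_s = beam_s,
                            interval_s = beam_s)
    return(list(total_s = total, breakdown = breakdown))
  }

  span <- span_degrees(plan$spec$arc_start, plan$spec$arc_stop)
  offs <- angle_offset(cps$angle, plan$spec$arc_start)
  ord <- order(offs)
  offs <- offs[ord]; beam_s <- beam_s[ord]
  travel <- diff(c(0, offs)) / deg_per_s
  tail_s <- (span - offs[length(offs)]) / deg_per_s
  interval <- pmax(travel, beam_s)
  breakdown <- data.frame(cp = cps$cp[ord], angle = cps$angle[ord],
                          travel_s = travel, beam_s = beam_s,
                          interval_s = interval)
  list(total_s = sum(interval) + tail_s, breakdown = breakdown)
}
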