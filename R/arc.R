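# Arc span helpers. A span runs from arc_start to arc_stop in the direction
# of increasing gantry angle, wrapping through 0 (e.g. 160 -> 40 spans 240
# degrees). Control points are parameterized by their offset into the span.

span_degrees <- function(start, stop) {
  s <- (stop - start) %% 360
  if (s == 0) 360 else s
}

angle_offset <- function(angle, start) (angle - start) %% 360

#' Initialize arc control points by coarse sampling
#'
#' Equally spaced control points across the arc span (cell centers), wrapping
#' through 0 degrees for spans like 160 to 40. If the spacing does not divide
#' the span, the effective spacing is widened to the nearest divisor; a span
#' not exceeding the spacing collapses to a single control point with a
#' warning.
#'
#' @param arc_start,arc_stop arc span, degrees (IEC 61217).
#' @param spacing coarse sampling frequency, degrees (default 20).
#' @return data frame with columns `cp`, `angle`, `parent_angle`, `spacing`.
#' @export
init_control_points <- function(arc_start, arc_stop, spacing = 20) {
  span <- span_degrees(arc_start, arc_stop)
  n <- floor(span / spacing + 1e-9)
  if (n <= 1) {
    if (n < 1) warning(sprintf("arc span %g deg below the %g deg sampling: single control point",
                               span, spacing))
    else warning("degenerate arc span: single control point")
    n <- 1L
  }
  eff <- span / n
  offs <- (seq_len(n) - 0.5) * eff
  data.frame(cp = seq_len(n), angle = (arc_start + offs) %% 360,
             parent_angle = NA_real_, spacing = eff)
}

# spots for every control point of a target ROI
build_arc_spots <- function(phantom, roi, model, cps, lateral_spacing = 5,
                            layer_spacing = 0.5, margin = 5) {
  out <- lapply(seq_len(nrow(cps)), function(k) {
    s <- place_spots(phantom, roi, model, cps$angle[k],
                     lateral_spacing, layer_spacing, margin)
    cbind(cp = cps$cp[k], s)
  })
  do.call(rbind, out)
}

# lateral spot lattice for one fixed energy layer at a given angle
place_layer_spots <- function(phantom, roi, model, angle, energy,
                              lateral_spacing, layer_spacing, margin) {
  idx <- which(roi$mask)
  pts <- index_to_world(phantom, idx)
  w <- wepl_raytrace(phantom, angle, pts)
  uv <- bev_coords(pts, angle)
  r <- proton_range(model, energy)
  sel <- abs(w - r) <= layer_spacing
  if (!any(sel)) sel <- abs(w - r) <= min(abs(w - r)) + layer_spacing / 2
  nodes <- lattice_nodes(uv[sel, , drop = FALSE], lateral_spacing,
                         max(0L, round(margin / lateral_spacing)))
  data.frame(angle = angle, energy = energy, u = nodes[, 1], v = nodes[, 2],
             weight = 0)
}

#' Reduce the energy layers of one control point
#'
#' Retains the `k` layers with the greatest summed spot weight, ties broken
#' toward the lower energy; the remaining layers are removed (their weights
#' are zeroed out of the plan before the next optimization round).
#' `k` at or above the layer count is the identity.
#'
#' @param spots spot table of a single control point.
#' @param k number of layers to keep (`>= 1`).
#' @return the spot table restricted to the retained layers.
#' @export
reduce_layers <- function(spots, k) {
  stopifnot(k >= 1)
  en <- sort(unique(spots$energy))
  tot <- vapply(en, function(e) sum(spots$weight[spots$energy == e]), 0)
  ord <- order(-tot, en)
  keep <- en[ord][seq_len(min(k, length(en)))]
  spots[spots$energy %in% keep, , drop = FALSE]
}

#' Double the arc sampling frequency, redistributing energy layers
#'
#' Every control point splits into two children at plus/minus a quarter of
#' the current spacing. The parent's energy layers, sorted by summed spot
#' weight, are dealt alternately to the two children (strongest first, to
#' the earlier child) so the partition is disjoint and exhaustive; a child
#' that would end up empty receives a zero-weight copy of the parent's
#' strongest layer. Each child layer's lateral spots are re-placed for the
#' child angle and the parent layer's total MU is carried over (spread
#' equally), so total plan MU is conserved by the redistribution.
#'
#' @param cps control-point table (with current `spacing`).
#' @param spots weighted spot table.
#' @param phantom,roi,model geometry for re-placing the children's spots.
#' @param lateral_spacing,layer_spacing,margin spot placement parameters.
#' @param arc_start arc start angle (offset reference).
#' @return list with the refined `cps` and `spots`.
#' @export
refine_and_reduce <- function(cps, spots, phantom, roi, model,
                              lateral_spacing = 5, layer_spacing = 0.5,
                              margin = 5, arc_start = 0) {
  s <- cps$spacing[1]
  kids <- list()
  for (k in seq_len(nrow(cps))) {
    a <- cps$angle[k]
    child_angles <- (a + c(-s / 4, s / 4)) %% 360
    csp <- spots[spots$cp == cps$cp[k], , drop = FALSE]
    en <- sort(unique(csp$energy))
    tot <- vapply(en, function(e) sum(csp$weight[csp$energy == e]), 0)
    ord <- order(-tot, en)
    idx1 <- ord[seq_along(ord) %% 2 == 1]
    idx2 <- ord[seq_along(ord) %% 2 == 0]
    dup2 <- FALSE
    if (!length(idx2)) {               # single-layer parent: duplicate
      idx2 <- ord[1]
      dup2 <- TRUE
      message(sprintf("control point at %g deg: child received a zero-weight copy of the strongest layer", a))
    }
    for (side in 1:2) {
      iis <- if (side == 1) idx1 else idx2
      for (ii in iis) {
        ls <- place_layer_spots(phantom, roi, model, child_angles[side],
                                en[ii], lateral_spacing, layer_spacing, margin)
        wtot <- if (side == 2 && dup2) 0 else tot[ii]
        ls$weight <- wtot / nrow(ls)
        ls$.offset <- angle_offset(child_angles[side], arc_start)
        kids[[length(kids) + 1L]] <- ls
      }
    }
  }
  allsp <- do.call(rbind, kids)
  offs <- sort(unique(allsp$.offset))
  new_cps <- data.frame(cp = seq_along(offs),
                        angle = (arc_start + offs) %% 360,
                        parent_angle = NA_real_, spacing = s / 2)
  # recover provenance: nearest parent angle
  po <- angle_offset(cps$angle, arc_start)
  new_cps$parent_angle <- cps$angle[vapply(offs, function(o)
    which.min(pmin(abs(po - o), 360 - abs(po - o))), 1L)]
  allsp$cp <- match(allsp$.offset, offs)
  allsp$.offset <- NULL
  ord <- order(allsp$cp, -allsp$energy, allsp$u, allsp$v)
  list(cps = new_cps, spots = allsp[ord, , drop = FALSE])
}

finalize_plan <- function(mode, cps, spots, weights, spec, objectives, model,
                          inf, min_mu, schedule = NULL) {
  spots$weight <- weights
  ord <- order(spots$cp, -spots$energy, spots$u, spots$v)
  spots <- spots[ord, , drop = FALSE]
  inf <- subset_spots(inf, ord)
  inf$spots <- spots
  structure(list(mode = mode, control_points = cps, spots = spots,
                 spec = spec, objectives = objectives, model = model,
                 influence = inf, min_mu = min_mu, schedule = schedule),
            class = "proton_plan")
}

#' @export
print.proton_plan <- function(x, ...) {
  live <- x$spots$weight > 0
  cat(sprintf("<proton_plan> %s: %d control points, %d/%d active spots, %.1f MU total\n",
              toupper(x$mode), nrow(x$control_points), sum(live),
              nrow(x$spots), sum(x$spots$weight)))
  invisible(x)
}

default_scoring <- function(rois, include_body = FALSE) {
  keep <- if (include_body) rois else rois[names(rois) != "body"]
  Reduce(`|`, lapply(keep, `[[`, "mask"))
}

#' Generate an LET_d-optimized SPArc plan
#'
#' The six-step arc workflow: (1) arc span from the scenario, (2) coarse
#' control-point sampling, (3) influence computation, (4) joint dose +
#' LET_d optimization, (5) iterative sampling refinement with energy-layer
#' redistribution, repeating (3)-(4) with warm-started weights until the
#' final sampling frequency is reached, then layer reduction, and (6)
#' deliverable optimization at the minimum MU. Fully deterministic.
#'
#' @param phantom a `voxel_phantom`.
#' @param rois named list of `roi_mask` (must contain the target).
#' @param spec a [scenario_spec()] (arc span and prescription).
#' @param objectives an [objective_set()]; defaults to
#'   [default_objectives()].
#' @param model a [beam_model()].
#' @param schedule control-point sampling schedule, degrees; each step
#'   halves the previous (default 20, 10, 5, 2.5).
#' @param keep_layers energy layers retained per control point after final
#'   sequencing (default 1).
#' @param target name of the target ROI driving spot placement.
#' @param min_mu minimum deliverable MU per spot.
#' @param lateral_spacing,layer_spacing,margin spot placement parameters.
#' @param cutoff influence sparsification threshold.
#' @param scoring optional scoring mask (default: union of the ROIs).
#' @param max_iter optimizer iteration cap for the final round and the
#'   deliverable re-optimization.
#' @param refine_iter iteration cap for the warm-started intermediate
#'   refinement rounds (their solutions are only re-refined, so they need
#'   not be fully converged).
#' @return a `proton_plan` (mode `"sparc"`) carrying the final influence.
#' @export
plan_sparc <- function(phantom, rois, spec, objectives = NULL,
                       model = beam_model(), schedule = c(20, 10, 5, 2.5),
                       keep_layers = 1, target = "ctv", min_mu = 0.02,
                       lateral_spacing = 5, layer_spacing = 0.5, margin = 5,
                       cutoff = 1e-4, scoring = NULL, max_iter = 200,
                       refine_iter = 60) {
  stopifnot(length(schedule) >= 1, all(diff(schedule) < 0))
  for (k in seq_len(length(schedule) - 1))
    if (abs(schedule[k + 1] - schedule[k] / 2) > 1e-9)
      stop("sequencing error: the sampling schedule must halve at each step")
  if (is.null(objectives)) objectives <- default_objectives(spec, rois)
  if (is.null(scoring)) scoring <- default_scoring(rois)
  troi <- rois[[target]]
  if (is.null(troi)) stop(sprintf("configuration error: unknown target ROI '%s'", target))

  cps <- init_control_points(spec$arc_start, spec$arc_stop, schedule[1])
  spots <- build_arc_spots(phantom, troi, model, cps,
                           lateral_spacing, layer_spacing, margin)
  inf <- compute_influence(phantom, spots, model, scoring, cutoff)
  fit <- solve_weights(inf, objectives, rois, max_iter = refine_iter)
  w <- fit$weights
  trace <- list(fit$report)

  for (k in seq_len(length(schedule) - 1)) {
    spots$weight <- w
    ref <- refine_and_reduce(cps, spots, phantom, troi, model,
                             lateral_spacing, layer_spacing, margin,
                             arc_start = spec$arc_start)
    cps <- ref$cps
    spots <- ref$spots
    inf <- compute_influence(phantom, spots, model, scoring, cutoff)
    fit <- solve_weights(inf, objectives, rois, init = spots$weight,
                         max_iter = refine_iter)
    w <- fit$weights
    trace[[length(trace) + 1L]] <- fit$report
  }

  # energy-layer reduction to the deliverable layer count, then re-optimize
  spots$weight <- w
  kept <- unlist(lapply(split(seq_len(nrow(spots)), spots$cp), function(ii) {
    sub <- spots[ii, , drop = FALSE]
    ii[sub$energy %in% reduce_layers(sub, keep_layers)$energy]
  }), use.names = FALSE)
  kept <- sort(kept)
  spots <- spots[kept, , drop = FALSE]
  inf <- subset_spots(inf, kept)
  fit <- solve_weights(inf, objectives, rois, init = spots$weight,
                       max_iter = max_iter)
  trace[[length(trace) + 1L]] <- fit$report

  post <- deliverable_postprocess(fit$weights, inf, objectives, rois,
                                  min_mu = min_mu, max_iter = max_iter)
  plan <- finalize_plan("sparc", cps, spots, post$weights, spec, objectives,
                        model, inf, min_mu, schedule)
  plan$optimizer_trace <- trace
  plan$deliverable_report <- post$report
  plan
}

#' Generate a multi-beam IMPT plan
#'
#' One control point per beam with an unrestricted layer set, jointly
#' optimized and made deliverable. The LET-free variant (`let_opt = FALSE`)
#' runs the same path with every LET_d penalty zeroed, so both variants
#' share an identical spot set and differ only in weights.
#'
#' @param phantom,rois,spec,objectives,model,target,min_mu as in
#'   [plan_sparc()].
#' @param angles 1 to 8 gantry angles, degrees.
#' @param let_opt include the LET_d objective terms?
#' @param lateral_spacing,layer_spacing,margin,cutoff,scoring,max_iter as in
#'   [plan_sparc()].
#' @return a `proton_plan` (mode `"impt"`).
#' @export
plan_impt <- function(phantom, rois, spec, angles, objectives = NULL,
                      model = beam_model(), let_opt = TRUE, target = "ctv",
                      min_mu = 0.02, lateral_spacing = 5, layer_spacing = 0.5,
                      margin = 5, cutoff = 1e-4, scoring = NULL,
                      max_iter = 200) {
  stopifnot(length(angles) >= 1, length(angles) <= 8)
  if (is.null(objectives)) objectives <- default_objectives(spec, rois)
  if (!let_opt) objectives <- scale_let_penalties(objectives, 0)
  if (is.null(scoring)) scoring <- default_scoring(rois)
  troi <- rois[[target]]
  if (is.null(troi)) stop(sprintf("configuration error: unknown target ROI '%s'", target))

  cps <- data.frame(cp = seq_along(angles), angle = angles %% 360,
                    parent_angle = NA_real_, spacing = NA_real_)
  spots <- build_arc_spots(phantom, troi, model, cps,
                           lateral_spacing, layer_spacing, margin)
  inf <- compute_influence(phantom, spots, model, scoring, cutoff)
  fit <- solve_weights(inf, objectives, rois, max_iter = max_iter)
  post <- deliverable_postprocess(fit$weights, inf, objectives, rois,
                                  min_mu = min_mu, max_iter = max_iter)
  plan <- finalize_plan("impt", cps, spots, post$weights, spec, objectives,
                        model, inf, min_mu)
  plan$optimizer_trace <- list(fit$report)
  plan$deliverable_report <- post$report
  plan
}

#' Serialize a plan to JSON
#'
#' Writes mode, control points, spots (angle, energy, lateral position, MU),
#' prescription and machine metadata. Round-trips losslessly through
#' [read_plan()] (the influence matrix is not serialized and is recomputed
#' on demand).
#'
#' @param plan a `proton_plan`.
#' @param path output file path.
#' @export
plan_to_json <- function(plan, path) {
  machine <- plan$model[setdiff(names(plan$model), c("cache", "zgrid"))]
  payload <- list(
    mode = plan$mode,
    control_points = plan$control_points,
    spots = plan$spots,
    scenario = unclass(plan$spec)[c("id", "spacing", "arc_start", "arc_stop",
                                    "rx_gy", "fractions")],
    min_mu = plan$min_mu,
    schedule = plan$schedule,
    machine = machine)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized plan
#'
#' @param path JSON file written by [plan_to_json()].
#' @return a `proton_plan` without an attached influence matrix.
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- scenario_spec(p$scenario$id, p$scenario$spacing,
                        p$scenario$arc_start, p$scenario$arc_stop,
                        p$scenario$rx_gy, p$scenario$fractions)
  model <- do.call(beam_model, p$machine[setdiff(names(p$machine),
                                                 c("energy_span"))])
  structure(list(mode = p$mode, control_points = p$control_points,
                 spots = p$spots, spec = spec, objectives = NULL,
                 model = model, influence = NULL, min_mu = p$min_mu,
                 schedule = p$schedule),
            class = "proton_plan")
}
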