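# Gantry geometry, IEC 61217: 0 degrees enters anteriorly (+y side of the
# phantom), angles increase clockwise viewed from the couch foot. The couch
# axis is z; beams are parallel (no divergence) in the axial plane.

#' Beam travel direction for a gantry angle
#'
#' @param angle gantry angle, degrees (IEC 61217).
#' @return unit length-3 vector (mm world axes).
#' @export
beam_direction <- function(angle) {
  a <- angle * pi / 180
  c(-sin(a), -cos(a), 0)
}

# beam's-eye-view lateral axes: u in the axial plane, v along the couch axis
bev_axes <- function(angle) {
  a <- angle * pi / 180
  list(u = c(cos(a), -sin(a), 0), v = c(0, 0, 1))
}

#' Water-equivalent path length by exact voxel traversal
#'
#' Line integral of relative stopping power from the phantom boundary to each
#' query point along the beam direction of the given gantry angle, using an
#' exact voxel-traversal (Amanatides-Woo) algorithm.
#'
#' @param phantom a `voxel_phantom`.
#' @param angle gantry angle, degrees.
#' @param points n x 3 matrix of world coordinates (mm), inside the grid.
#' @return numeric vector of WEPL values, cm of water. Points whose ray
#'   misses the grid return 0 with a warning.
#' @export
wepl_raytrace <- function(phantom, angle, points) {
  points <- rbind(points)
  lo <- phantom$origin - phantom$spacing / 2
  hi <- phantom$origin + (phantom$shape - 0.5) * phantom$spacing
  outside <- points[, 1] < lo[1] | points[, 1] > hi[1] |
    points[, 2] < lo[2] | points[, 2] > hi[2] |
    points[, 3] < lo[3] | points[, 3] > hi[3]
  if (any(outside))
    warning(sprintf("%d point(s) outside the grid: WEPL set to 0", sum(outside)))
  w <- cpp_wepl(phantom$density, as.integer(phantom$shape), phantom$spacing,
                phantom$origin, points, beam_direction(angle))
  w[outside] <- 0
  w
}

# BEV (u, v) coordinates of world points for a gantry angle
bev_coords <- function(points, angle) {
  ax <- bev_axes(angle)
  cbind(u = as.numeric(points %*% ax$u), v = as.numeric(points %*% ax$v))
}

# snap-to-lattice helper: lattice nodes at integer multiples of `spacing`
lattice_nodes <- function(uv, spacing, dilate_steps) {
  iu <- round(uv[, 1] / spacing)
  iv <- round(uv[, 2] / spacing)
  nodes <- unique(data.frame(iu = iu, iv = iv))
  if (dilate_steps > 0) {
    offs <- expand.grid(du = -dilate_steps:dilate_steps,
                        dv = -dilate_steps:dilate_steps)
    nodes <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(q)
      data.frame(iu = nodes$iu + offs$du[q], iv = nodes$iv + offs$dv[q]))))
  }
  nodes <- nodes[order(nodes$iu, nodes$iv), , drop = FALSE]
  cbind(u = nodes$iu * spacing, v = nodes$iv * spacing)
}

#' Place energy layers and spots for one beam direction
#'
#' Energies are chosen so that layer ranges cover the target's WEPL span
#' along the beam at the requested layer spacing; lateral spot positions are
#' a regular lattice covering the beam's-eye-view projection of each layer's
#' target voxels, expanded by the margin. Layers are returned in descending
#' energy order.
#'
#' @param phantom a `voxel_phantom`.
#' @param roi target `roi_mask` (non-empty).
#' @param model a [beam_model()].
#' @param angle gantry angle, degrees.
#' @param lateral_spacing lateral spot lattice spacing, mm.
#' @param layer_spacing energy-layer spacing, cm WEPL.
#' @param margin lateral expansion of the target projection, mm.
#' @return data frame of spots with columns `angle`, `energy` (MeV), `u`,
#'   `v` (mm, BEV) and `weight` (MU, initialized to 0).
#' @export
place_spots <- function(phantom, roi, model, angle, lateral_spacing = 5,
                        layer_spacing = 0.5, margin = 5) {
  stopifnot(any(roi$mask), lateral_spacing > 0, layer_spacing > 0, margin >= 0)
  idx <- which(roi$mask)
  pts <- index_to_world(phantom, idx)
  w <- wepl_raytrace(phantom, angle, pts)
  uv <- bev_coords(pts, angle)
  wmin <- min(w); wmax <- max(w)
  if (wmax > proton_range(model, model$energy_max))
    stop(sprintf("planning error: target WEPL %.1f cm at gantry %g deg exceeds the machine range",
                 wmax, angle))
  nlay <- max(1L, ceiling((wmax - wmin) / layer_spacing) + 1L)
  ranges <- wmin + (seq_len(nlay) - 1) * layer_spacing
  ranges <- ranges[ranges <= wmax + layer_spacing / 2]
  ranges <- pmax(ranges, proton_range(model, model$energy_min))
  ranges <- sort(unique(round(ranges, 6)), decreasing = TRUE)
  steps <- max(0L, round(margin / lateral_spacing))
  out <- lapply(ranges, function(r) {
    sel <- abs(w - r) <= layer_spacing
    if (!any(sel)) sel <- abs(w - r) <= min(abs(w - r)) + layer_spacing / 2
    nodes <- lattice_nodes(uv[sel, , drop = FALSE], lateral_spacing, steps)
    data.frame(angle = angle, energy = range_to_energy(model, r),
               u = nodes[, 1], v = nodes[, 2], weight = 0)
  })
  do.call(rbind, out)
}

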