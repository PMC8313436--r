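#' Sparse spot-to-voxel influence pair
#'
#' Holds the matched sparse dose matrix `D` (Gy per MU) and LET matrix `L`
#' (keV/um), voxels by spots, with identical sparsity patterns, plus the
#' scoring-voxel index map and the spot table. The elementwise product
#' `M = D * L` (the numerator kernel of the dose-averaged LET quotient) is
#' cached at construction.
#'
#' @param D,L sparse dgCMatrix, voxels x spots; same dimensions and pattern,
#'   all entries `>= 0`.
#' @param voxel_index integer linear indices of the scoring voxels in the
#'   phantom grid.
#' @param spots spot table (one row per column of `D`).
#' @param grid list with `dim` and `spacing` of the parent phantom.
#' @return an object of class `influence_pair`.
#' @export
influence_pair <- function(D, L, voxel_index, spots, grid) {
  stopifnot(all(dim(D) == dim(L)), nrow(D) == length(voxel_index),
            ncol(D) == nrow(spots))
  if (any(D@x < 0) || any(L@x < 0))
    stop("influence entries must be nonnegative")
  structure(list(D = D, L = L, M = D * L, voxel_index = voxel_index,
                 spots = spots, grid = grid),
            class = "influence_pair")
}

#' @export
print.influence_pair <- function(x, ...) {
  cat(sprintf("<influence_pair> %d voxels x %d spots, %d nonzeros (%.1f%% dense)\n",
              nrow(x$D), ncol(x$D), length(x$D@x),
              100 * length(x$D@x) / prod(dim(x$D))))
  invisible(x)
}

#' Assemble the spot-to-voxel dose and LET influence matrices
#'
#' For every spot, the unit-weight (1 MU) dose to each scoring voxel is the
#' pristine depth-dose at the voxel's WEPL times a lateral Gaussian in the
#' beam's-eye view; the matching LET entry is the depth-LET_d value at the
#' same WEPL. Entries below `cutoff` times the column maximum are dropped.
#'
#' @param phantom a `voxel_phantom`.
#' @param spots spot table with columns `cp`, `angle`, `energy`, `u`, `v`
#'   (as produced by [place_spots()] plus a control-point index).
#' @param model a [beam_model()].
#' @param scoring logical array (phantom shape) or integer linear indices
#'   selecting the scoring voxels.
#' @param cutoff relative per-column sparsification threshold in `[0, 1)`.
#' @return an [influence_pair()]. Spots that deposit no dose in the scoring
#'   volume keep an all-zero column (with a warning).
#' @export
compute_influence <- function(phantom, spots, model, scoring, cutoff = 1e-4) {
  stopifnot(nrow(spots) > 0, cutoff >= 0, cutoff < 1)
  voxel_index <- if (is.logical(scoring)) which(scoring) else as.integer(scoring)
  stopifnot(length(voxel_index) > 0)
  pts <- index_to_world(phantom, voxel_index)

  trip <- list()
  for (ang in unique(spots$angle)) {
    rows <- which(spots$angle == ang)
    w <- wepl_raytrace(phantom, ang, pts)
    uv <- bev_coords(pts, ang)
    energies <- sort(unique(spots$energy[rows]))
    tabs <- curve_tables(model, energies)
    cur_idx <- match(spots$energy[rows], energies) - 1L
    tr <- cpp_spot_influence(uv[, 1], uv[, 2], w,
                             spots$u[rows], spots$v[rows], cur_idx,
                             tabs$z, tabs$ddd, tabs$letd,
                             model$sigma0, model$sigma_growth, cutoff, 0L)
    if (length(tr$i)) {
      tr$j <- rows[tr$j]          # map group-local columns to global spots
      trip[[length(trip) + 1L]] <- tr
    }
  }
  i <- unlist(lapply(trip, `[[`, "i"))
  j <- unlist(lapply(trip, `[[`, "j"))
  d <- unlist(lapply(trip, `[[`, "d"))
  l <- unlist(lapply(trip, `[[`, "l"))
  dims <- c(length(voxel_index), nrow(spots))
  D <- Matrix::sparseMatrix(i = i, j = j, x = d, dims = dims)
  L <- Matrix::sparseMatrix(i = i, j = j, x = l, dims = dims)
  empty <- setdiff(seq_len(nrow(spots)), unique(j))
  if (length(empty))
    warning(sprintf("%d spot(s) deposit no dose in the scoring volume", length(empty)))
  influence_pair(methods::as(D, "CsparseMatrix"),
                 methods::as(L, "CsparseMatrix"),
                 voxel_index, spots,
                 list(dim = phantom$shape, spacing = phantom$spacing))
}

# subset an influence pair to a set of spot columns
subset_spots <- function(inf, cols) {
  influence_pair(inf$D[, cols, drop = FALSE], inf$L[, cols, drop = FALSE],
                 inf$voxel_index, inf$spots[cols, , drop = FALSE], inf$grid)
}

check_weights <- function(inf, weights) {
  if (length(weights) != ncol(inf$D))
    stop("contract violation: weight vector length must equal the spot count")
  if (any(weights < 0))
    stop("contract violation: spot weights must be nonnegative")
  invisible(TRUE)
}

#' Accumulate per-voxel dose from spot weights
#'
#' The weighted column sum `D_i = sum_j D_ij w_j`, exact and linear in the
#' weights.
#'
#' @param inf an [influence_pair()].
#' @param weights nonnegative spot weights (MU), one per spot.
#' @return a `value_map` of per-voxel dose in Gy.
#' @export
accumulate_dose <- function(inf, weights) {
  check_weights(inf, weights)
  v <- as.numeric(inf$D %*% weights)
  structure(list(values = v, voxel_index = inf$voxel_index,
                 grid = inf$grid, quantity = "dose"),
            class = "value_map")
}

#' Accumulate per-voxel dose-averaged LET from spot weights
#'
#' `LET_i = sum_j LET_ij D_ij w_j / sum_j D_ij w_j`; voxels receiving no
#' dose are assigned 0 by convention. The result is invariant under uniform
#' scaling of the weights, and each value lies within the span of the
#' contributing per-spot LET entries.
#'
#' @inheritParams accumulate_dose
#' @return a `value_map` of per-voxel LET_d in keV/um.
#' @export
accumulate_letd <- function(inf, weights) {
  check_weights(inf, weights)
  d <- as.numeric(inf$D %*% weights)
  m <- as.numeric(inf$M %*% weights)
  v <- ifelse(d > 0, m / d, 0)
  structure(list(values = v, voxel_index = inf$voxel_index,
                 grid = inf$grid, quantity = "letd"),
            class = "value_map")
}

#' @export
print.value_map <- function(x, ...) {
  unit <- if (x$quantity == "dose") "Gy" else "keV/um"
  cat(sprintf("<value_map> %s over %d voxels: mean %.3g, max %.3g %s\n",
              x$quantity, length(x$values), mean(x$values), max(x$values), unit))
  invisible(x)
}

# values of a map on an ROI (rows resolved through the voxel index map)
map_on_roi <- function(map, roi) {
  rows <- match(which(roi$mask), map$voxel_index)
  if (anyNA(rows))
    stop(sprintf("evaluation error: ROI '%s' has voxels outside the scoring volume",
                 roi$name))
  map$values[rows]
}
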