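#' Voxel phantom
#'
#' A 3-D relative-stopping-power grid (water = 1.0, air ~ 0.001) with voxel
#' spacing in mm and the world position of the first voxel center.
#' Coordinates are 0-based voxel indices; world positions refer to voxel
#' centers; voxel extents are half-open.
#'
#' @param density 3-D numeric array of relative stopping powers (all `>= 0`).
#' @param spacing length-3 numeric, voxel spacing in mm (strictly positive).
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0) center.
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(density, spacing, origin = NULL) {
  stopifnot(is.array(density), length(dim(density)) == 3,
            all(density >= 0), length(spacing) == 3, all(spacing > 0))
  if (is.null(origin)) origin <- -(dim(density) - 1) / 2 * spacing
  stopifnot(length(origin) == 3)
  structure(list(shape = dim(density), spacing = as.numeric(spacing),
                 density = density, origin = as.numeric(origin)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param name ROI name.
#' @param mask 3-D logical array matching the phantom shape.
#' @param kind one of `"target"`, `"oar"`, `"external"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(name, mask, kind = c("target", "oar", "external")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), is.logical(mask), length(dim(mask)) == 3)
  if (kind == "target" && !any(mask))
    stop(sprintf("geometry error: target ROI '%s' is empty", name))
  structure(list(name = name, mask = mask, kind = kind), class = "roi_mask")
}

#' ROI volume in cubic centimeters
#'
#' Voxel count times voxel volume.
#' @param roi a `roi_mask`.
#' @param phantom the `voxel_phantom` the mask lives on.
#' @return volume, cc.
#' @export
roi_volume_cc <- function(roi, phantom) {
  stopifnot(all(dim(roi$mask) == phantom$shape))
  sum(roi$mask) * prod(phantom$spacing) / 1000
}

#' Scenario specification
#'
#' Parameterizes one of three packaged planning scenarios: a prostate-like
#' central target with two adjacent OARs (full arc), a liver-like lateralized
#' target planned with a partial arc from 160 to 40 degrees (IEC 61217), and
#' a brain-like target surrounded by four small OARs (full arc). Gantry
#' angles follow IEC 61217 (0 degrees enters anteriorly, increasing clockwise
#' viewed from the couch foot). Prescriptions are physical-dose values quoted
#' at a constant RBE of 1.1.
#'
#' @param id scenario identifier.
#' @param spacing isotropic voxel spacing in mm (1 to 5).
#' @param arc_start,arc_stop arc span override, degrees in `[0, 360)`.
#' @param rx_gy,fractions prescription override (total Gy and fraction count).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id = c("prostate-like", "liver-like", "brain-like"),
                          spacing = 2, arc_start = NULL, arc_stop = NULL,
                          rx_gy = NULL, fractions = NULL) {
  id <- tryCatch(match.arg(id),
                 error = function(e) stop(sprintf(
                   "configuration error: unknown scenario id '%s'", id[1])))
  stopifnot(length(spacing) == 1, spacing >= 1, spacing <= 5)
  defaults <- switch(id,
    "prostate-like" = list(arc_start = 0, arc_stop = 360, rx_gy = 78, fractions = 39,
      geometry = list(body = c(rx = 110, ry = 85, hz = 45),
                      target = list(center = c(0, 0, 0), radius = 28),
                      oars = list(
                        rectum = list(center = c(0, -44, 0), radius = 12, shape = "zcyl", hz = 40),
                        bladder = list(center = c(0, 52, 0), radius = 18, shape = "sphere")))),
    "liver-like" = list(arc_start = 160, arc_stop = 40, rx_gy = 75, fractions = 25,
      geometry = list(body = c(rx = 130, ry = 95, hz = 45),
                      target = list(center = c(-55, 18, 0), radius = 21),
                      gtv = list(center = c(-55, 18, 0), radius = 14),
                      oars = list(
                        liver = list(center = c(-45, 12, 0), radius = 45, shape = "sphere")))),
    "brain-like" = list(arc_start = 0, arc_stop = 360, rx_gy = 54, fractions = 30,
      geometry = list(body = c(rx = 65, ry = 65, hz = 45),
                      target = list(center = c(0, 12, 0), radius = 15),
                      oars = list(
                        brainstem = list(center = c(0, -22, 0), radius = 8, shape = "sphere"),
                        chiasm = list(center = c(0, -10, 0), radius = 5, shape = "sphere"),
                        optic_nerve_l = list(center = c(14, -8, 0), radius = 4, shape = "sphere"),
                        optic_nerve_r = list(center = c(-14, -8, 0), radius = 4, shape = "sphere")))))
  spec <- list(id = id, spacing = spacing,
               arc_start = if (is.null(arc_start)) defaults$arc_start else arc_start,
               arc_stop = if (is.null(arc_stop)) defaults$arc_stop else arc_stop,
               rx_gy = if (is.null(rx_gy)) defaults$rx_gy else rx_gy,
               fractions = if (is.null(fractions)) defaults$fractions else fractions,
               geometry = defaults$geometry)
  stopifnot(spec$arc_start >= 0, spec$arc_start < 360,
            spec$arc_stop >= 0, spec$arc_stop <= 360, spec$rx_gy > 0,
            spec$fractions >= 1)
  class(spec) <- "scenario_spec"
  spec
}

# world coordinates (n x 3) of a set of linear voxel indices
index_to_world <- function(phantom, idx) {
  sh <- phantom$shape
  idx0 <- idx - 1L
  i <- idx0 %% sh[1]
  j <- (idx0 %/% sh[1]) %% sh[2]
  k <- idx0 %/% (sh[1] * sh[2])
  cbind(phantom$origin[1] + i * phantom$spacing[1],
        phantom$origin[2] + j * phantom$spacing[2],
        phantom$origin[3] + k * phantom$spacing[3])
}

shape_mask <- function(cx, cy, cz, shape_def) {
  ctr <- shape_def$center
  r <- shape_def$radius
  X <- outer(cx - ctr[1], rep(1, length(cy)))
  Y <- outer(rep(1, length(cx)), cy - ctr[2])
  if (identical(shape_def$shape, "zcyl")) {
    inplane <- X^2 + Y^2 <= r^2
    out <- array(FALSE, c(length(cx), length(cy), length(cz)))
    zin <- abs(cz - ctr[3]) <= shape_def$hz
    for (k in which(zin)) out[, , k] <- inplane
    out
  } else {
    out <- array(FALSE, c(length(cx), length(cy), length(cz)))
    for (k in seq_along(cz)) {
      dz2 <- (cz[k] - ctr[3])^2
      out[, , k] <- X^2 + Y^2 + dz2 <= r^2
    }
    out
  }
}

#' Build a scenario phantom and its ROI set
#'
#' Constructs a water-density body (elliptical cylinder, relative stopping
#' power 1.0) surrounded by air, with the scenario's target and OAR shapes
#' embedded, plus a `ring` conformity shell around the target (kind
#' `external`) and the `body` external contour. The liver-like scenario adds
#' a `gtv` target nested inside the CTV; the brain-like scenario carries four
#' small OARs flanking the target. Construction is fully deterministic.
#'
#' @param spec a [scenario_spec()].
#' @return list with elements `phantom` (a `voxel_phantom`) and `rois`
#'   (named list of `roi_mask`).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  g <- spec$geometry
  sp <- spec$spacing
  pad <- 2 * sp
  half <- unname(c(g$body["rx"], g$body["ry"], g$body["hz"])) + pad
  n <- 2 * ceiling(half / sp) + 1
  origin <- -(n - 1) / 2 * sp
  cx <- origin[1] + (seq_len(n[1]) - 1) * sp
  cy <- origin[2] + (seq_len(n[2]) - 1) * sp
  cz <- origin[3] + (seq_len(n[3]) - 1) * sp

  X <- outer(cx / g$body["rx"], rep(1, n[2]))
  Y <- outer(rep(1, n[1]), cy / g$body["ry"])
  body_plane <- X^2 + Y^2 <= 1
  body <- array(FALSE, n)
  for (k in which(abs(cz) <= g$body["hz"])) body[, , k] <- body_plane

  density <- array(0.001, n)
  density[body] <- 1.0
  phantom <- voxel_phantom(density, rep(sp, 3), origin)

  tgt <- shape_mask(cx, cy, cz, c(g$target, shape = "sphere"))
  check_inside <- function(mask, name) {
    if (!all(body[mask]))
      stop(sprintf("geometry error: ROI '%s' extends outside the body", name))
  }
  check_inside(tgt, "ctv")
  rois <- list(ctv = roi_mask("ctv", tgt, "target"))
  if (!is.null(g$gtv)) {
    gm <- shape_mask(cx, cy, cz, c(g$gtv, shape = "sphere"))
    rois$gtv <- roi_mask("gtv", gm, "target")
  }
  for (nm in names(g$oars)) {
    m <- shape_mask(cx, cy, cz, g$oars[[nm]]) & !tgt
    check_inside(m, nm)
    rois[[nm]] <- roi_mask(nm, m, "oar")
  }
  ring <- dilate_mask(tgt, 10, rep(sp, 3)) & !dilate_mask(tgt, 4, rep(sp, 3)) & body
  rois$ring <- roi_mask("ring", ring, "external")
  rois$body <- roi_mask("body", body, "external")
  list(phantom = phantom, rois = rois)
}

# integer voxel offsets inside a metric ball of the given radius (mm)
ball_offsets <- function(radius, spacing) {
  r <- floor(radius / spacing)
  if (any(r < 0)) stop("radius must be >= 0")
  grid <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (grid$dx * spacing[1])^2 + (grid$dy * spacing[2])^2 + (grid$dz * spacing[3])^2
  grid[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(mask, off, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
    else { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# metric morphology on the mm distance ball; exact for any anisotropic grid.
# Large balls switch to an FFT convolution of the indicator with the ball
# kernel (same result up to floating roundoff, thresholded at 1/2).
morph_mask <- function(mask, radius, spacing, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (radius <= 0) return(mask)
  offs <- ball_offsets(radius, spacing)
  if (nrow(offs) <= 400) {
    acc <- mask
    base <- if (op == "erode") mask else mask
    for (q in seq_len(nrow(offs))) {
      o <- as.integer(offs[q, ])
      if (all(o == 0)) next
      sh <- shift_mask(base, o, fill = op == "dilate" && FALSE)
      acc <- if (op == "erode") acc & sh else acc | sh
    }
    return(acc)
  }
  d <- dim(mask)
  r <- floor(radius / spacing)
  nfft <- d + 2 * r
  ind <- array(0, nfft)
  ind[r[1] + 1:d[1], r[2] + 1:d[2], r[3] + 1:d[3]] <-
    if (op == "erode") !mask else mask
  if (op == "erode") {            # outside the grid counts as background
    ind[c(1:r[1], r[1] + d[1] + 1:r[1]), , ] <- 1
    ind[, c(1:r[2], r[2] + d[2] + 1:r[2]), ] <- 1
    ind[, , c(1:r[3], r[3] + d[3] + 1:r[3])] <- 1
  }
  kern <- array(0, nfft)
  ii <- (offs$dx %% nfft[1]) + 1
  jj <- (offs$dy %% nfft[2]) + 1
  kk <- (offs$dz %% nfft[3]) + 1
  for (q in seq_len(nrow(offs))) kern[ii[q], jj[q], kk[q]] <- 1
  conv <- Re(stats::fft(stats::fft(ind) * stats::fft(kern), inverse = TRUE)) /
    prod(nfft)
  hits <- conv[r[1] + 1:d[1], r[2] + 1:d[2], r[3] + 1:d[3]] > 0.5
  if (op == "erode") mask & !hits else hits
}

dilate_mask <- function(mask, radius, spacing) morph_mask(mask, radius, spacing, "dilate")

#' Shrink an ROI by a metric margin
#'
#' Morphological erosion by a ball of the given radius measured in mm on the
#' voxel grid (anisotropic grids erode correctly). A zero margin returns the
#' input unchanged. Eroding to the empty set is legal (it terminates a
#' shrinking series) and raises a warning.
#'
#' @param roi a `roi_mask`.
#' @param margin erosion margin, mm (`>= 0`).
#' @param phantom the `voxel_phantom` providing the grid spacing.
#' @return the eroded `roi_mask` (kind preserved, name suffixed with the
#'   margin).
#' @export
shrink_roi <- function(roi, margin, phantom) {
  stopifnot(inherits(roi, "roi_mask"), margin >= 0)
  if (margin == 0) return(roi)
  m <- morph_mask(roi$mask, margin, phantom$spacing, "erode")
  if (!any(m)) warning(sprintf("ROI '%s' eroded by %g mm is empty", roi$name, margin))
  structure(list(name = sprintf("%s-%gmm", roi$name, margin), mask = m,
                 kind = roi$kind), class = "roi_mask")
}
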