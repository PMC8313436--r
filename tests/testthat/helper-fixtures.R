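# Shared fixtures, built in code and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

test_model <- function() fixture("model", function() beam_model())

# uniform water box, default 5 mm voxels, centered on the origin
water_box <- function(n = c(24, 24, 12), spacing = 5, density = 1) {
  voxel_phantom(array(density, n), rep(spacing, 3))
}

# small spherical target centered in a water box
boxed_sphere <- function(phantom, radius = 15, center = c(0, 0, 0)) {
  idx <- seq_len(prod(phantom$shape))
  pts <- index_to_world_test(phantom, idx)
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2
  roi_mask("target", array(d2 <= radius^2, phantom$shape), "target")
}

index_to_world_test <- function(phantom, idx) {
  sh <- phantom$shape
  idx0 <- idx - 1L
  i <- idx0 %% sh[1]
  j <- (idx0 %/% sh[1]) %% sh[2]
  k <- idx0 %/% (sh[1] * sh[2])
  cbind(phantom$origin[1] + i * phantom$spacing[1],
        phantom$origin[2] + j * phantom$spacing[2],
        phantom$origin[3] + k * phantom$spacing[3])
}

# randomized dense-ish influence pair for oracle tests: L shares D's pattern
random_influence <- function(n_vox = 1000, n_spot = 20, seed = 1,
                             density = 0.3) {
  set.seed(seed)
  nz <- rbinom(n_vox * n_spot, 1, density) == 1
  d <- numeric(n_vox * n_spot)
  d[nz] <- runif(sum(nz), 0.01, 1)
  l <- numeric(n_vox * n_spot)
  l[nz] <- runif(sum(nz), 0.5, 12)
  D <- Matrix::Matrix(matrix(d, n_vox, n_spot), sparse = TRUE)
  L <- Matrix::Matrix(matrix(l, n_vox, n_spot), sparse = TRUE)
  spots <- data.frame(cp = 1L, angle = 0, energy = seq_len(n_spot) + 99,
                      u = 0, v = 0, weight = 0)
  influence_pair(methods::as(D, "CsparseMatrix"),
                 methods::as(L, "CsparseMatrix"),
                 seq_len(n_vox), spots,
                 list(dim = c(n_vox, 1L, 1L), spacing = c(1, 1, 1)))
}

# hand-built influence pair from explicit dense matrices
manual_influence <- function(D, L) {
  D <- rbind(D); L <- rbind(L)
  spots <- data.frame(cp = 1L, angle = 0, energy = seq_len(ncol(D)) + 99,
                      u = 0, v = 0, weight = 0)
  influence_pair(methods::as(Matrix::Matrix(D, sparse = TRUE), "CsparseMatrix"),
                 methods::as(Matrix::Matrix(L, sparse = TRUE), "CsparseMatrix"),
                 seq_len(nrow(D)), spots,
                 list(dim = c(nrow(D), 1L, 1L), spacing = c(1, 1, 1)))
}

# single-ROI wrapper for manual influence instances (all voxels in the ROI)
manual_rois <- function(inf, kind = "target", rows = NULL) {
  n <- nrow(inf$D)
  m <- rep(FALSE, n)
  m[if (is.null(rows)) seq_len(n) else rows] <- TRUE
  list(roi = roi_mask("roi", array(m, c(n, 1, 1)), kind))
}

# scenario fixtures at coarse test resolution
get_scenario <- function(id, spacing = 5) {
  fixture(paste0("scenario_", id, "_", spacing), function() {
    spec <- scenario_spec(id, spacing = spacing)
    c(list(spec = spec), build_phantom(spec))
  })
}

# a small deliverable IMPT plan on the prostate-like scenario (shared)
get_prostate_impt <- function() {
  fixture("prostate_impt", function() {
    sc <- get_scenario("prostate-like")
    plan_impt(sc$phantom, sc$rois, sc$spec, c(90, 270),
              default_objectives(sc$spec, sc$rois), test_model(),
              let_opt = FALSE)
  })
}

# the SPArc plan reused by the experiment-level tests
get_prostate_sparc <- function() {
  fixture("prostate_sparc", function() {
    sc <- get_scenario("prostate-like")
    plan_sparc(sc$phantom, sc$rois, sc$spec,
               default_objectives(sc$spec, sc$rois), test_model())
  })
}

expect_deliverable <- function(weights, min_mu = 0.02) {
  expect_true(all(weights == 0 | weights >= min_mu - 1e-12))
}

span_deg_test <- function(spec) {
  s <- (spec$arc_stop - spec$arc_start) %% 360
  if (s == 0) 360 else s
}

beam_direction_test <- function(angle) {
  a <- angle * pi / 180
  c(-sin(a), -cos(a), 0)
}

# voxelwise definition of metric erosion, as an oracle for the FFT path
erode_brute <- function(mask, radius, spacing) {
  offs <- sparclet:::ball_offsets(radius, spacing)
  out <- mask
  for (q in seq_len(nrow(offs))) {
    o <- as.integer(offs[q, ])
    if (all(o == 0)) next
    out <- out & sparclet:::shift_mask(mask, o)
  }
  out
}

# central finite-difference gradient oracle
fd_gradient <- function(f, w, h = 1e-6) {
  g <- numeric(length(w))
  for (j in seq_along(w)) {
    e <- numeric(length(w)); e[j] <- h * max(1, abs(w[j]))
    g[j] <- (f(w + e) - f(w - e)) / (2 * e[j])
  }
  g
}

# synthetic feather-weight arc plan for delivery-model closed forms
light_sparc_plan <- function(arc_start = 0, arc_stop = 360, spacing = 2.5,
                             weight = 1) {
  cps <- init_control_points(arc_start, arc_stop, spacing)
  spots <- data.frame(cp = cps$cp, angle = cps$angle, energy = 100,
                      u = 0, v = 0, weight = weight)
  structure(list(mode = "sparc", control_points = cps, spots = spots,
                 spec = list(arc_start = arc_start, arc_stop = arc_stop),
                 min_mu = 0.02),
            class = "proton_plan")
}

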