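test_that("range-energy fit reproduces published proton ranges", {
  m <- test_model()
  # 160 MeV protons stop near 17.5 cm in water
  expect_lt(abs(proton_range(m, 160) - 17.5) / 17.5, 0.02)
  # strictly increasing with energy, and the inverse round-trips
  e <- seq(m$energy_min, m$energy_max, by = 5)
  r <- proton_range(m, e)
  expect_true(all(diff(r) > 0))
  expect_equal(range_to_energy(m, r), e, tolerance = 1e-10)
})

test_that("Bragg curve has the required pristine-peak shape", {
  m <- test_model()
  for (e in c(100, 160, 200)) {
    R <- proton_range(m, e)
    z <- seq(0, R + 3, by = 0.01)
    d <- depth_dose(m, e, z)
    expect_true(all(is.finite(d)) && all(d >= 0))
    # single peak near the predicted range (within one falloff width)
    zpk <- z[which.max(d)]
    expect_lt(abs(zpk - R), 0.5)
    # peak-to-entrance ratio
    expect_gt(max(d) / d[2], 2)
    # near-zero beyond the distal falloff
    expect_lt(depth_dose(m, e, R + 2) / max(d), 0.001)
  }
  expect_error(depth_dose(m, 500, 1), "physics-model")
  expect_error(depth_dose(m, 10, 1), "physics-model")
})

test_that("depth-LET_d curve rises from tabulated entrance values to the falloff", {
  m <- test_model()
  # published stopping power of 160 MeV protons in water: ~5.2 MeV cm2/g
  expect_lt(abs(depth_let(m, 160, 0.05) - 0.52) / 0.52, 0.1)
  R <- proton_range(m, 160)
  z <- seq(0, R + 1, by = 0.02)
  l <- depth_let(m, 160, z)
  d <- depth_dose(m, 160, z)
  expect_true(all(diff(l) > -1e-9))              # monotone non-decreasing
  expect_true(all(l[d > 0] > 0))
  # LET at distal falloff > LET at the dose peak > entrance LET
  ipk <- which.max(d)
  idist <- which(d < 0.2 * max(d) & z > z[ipk])[1]
  expect_gt(l[idist], l[ipk])
  expect_gt(l[ipk], l[1])
  # depth of maximal LET_d at or beyond depth of maximal dose
  expect_gte(z[which.max(l)], z[ipk])
})

test_that("energy-stacked SOBP is flat with mid-plateau LET_d in the physical band", {
  s <- build_sobp(test_model(), distal_range = 16, modulation = 6)
  expect_lt(s$flatness, 0.03)
  expect_gte(s$mid_letd, 2)
  expect_lte(s$mid_letd, 3)
  # weights of the deeper layers dominate (classic SOBP weighting)
  expect_gt(s$weights[length(s$weights)], max(s$weights[1:3]))
})

test_that("WEPL traversal equals geometric depth in water and scales with density", {
  ph <- water_box(c(30, 30, 10), spacing = 4)
  pts <- rbind(c(0, 0, 0), c(10, -14, 4), c(-22, 30, -8))
  for (ang in c(0, 90, 215)) {
    w <- wepl_raytrace(ph, ang, pts)
    # geometric path from the entry face, in cm
    d <- beam_direction_test(ang)
    lo <- ph$origin - ph$spacing / 2
    hi <- ph$origin + (ph$shape - 0.5) * ph$spacing
    geo <- apply(pts, 1, function(p) {
      tt <- c((lo - p) / -d, (hi - p) / -d)
      tt <- tt[is.finite(tt) & tt > 0]
      min(tt) / 10
    })
    expect_equal(w, geo, tolerance = 0.05)
  }
  half <- water_box(c(30, 30, 10), spacing = 4, density = 0.5)
  expect_equal(wepl_raytrace(half, 45, pts),
               wepl_raytrace(ph, 45, pts) / 2, tolerance = 1e-12)
})

test_that("exact traversal matches a dense sampled line integral within 1%", {
  set.seed(7)
  n <- c(19, 17, 9)
  dens <- array(runif(prod(n), 0.2, 1.5), n)
  ph <- voxel_phantom(dens, c(3, 4, 5))
  pts <- rbind(c(1, 2, 0), c(-8, 10, 3), c(12, -6, -4))
  for (ang in c(33, 127, 301)) {
    w <- wepl_raytrace(ph, ang, pts)
    d <- beam_direction_test(ang)
    step <- 0.02
    brute <- apply(pts, 1, function(p) {
      acc <- 0
      for (t in seq(step / 2, 500, by = step)) {
        q <- p - t * d
        ijk <- floor((q - ph$origin) / ph$spacing + 0.5)
        if (any(ijk < 0) || any(ijk >= n)) break
        acc <- acc + dens[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] * step
      }
      acc / 10
    })
    expect_equal(w, brute, tolerance = 0.01)
  }
  expect_warning(wepl_raytrace(ph, 0, rbind(c(500, 0, 0))), "outside")
})

test_that("spot placement covers the target WEPL span and BEV projection", {
  ph <- water_box(c(24, 24, 14), spacing = 5)
  roi <- boxed_sphere(ph, radius = 15)
  m <- test_model()
  sp <- place_spots(ph, roi, m, angle = 0, lateral_spacing = 5,
                    layer_spacing = 0.5, margin = 5)
  idx <- which(roi$mask)
  w <- wepl_raytrace(ph, 0, index_to_world_test(ph, idx))
  nlay <- length(unique(sp$energy))
  expect_equal(nlay, ceiling((max(w) - min(w)) / 0.5) + 1, tolerance = 1)
  # energies sorted descending and unique per control point
  expect_true(all(diff(unique(sp$energy)) < 0))
  # margin monotonicity
  sp0 <- place_spots(ph, roi, m, 0, 5, 0.5, margin = 0)
  expect_gt(nrow(sp), nrow(sp0))
  # every target voxel gets dose from the unit-weight spot set
  spots <- cbind(cp = 1L, sp)
  inf <- compute_influence(ph, spots, m, roi$mask, cutoff = 1e-4)
  dmap <- accumulate_dose(inf, rep(1, nrow(spots)))
  expect_true(all(dmap$values > 0))
  # an over-deep target errors with the offending angle
  deep <- water_box(c(44, 24, 14), spacing = 5)
  roi_deep <- boxed_sphere(deep, radius = 12, center = c(0, 0, 0))
  shallow_model <- beam_model(energy_min = 70, energy_max = 100)
  expect_error(place_spots(deep, roi_deep, shallow_model, 90),
               "planning error.*90")
})
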