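test_that("coarse control-point sampling covers full and partial arcs", {
  full <- init_control_points(0, 360, 20)
  expect_equal(nrow(full), 18)
  expect_true(all(diff(full$angle) == 20))

  partial <- init_control_points(160, 40, 20)
  expect_equal(nrow(partial), 12)
  offs <- (partial$angle - 160) %% 360
  expect_true(all(offs >= 0 & offs <= 240))
  expect_true(all(diff(offs) == 20))

  expect_warning(one <- init_control_points(10, 30, 20), "single control point")
  expect_equal(nrow(one), 1)
})

test_that("layer reduction keeps the heaviest layers with low-energy tie-break", {
  spots <- data.frame(cp = 1L, angle = 0,
                      energy = rep(c(100, 120, 140), each = 2),
                      u = 0, v = 0,
                      weight = c(2.5, 2.5, 1.5, 1.5, 0.05, 0.05))
  # k >= layer count: identity
  expect_identical(reduce_layers(spots, 5), spots)
  # {5, 3, 0.1} summed weights, k = 2: the 0.1 layer goes
  red <- reduce_layers(spots, 2)
  expect_setequal(unique(red$energy), c(100, 120))
  # equal-weight tie at the boundary: the lower energy is retained
  tie <- data.frame(cp = 1L, angle = 0, energy = c(100, 140),
                    u = 0, v = 0, weight = c(1, 1))
  expect_equal(unique(reduce_layers(tie, 1)$energy), 100)
})

test_that("refinement doubles sampling, partitions layers, conserves MU", {
  sc <- get_scenario("brain-like")
  m <- test_model()
  cps <- init_control_points(0, 360, 40)
  spots <- sparclet:::build_arc_spots(sc$phantom, sc$rois$ctv, m, cps)
  set.seed(3)
  spots$weight <- runif(nrow(spots), 0, 2)

  ref <- refine_and_reduce(cps, spots, sc$phantom, sc$rois$ctv, m,
                           arc_start = 0)
  expect_equal(nrow(ref$cps), 2 * nrow(cps))
  expect_equal(ref$cps$spacing[1], 20)
  # children's energies partition the parent's (disjoint, exhaustive)
  for (k in cps$cp) {
    parent_en <- sort(unique(spots$energy[spots$cp == k]))
    kids <- which(ref$cps$parent_angle == cps$angle[k])
    kid_en <- lapply(kids, function(j)
      unique(ref$spots$energy[ref$spots$cp == ref$cps$cp[j]]))
    expect_setequal(unlist(kid_en), parent_en)
    if (length(parent_en) > 1)
      expect_length(intersect(kid_en[[1]], kid_en[[2]]), 0)
  }
  # total MU conserved by the redistribution
  expect_equal(sum(ref$spots$weight), sum(spots$weight), tolerance = 1e-9)
  # every refined control point stays inside the span
  expect_true(all((ref$cps$angle - 0) %% 360 < 360))

  # single-layer parents duplicate their strongest layer to the empty child
  one_layer <- spots[spots$cp == 1 &
                       spots$energy == max(spots$energy[spots$cp == 1]), ]
  expect_message(
    ref1 <- refine_and_reduce(cps[1, ], one_layer, sc$phantom, sc$rois$ctv,
                              m, arc_start = 0),
    "zero-weight copy")
  expect_equal(sum(ref1$spots$weight), sum(one_layer$weight), tolerance = 1e-9)
})

test_that("partial-arc refinement keeps every control point inside the span", {
  cps <- init_control_points(160, 40, 20)
  sc <- get_scenario("brain-like")
  m <- test_model()
  spots <- sparclet:::build_arc_spots(sc$phantom, sc$rois$ctv, m, cps[1:3, ])
  spots$weight <- 1
  ref <- refine_and_reduce(cps[1:3, ], spots, sc$phantom, sc$rois$ctv, m,
                           arc_start = 160)
  offs <- (ref$cps$angle - 160) %% 360
  expect_true(all(offs >= 0 & offs <= 240))
  expect_equal(nrow(ref$cps), 6)
})

test_that("IMPT planning is deterministic and shares spots across LET variants", {
  sc <- get_scenario("brain-like")
  obj <- default_objectives(sc$spec, sc$rois)
  m <- test_model()
  p1 <- plan_impt(sc$phantom, sc$rois, sc$spec, c(0, 120, 240), obj, m,
                  let_opt = FALSE)
  p2 <- plan_impt(sc$phantom, sc$rois, sc$spec, c(0, 120, 240), obj, m,
                  let_opt = FALSE)
  expect_identical(p1$spots, p2$spots)           # byte-identical reruns
  p3 <- plan_impt(sc$phantom, sc$rois, sc$spec, c(0, 120, 240), obj, m,
                  let_opt = TRUE)
  # identical spot geometry, only weights may differ
  expect_identical(p1$spots[, c("cp", "angle", "energy", "u", "v")],
                   p3$spots[, c("cp", "angle", "energy", "u", "v")])
  expect_equal(nrow(p1$control_points), 3)
  # deliverable invariant
  expect_deliverable(p1$spots$weight, p1$min_mu)
  expect_deliverable(p3$spots$weight, p3$min_mu)
  # two opposed beams on the symmetric brain phantom give symmetric doses
  psym <- plan_impt(sc$phantom, sc$rois, sc$spec, c(90, 270), obj, m,
                    let_opt = FALSE)
  d <- accumulate_dose(psym$influence, psym$spots$weight)
  ctv <- sparclet:::map_on_roi(d, sc$rois$ctv)
  pts <- index_to_world_test(sc$phantom, which(sc$rois$ctv$mask))
  mirrored <- match(paste(-pts[, 1], pts[, 2], pts[, 3]),
                    paste(pts[, 1], pts[, 2], pts[, 3]))
  ok <- !is.na(mirrored)
  expect_lt(max(abs(ctv[ok] - ctv[mirrored[ok]])) / max(ctv), 0.05)
})

test_that("plans serialize to JSON and round-trip", {
  p <- get_prostate_impt()
  path <- tempfile(fileext = ".json")
  plan_to_json(p, path)
  q <- read_plan(path)
  expect_equal(q$mode, p$mode)
  expect_equal(q$spots$weight, p$spots$weight, tolerance = 1e-12)
  expect_equal(q$spots$energy, p$spots$energy, tolerance = 1e-12)
  expect_equal(q$control_points$angle, p$control_points$angle)
  expect_equal(q$spec$rx_gy, p$spec$rx_gy)
  unlink(path)
})
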