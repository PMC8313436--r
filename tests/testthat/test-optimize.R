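test_that("objective value reproduces hand arithmetic and Heaviside gating", {
  # one voxel, one spot, D_ij = 1 Gy/MU, uniform goal 2 Gy, p = 1, w = 1
  inf <- manual_influence(D = matrix(1), L = matrix(3))
  rois <- manual_rois(inf)
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1))
  expect_equal(objective_value(1, obj, inf, rois), (1 - 2)^2)
  # exactly at goal: zero objective
  expect_equal(objective_value(2, obj, inf, rois), 0)
  # OAR voxel below its dose bound contributes exactly zero
  inf2 <- manual_influence(D = matrix(1), L = matrix(3))
  rois2 <- manual_rois(inf2, kind = "oar")
  obj2 <- objective_set(objective_term("roi", "dose", "max", 5, 7))
  expect_equal(objective_value(2, obj2, inf2, rois2), 0)
  expect_equal(objective_value(6, obj2, inf2, rois2), 7 * (6 - 5)^2)
  # target-LET undershoot gating: above the goal contributes zero
  obj3 <- objective_set(objective_term("roi", "letd", "min", 2.5, 1))
  expect_equal(objective_value(1, obj3, inf, rois), (3 - 2.5)^2 * 0)
  obj4 <- objective_set(objective_term("roi", "letd", "min", 4, 1))
  expect_equal(objective_value(1, obj4, inf, rois), (3 - 4)^2)
  # uniform sense is rejected on non-target ROIs; unknown ROI is an error
  expect_error(objective_value(1, objective_set(
    objective_term("roi", "dose", "uniform", 2, 1)), inf2, rois2),
    "configuration error")
  expect_error(objective_value(1, objective_set(
    objective_term("missing", "dose", "max", 2, 1)), inf, rois),
    "unknown ROI")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(42)
  inf <- random_influence(120, 12, seed = 3)
  rois <- list(
    tgt = roi_mask("tgt", array(seq_len(120) <= 60, c(120, 1, 1)), "target"),
    oar = roi_mask("oar", array(seq_len(120) > 60, c(120, 1, 1)), "oar"))
  obj_dose <- objective_set(
    objective_term("tgt", "dose", "uniform", 2, 1),
    objective_term("oar", "dose", "max", 0.8, 0.5))
  obj_full <- objective_set(
    objective_term("tgt", "dose", "uniform", 2, 1),
    objective_term("oar", "dose", "max", 0.8, 0.5),
    objective_term("tgt", "letd", "min", 9, 0.02),
    objective_term("oar", "letd", "max", 2, 0.02))
  for (obj in list(obj_dose, obj_full)) {
    for (rep in 1:20) {
      w <- runif(12, 0.05, 2)
      g <- objective_gradient(w, obj, inf, rois)
      fd <- fd_gradient(function(x) objective_value(x, obj, inf, rois), w)
      denom <- max(abs(fd), 1)
      expect_lt(max(abs(g - fd)) / denom, 1e-6)
    }
  }
})

test_that("LET-only objective is flat along the uniform scaling direction", {
  inf <- random_influence(100, 10, seed = 11)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "letd", "min", 9, 1))
  set.seed(11)
  for (rep in 1:5) {
    w <- runif(10, 0.2, 2)
    g <- objective_gradient(w, obj, inf, rois)
    # directional derivative along w vanishes (homogeneity of the LET quotient)
    expect_lt(abs(sum(g * w)) / max(sum(abs(g * w)), 1e-8), 1e-8)
  }
  # a zero-penalty term contributes no gradient
  obj0 <- objective_set(objective_term("roi", "letd", "min", 9, 0),
                        objective_term("roi", "dose", "uniform", 1, 1))
  objd <- objective_set(objective_term("roi", "dose", "uniform", 1, 1))
  w <- runif(10, 0.2, 2)
  expect_identical(objective_gradient(w, obj0, inf, rois),
                   objective_gradient(w, objd, inf, rois))
})

test_that("objective is invariant to spot reordering", {
  inf <- random_influence(80, 8, seed = 13)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1),
                       objective_term("roi", "letd", "min", 8, 0.05))
  set.seed(13)
  w <- runif(8, 0.1, 2)
  perm <- sample(8)
  inf_p <- sparclet:::subset_spots(inf, perm)
  expect_equal(objective_value(w[perm], obj, inf_p, rois),
               objective_value(w, obj, inf, rois), tolerance = 1e-12)
})

test_that("solver reaches grid-search optimality on a 3-spot instance", {
  set.seed(21)
  D <- matrix(runif(15, 0.1, 1), 5, 3)
  L <- matrix(runif(15, 1, 8), 5, 3)
  inf <- manual_influence(D, L)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1),
                       objective_term("roi", "letd", "min", 6, 0.05))
  fit <- solve_weights(inf, obj, rois)
  # exhaustive grid search over the weight box (objectives bound once)
  bound <- sparclet:::bind_objectives(obj, inf, rois)
  grid <- seq(0, 4, by = 0.1)
  best <- Inf
  for (w1 in grid) for (w2 in grid) for (w3 in grid) {
    v <- objective_value(c(w1, w2, w3), bound, inf)
    if (v < best) best <- v
  }
  expect_lte(fit$report$value, best * 1.01 + 1e-12)
})

test_that("solver contracts the objective and respects stationary starts", {
  # more spots than voxels: the prescription is exactly attainable
  inf <- random_influence(8, 12, seed = 31, density = 0.9)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1))
  fit <- solve_weights(inf, obj, rois)
  init_val <- objective_value(sparclet:::default_init(
    inf, sparclet:::bind_objectives(obj, inf, rois)), obj, inf, rois)
  expect_lt(fit$report$value, 1e-3 * init_val)
  expect_true(all(diff(fit$report$trace) <= 0))
  # restart at the optimum stays put (up to solver polish)
  fit2 <- solve_weights(inf, obj, rois, init = fit$weights)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-4)
  expect_lte(fit2$report$value, fit$report$value + 1e-12)
  # dose-only reduction: zeroed LET penalties match a pure dose run exactly
  obj_zero <- objective_set(objective_term("roi", "dose", "uniform", 2, 1),
                            objective_term("roi", "letd", "min", 8, 0))
  expect_identical(solve_weights(inf, obj_zero, rois)$weights, fit$weights)
})

test_that("raising the target-LET penalty trades toward higher target LET_d", {
  inf <- random_influence(30, 8, seed = 41, density = 0.9)
  rois <- manual_rois(inf, kind = "target")
  goal <- 10
  undershoot <- function(w) {
    l <- accumulate_letd(inf, w)$values
    sum(pmin(l - goal, 0)^2)
  }
  means <- c(); shorts <- c()
  w <- NULL
  for (p in c(0, 0.001, 0.01, 0.1, 1)) {
    obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1),
                         objective_term("roi", "letd", "min", goal, p))
    fit <- solve_weights(inf, obj, rois, init = w, max_iter = 2000,
                         factr = 1e2)
    w <- fit$weights
    means <- c(means, mean(accumulate_letd(inf, w)$values))
    shorts <- c(shorts, undershoot(w))
  }
  # the penalized LET-undershoot measure is non-increasing in the penalty
  # (guaranteed for minimizers of A + p B), and the mean target LET_d it
  # drives moves up with it
  expect_true(all(diff(shorts) <= 1e-8))
  expect_true(all(diff(means) > -1e-6))
  expect_gt(means[length(means)], means[1])
})

test_that("deliverable post-processing enforces the minimum MU", {
  inf <- random_influence(150, 10, seed = 51)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1))
  fit <- solve_weights(inf, obj, rois)
  # all weights far above threshold: re-optimization barely moves
  expect_true(all(fit$weights > 0.02))
  post <- deliverable_postprocess(fit$weights, inf, obj, rois, min_mu = 0.02)
  expect_deliverable(post$weights)
  expect_lt(abs(post$report$degradation), 0.01)
  # a sub-threshold spot is removed outright
  w <- fit$weights
  w[4] <- 0.001
  post2 <- deliverable_postprocess(w, inf, obj, rois, min_mu = 0.02)
  expect_equal(post2$weights[4], 0)
  expect_deliverable(post2$weights)
  # ideal-vs-deliverable dose gap shrinks as min MU tightens to zero
  gaps <- vapply(c(0.8, 0.2, 0.02), function(mu) {
    p <- deliverable_postprocess(fit$weights, inf, obj, rois, min_mu = mu)
    max(abs(accumulate_dose(inf, p$weights)$values -
              accumulate_dose(inf, fit$weights)$values))
  }, 0)
  expect_true(all(diff(gaps) <= 1e-9))
  expect_error(deliverable_postprocess(rep(0.001, 10), inf, obj, rois),
               "planning failure")
})

test_that("dose-volume terms penalize only the excess voxels", {
  D <- diag(5)
  inf <- manual_influence(D, D * 3)
  rois <- manual_rois(inf, kind = "oar")
  # doses will be w directly; allow 40% of 5 voxels (=2) above 1 Gy
  obj <- objective_set(objective_term("roi", "dose", "max", 10, 0),
                       dose_volume_term("roi", 1, 0.4, 1))
  expect_equal(objective_value(c(2, 2, 0.5, 0.5, 0.5), obj, inf, rois), 0)
  # three voxels above the level: the one closest above the level is penalized
  v <- objective_value(c(2, 2, 1.2, 0.5, 0.5), obj, inf, rois)
  expect_equal(v, (1.2 - 1)^2)
  # gradient exists and matches finite differences away from selection ties
  w <- c(2, 1.8, 1.2, 0.5, 0.5)
  g <- objective_gradient(w, obj, inf, rois)
  fd <- fd_gradient(function(x) objective_value(x, obj, inf, rois), w)
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("penalty ramp preserves target coverage while boosting LET_d", {
  inf <- random_influence(200, 14, seed = 61)
  rois <- manual_rois(inf, kind = "target")
  obj <- objective_set(objective_term("roi", "dose", "uniform", 2, 1),
                       objective_term("roi", "letd", "min", 10, 0.001))
  tuned <- tune_let_weights(inf, obj, rois, scales = c(0.5, 2, 8, 32))
  expect_gte(tuned$d95, 0.99 * tuned$d95_ref)
  base <- solve_weights(inf, sparclet:::scale_let_penalties(obj, 0), rois)
  expect_gte(mean(accumulate_letd(inf, tuned$weights)$values),
             mean(accumulate_letd(inf, base$weights)$values) - 1e-9)
})
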