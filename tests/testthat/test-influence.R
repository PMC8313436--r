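test_that("dose accumulation matches a brute-force double loop", {
  for (seed in 1:3) {
    inf <- random_influence(1000, 20, seed = seed)
    set.seed(seed + 100)
    w <- runif(20, 0, 5)
    got <- accumulate_dose(inf, w)$values
    Dd <- as.matrix(inf$D)
    want <- numeric(1000)
    for (i in 1:1000) for (j in 1:20) want[i] <- want[i] + Dd[i, j] * w[j]
    expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-12)
  }
})

test_that("dose-averaged LET matches the brute-force quotient", {
  for (seed in 1:3) {
    inf <- random_influence(1000, 20, seed = seed)
    set.seed(seed + 200)
    w <- runif(20, 0, 5)
    got <- accumulate_letd(inf, w)$values
    Dd <- as.matrix(inf$D); Ll <- as.matrix(inf$L)
    want <- numeric(1000)
    for (i in 1:1000) {
      num <- 0; den <- 0
      for (j in 1:20) {
        num <- num + Ll[i, j] * Dd[i, j] * w[j]
        den <- den + Dd[i, j] * w[j]
      }
      want[i] <- if (den > 0) num / den else 0
    }
    rel <- abs(got - want) / pmax(abs(want), 1e-12)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("dose-averaged LET obeys its structural invariants", {
  inf <- random_influence(500, 15, seed = 9)
  set.seed(9)
  w <- runif(15, 0.1, 3)
  let1 <- accumulate_letd(inf, w)$values
  # scale invariance of the quotient
  expect_equal(accumulate_letd(inf, 3 * w)$values, let1, tolerance = 1e-12)
  # convex-combination bounds over contributing spots
  Dd <- as.matrix(inf$D); Ll <- as.matrix(inf$L)
  for (i in seq(1, 500, by = 11)) {
    contrib <- Dd[i, ] * w > 0
    if (!any(contrib)) next
    expect_gte(let1[i], min(Ll[i, contrib]) - 1e-9)
    expect_lte(let1[i], max(Ll[i, contrib]) + 1e-9)
  }
  # single contributing spot: the quotient collapses to LET_ij
  inf1 <- manual_influence(D = matrix(c(0.7, 0), 1), L = matrix(c(4.2, 0), 1))
  expect_equal(accumulate_letd(inf1, c(2, 5))$values, 4.2)
  # two spots with equal dose-weight contributions average their LETs
  inf2 <- manual_influence(D = matrix(c(0.5, 1), 1), L = matrix(c(2, 6), 1))
  expect_equal(accumulate_letd(inf2, c(2, 1))$values, 4)
  # zero weights: zero dose everywhere, LET_d = 0 by convention
  z <- accumulate_dose(inf, rep(0, 15))$values
  expect_true(all(z == 0))
  expect_true(all(accumulate_letd(inf, rep(0, 15))$values == 0))
})

test_that("accumulation is linear and rejects bad weights", {
  inf <- random_influence(300, 10, seed = 5)
  set.seed(5)
  w1 <- runif(10); w2 <- runif(10)
  expect_equal(accumulate_dose(inf, w1 + w2)$values,
               accumulate_dose(inf, w1)$values + accumulate_dose(inf, w2)$values,
               tolerance = 1e-12)
  expect_equal(accumulate_dose(inf, 2 * w1)$values,
               2 * accumulate_dose(inf, w1)$values, tolerance = 1e-14)
  expect_error(accumulate_dose(inf, -w1), "contract violation")
  expect_error(accumulate_dose(inf, w1[1:5]), "contract violation")
})

test_that("assembled influence reproduces the depth-dose on the central axis", {
  ph <- water_box(c(21, 31, 9), spacing = 5)
  m <- test_model()
  spots <- data.frame(cp = 1L, angle = 0, energy = 130, u = 0, v = 0,
                      weight = 0)
  inf <- compute_influence(ph, spots, m, array(TRUE, ph$shape), cutoff = 0)
  pts <- index_to_world_test(ph, inf$voxel_index)
  axis <- abs(pts[, 1]) < 1e-9 & abs(pts[, 3]) < 1e-9
  w <- wepl_raytrace(ph, 0, pts[axis, , drop = FALSE])
  got <- accumulate_dose(inf, 1)$values[axis]
  expect_equal(got, depth_dose(m, 130, w), tolerance = 1e-6)
  # D and L share one sparsity pattern; LET present wherever dose is
  expect_identical(inf$D@i, inf$L@i)
  expect_identical(inf$D@p, inf$L@p)
  expect_true(all(inf$L@x[inf$D@x > 0] > 0))
  # total unit-weight column dose is positive and finite
  cs <- Matrix::colSums(inf$D)
  expect_true(all(cs > 0) && all(is.finite(cs)))
})

test_that("column cutoff perturbs accumulated dose within its bound", {
  ph <- water_box(c(20, 20, 10), spacing = 5)
  m <- test_model()
  spots <- data.frame(cp = 1L, angle = c(0, 0), energy = c(120, 140),
                      u = c(0, 10), v = c(0, -5), weight = 0)
  inf0 <- compute_influence(ph, spots, m, array(TRUE, ph$shape), cutoff = 0)
  infc <- compute_influence(ph, spots, m, array(TRUE, ph$shape), cutoff = 1e-4)
  w <- c(1, 1)
  d0 <- accumulate_dose(inf0, w)$values
  dc <- accumulate_dose(infc, w)$values
  colmax <- apply(as.matrix(inf0$D), 2, max)
  expect_true(all(abs(d0 - dc) <= 1e-4 * sum(colmax) + 1e-15))
  expect_lt(length(infc$D@x), length(inf0$D@x))
  # a spot that misses the scoring volume keeps an all-zero column
  far <- data.frame(cp = 1L, angle = 0, energy = 120, u = 500, v = 0,
                    weight = 0)
  expect_warning(inf_miss <- compute_influence(ph, rbind(spots, far), m,
                                               array(TRUE, ph$shape)),
                 "no dose")
  expect_equal(ncol(inf_miss$D), 3)
  expect_equal(Matrix::colSums(inf_miss$D)[3], 0, ignore_attr = TRUE)
})
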