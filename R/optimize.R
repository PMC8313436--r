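#' Objective term
#'
#' One term of the joint quadratic dose + LET_d objective. Senses:
#' `uniform` (two-sided quadratic pull to the goal; valid only on target
#' ROIs), `max` (penalize overshoot above the goal, gated by the Heaviside
#' step), `min` (penalize undershoot below the goal). The LET_d term of a
#' target is expressed as a `min` bound (penalize undershoot of the LET
#' goal); OAR LET_d terms as `max` bounds.
#'
#' @param roi ROI name the term binds to.
#' @param quantity `"dose"` (Gy) or `"letd"` (keV/um).
#' @param sense `"uniform"`, `"max"` or `"min"`.
#' @param goal dose goal D_0 (Gy) or LET goal LET_0 (keV/um), `>= 0`.
#' @param penalty nonnegative penalty weight p.
#' @return an object of class `objective_term`.
#' @export
objective_term <- function(roi, quantity = c("dose", "letd"),
                           sense = c("uniform", "max", "min"),
                           goal, penalty = 1) {
  quantity <- match.arg(quantity)
  sense <- match.arg(sense)
  stopifnot(is.character(roi), goal >= 0, penalty >= 0)
  structure(list(roi = roi, quantity = quantity, sense = sense,
                 goal = goal, penalty = penalty, type = "plain"),
            class = "objective_term")
}

#' Dose-volume objective term
#'
#' A maximum dose-volume constraint: at most `volume_fraction` of the ROI may
#' exceed `dose`. Implemented by the standard per-evaluation voxel-selection
#' reformulation: the excess voxels closest above the dose level receive a
#' quadratic penalty toward it.
#'
#' @param roi ROI name.
#' @param dose dose level, Gy.
#' @param volume_fraction allowed fraction of the ROI above the level, in
#'   `[0, 1]`.
#' @param penalty nonnegative penalty weight.
#' @return an object of class `objective_term`.
#' @export
dose_volume_term <- function(roi, dose, volume_fraction, penalty = 1) {
  stopifnot(dose >= 0, volume_fraction >= 0, volume_fraction <= 1, penalty >= 0)
  structure(list(roi = roi, quantity = "dose", sense = "max", goal = dose,
                 volume_fraction = volume_fraction, penalty = penalty,
                 type = "dv"),
            class = "objective_term")
}

#' Objective set
#'
#' Ordered collection of [objective_term()]s. Must contain at least one dose
#' term on a target ROI (checked when the set is bound to a phantom's ROIs).
#'
#' @param ... objective terms, or a single list of them.
#' @param let_dose_min LET_d terms are evaluated only on voxels whose dose
#'   exceeds this threshold (Gy); zero-dose voxels carry LET_d = 0 by
#'   convention and no gradient.
#' @return an object of class `objective_set`.
#' @export
objective_set <- function(..., let_dose_min = 0) {
  terms <- list(...)
  if (length(terms) == 1 && !inherits(terms[[1]], "objective_term"))
    terms <- terms[[1]]
  stopifnot(length(terms) > 0,
            all(vapply(terms, inherits, TRUE, "objective_term")))
  structure(list(terms = terms, let_dose_min = let_dose_min),
            class = "objective_set")
}

#' @export
print.objective_set <- function(x, ...) {
  cat(sprintf("<objective_set> %d terms\n", length(x$terms)))
  for (t in x$terms)
    cat(sprintf("  %-12s %-5s %-8s goal %-7.3g p %.3g%s\n", t$roi, t$quantity,
                t$sense, t$goal, t$penalty,
                if (t$type == "dv") sprintf(" (DV, V<=%.0f%%)", 100 * t$volume_fraction) else ""))
  invisible(x)
}

# rescale the LET-term penalties of a set by a common factor
scale_let_penalties <- function(objectives, factor) {
  objectives$terms <- lapply(objectives$terms, function(t) {
    if (t$quantity == "letd") t$penalty <- t$penalty * factor
    t
  })
  objectives
}

# Resolve each term's ROI to scoring rows and pre-slice the influence
# matrices. Errors if a referenced ROI is missing or a `uniform` sense is
# bound to a non-target ROI.
bind_objectives <- function(objectives, inf, rois) {
  stopifnot(inherits(objectives, "objective_set"))
  if (inherits(objectives, "bound_objective_set")) return(objectives)
  bound <- lapply(objectives$terms, function(t) {
    roi <- rois[[t$roi]]
    if (is.null(roi))
      stop(sprintf("configuration error: objective references unknown ROI '%s'", t$roi))
    if (t$sense == "uniform" && roi$kind != "target")
      stop(sprintf("configuration error: uniform-target sense on non-target ROI '%s'", t$roi))
    rows <- match(which(roi$mask), inf$voxel_index)
    if (anyNA(rows))
      stop(sprintf("configuration error: ROI '%s' not fully inside the scoring volume", t$roi))
    t$rows <- rows
    t$Dsub <- inf$D[rows, , drop = FALSE]
    if (t$quantity == "letd") t$Msub <- inf$M[rows, , drop = FALSE]
    t
  })
  structure(list(terms = bound, let_dose_min = objectives$let_dose_min),
            class = c("bound_objective_set", "objective_set"))
}

# residual vector of one term given its per-voxel values
term_residual <- function(t, val) {
  switch(t$sense,
         uniform = val - t$goal,
         max = pmax(val - t$goal, 0),
         min = pmin(val - t$goal, 0))
}

# per-evaluation voxel selection for a DV term: indices (into the term rows)
# of the excess voxels closest above the dose level
dv_selection <- function(t, dsub) {
  over <- which(dsub > t$goal)
  allowed <- floor(t$volume_fraction * length(dsub))
  excess <- length(over) - allowed
  if (excess <= 0) return(integer(0))
  over[order(dsub[over])][seq_len(excess)]
}

objective_terms_eval <- function(w, bound, inf, gradient = FALSE) {
  d <- as.numeric(inf$D %*% w)
  need_let <- any(vapply(bound$terms, function(t) t$quantity == "letd", TRUE))
  if (need_let) {
    m <- as.numeric(inf$M %*% w)
    let <- ifelse(d > 0, m / d, 0)
  }
  vals <- numeric(length(bound$terms))
  grad <- if (gradient) numeric(length(w))
  for (k in seq_along(bound$terms)) {
    t <- bound$terms[[k]]
    if (t$penalty == 0) next
    if (t$quantity == "dose") {
      dsub <- d[t$rows]
      if (t$type == "dv") {
        sel <- dv_selection(t, dsub)
        if (!length(sel)) next
        r <- numeric(length(dsub))
        r[sel] <- dsub[sel] - t$goal
      } else {
        r <- term_residual(t, dsub)
      }
      vals[k] <- t$penalty * sum(r^2)
      if (gradient && any(r != 0))
        grad <- grad + 2 * t$penalty *
          as.numeric(Matrix::crossprod(t$Dsub, r))
    } else {
      dsub <- d[t$rows]
      act <- dsub > bound$let_dose_min
      lsub <- let[t$rows]
      r <- term_residual(t, lsub)
      r[!act] <- 0
      vals[k] <- t$penalty * sum(r^2)
      if (gradient && any(r != 0)) {
        a <- ifelse(act, r / dsub, 0)
        grad <- grad + 2 * t$penalty *
          (as.numeric(Matrix::crossprod(t$Msub, a)) -
             as.numeric(Matrix::crossprod(t$Dsub, a * lsub)))
      }
    }
  }
  list(value = sum(vals), terms = vals, grad = grad)
}

#' Evaluate the joint dose + LET_d objective
#'
#' Sum over terms of `p * sum(residual^2)` where target-dose terms use the
#' two-sided residual `D_i - D_0`, bound terms gate the residual with the
#' Heaviside step (`H(x) = 1` iff `x > 0`), and LET_d terms use the
#' dose-averaged LET of the current weights. Always `>= 0`.
#'
#' @param w nonnegative spot weights (MU).
#' @param objectives an [objective_set()].
#' @param inf an [influence_pair()].
#' @param rois named list of `roi_mask` (omit if `objectives` are already
#'   bound).
#' @return scalar objective value.
#' @export
objective_value <- function(w, objectives, inf, rois = NULL) {
  check_weights(inf, w)
  bound <- bind_objectives(objectives, inf, rois)
  objective_terms_eval(w, bound, inf, gradient = FALSE)$value
}

#' Exact gradient of the joint objective
#'
#' Analytic gradient of [objective_value()] with respect to the spot
#' weights, including the quotient-rule derivative of the dose-averaged LET
#' terms (`dLET_i/dw_j = (M_ij - LET_i D_ij) / D_i`). Heaviside gates and
#' dose-volume selections are held fixed at the evaluation point
#' (one-sided derivatives).
#'
#' @inheritParams objective_value
#' @return gradient vector, one entry per spot.
#' @export
objective_gradient <- function(w, objectives, inf, rois = NULL) {
  check_weights(inf, w)
  bound <- bind_objectives(objectives, inf, rois)
  objective_terms_eval(w, bound, inf, gradient = TRUE)$grad
}

# default initialization: uniform weights scaled so the mean dose on the
# first uniform target term equals its goal
default_init <- function(inf, bound) {
  uni <- Find(function(t) t$quantity == "dose" && t$sense == "uniform" &&
                t$type == "plain", bound$terms)
  w <- rep(1, ncol(inf$D))
  if (is.null(uni)) return(w)
  mu <- mean(as.numeric(uni$Dsub %*% w))
  if (mu <= 0) return(w)
  rep(uni$goal / mu, ncol(inf$D))
}

#' Minimize the joint objective over nonnegative spot weights
#'
#' Bound-constrained limited-memory quasi-Newton descent (L-BFGS-B) with the
#' exact analytic gradient. Deterministic given the initialization and
#' settings; the default initialization is uniform weights scaled so the
#' mean target dose equals the prescription goal.
#'
#' @param inf an [influence_pair()].
#' @param objectives an [objective_set()].
#' @param rois named list of `roi_mask`.
#' @param init initial weights (default: scaled uniform), must satisfy
#'   `init >= lower`.
#' @param lower lower bound on every weight (scalar or per-spot), `>= 0`.
#' @param max_iter iteration cap.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @return list with `weights` (the minimizer) and `report` (an
#'   `optimizer_report`: iterations, non-increasing objective trace over
#'   accepted iterates, convergence flag, per-term contributions at the
#'   solution).
#' @export
solve_weights <- function(inf, objectives, rois = NULL, init = NULL,
                          lower = 0, max_iter = 200, factr = 1e7) {
  bound <- bind_objectives(objectives, inf, rois)
  if (is.null(init)) init <- default_init(inf, bound)
  if (length(lower) == 1) lower <- rep(lower, ncol(inf$D))
  stopifnot(all(lower >= 0), all(init >= lower - 1e-12), length(init) == ncol(inf$D))
  init <- pmax(init, lower)

  evals <- new.env(parent = emptyenv())
  evals$trace <- numeric(0)
  fn <- function(w) {
    v <- objective_terms_eval(w, bound, inf, gradient = FALSE)$value
    if (!is.finite(v))
      stop("numerical error: non-finite objective during iteration; iterate range [",
           paste(signif(range(w), 4), collapse = ", "), "]")
    evals$trace <- c(evals$trace, v)
    v
  }
  gr <- function(w) objective_terms_eval(w, bound, inf, gradient = TRUE)$grad

  fit <- stats::optim(init, fn, gr, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = max_iter, factr = factr))
  w <- pmax(fit$par, lower)   # L-BFGS-B can breach the bound by an epsilon
  final <- objective_terms_eval(w, bound, inf, gradient = FALSE)
  report <- structure(list(
    iterations = unname(fit$counts["function"]),
    trace = cummin(evals$trace),
    converged = fit$convergence == 0,
    value = final$value,
    term_contributions = final$terms),
    class = "optimizer_report")
  list(weights = w, report = report)
}

#' @export
print.optimizer_report <- function(x, ...) {
  cat(sprintf("<optimizer_report> %d evaluations, objective %.6g (%s)\n",
              x$iterations, x$value,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Post-process weights into a deliverable plan
#'
#' Spots below the minimum deliverable MU are removed (set to 0); the
#' surviving spots are re-optimized with the minimum-MU lower bound active,
#' so every returned weight is either 0 or `>= min_mu`. The objective
#' degradation relative to the ideal weights is reported.
#'
#' @param w optimized weights from [solve_weights()].
#' @param inf an [influence_pair()].
#' @param objectives an [objective_set()].
#' @param rois named list of `roi_mask`.
#' @param min_mu minimum deliverable MU per spot.
#' @param max_iter,factr passed to the re-optimization.
#' @return list with `weights` (deliverable, full length), `kept` (logical),
#'   and `report` (including `degradation`, the relative objective change).
#' @export
deliverable_postprocess <- function(w, inf, objectives, rois = NULL,
                                    min_mu = 0.02, max_iter = 200,
                                    factr = 1e7) {
  check_weights(inf, w)
  keep <- w >= min_mu
  if (!any(keep))
    stop("planning failure: deliverable post-processing removed every spot")
  obj_before <- objective_value(w, objectives, inf, rois)
  sub <- subset_spots(inf, which(keep))
  objectives <- if (inherits(objectives, "bound_objective_set"))
    structure(list(terms = lapply(objectives$terms, function(t) {
      t$rows <- NULL; t$Dsub <- NULL; t$Msub <- NULL
      class(t) <- "objective_term"; t
    }), let_dose_min = objectives$let_dose_min), class = "objective_set")
  else objectives
  fit <- solve_weights(sub, objectives, rois, init = pmax(w[keep], min_mu),
                       lower = min_mu, max_iter = max_iter, factr = factr)
  out <- numeric(length(w))
  out[keep] <- fit$weights
  fit$report$degradation <-
    if (obj_before > 0) (fit$report$value - obj_before) / obj_before else 0
  list(weights = out, kept = keep, report = fit$report)
}

# dose percentile: largest dose received by at least q% of the ROI volume
dose_percentile <- function(values, q) {
  n <- length(values)
  sort(values, decreasing = TRUE)[ceiling(q / 100 * n)]
}

#' Ramp the LET_d penalties while holding target coverage
#'
#' The documented default schedule for trading dose against LET_d: the dose
#' penalties stay fixed and the LET_d penalties are scaled up a geometric
#' ladder, re-optimizing (warm-started) at each step, until the target D95
#' would degrade below `d95_keep` times the dose-only D95; the feasible
#' boundary is then refined by log-scale bisection so every geometry is
#' pushed to its own maximum compliant penalty rather than a shared ladder
#' rung. The last compliant solution is returned.
#'
#' @param inf an [influence_pair()].
#' @param objectives an [objective_set()] containing the LET_d terms at
#'   their base penalties.
#' @param rois named list of `roi_mask`.
#' @param scales increasing multipliers applied to every LET_d penalty.
#' @param n_bisect log-scale bisection steps refining the largest compliant
#'   multiplier.
#' @param d95_keep minimum fraction of the dose-only D95 to preserve.
#' @param base optional precomputed dose-only solution (list with `weights`
#'   and `d95_ref`), reused across repeated tunes on one geometry.
#' @param max_iter,factr passed to each solve.
#' @return list with `weights`, `scale` (the accepted multiplier; 0 if even
#'   the smallest scale violates coverage), `d95_ref`, `d95`, and `report`.
#' @export
tune_let_weights <- function(inf, objectives, rois, scales = 8^(0:2),
                             n_bisect = 3, d95_keep = 0.99, base = NULL,
                             max_iter = 150, factr = 1e7) {
  stopifnot(all(diff(scales) > 0), all(scales > 0))
  uni <- Find(function(t) t$quantity == "dose" && t$sense == "uniform",
              objectives$terms)
  if (is.null(uni)) stop("configuration error: need a uniform target dose term")
  troi <- rois[[uni$roi]]
  d95_of <- function(w)
    dose_percentile(map_on_roi(accumulate_dose(inf, w), troi), 95)

  if (is.null(base)) {
    fit0 <- solve_weights(inf, scale_let_penalties(objectives, 0), rois,
                          max_iter = max_iter, factr = factr)
    base <- list(weights = fit0$weights, d95_ref = d95_of(fit0$weights),
                 report = fit0$report)
  }
  d95_ref <- base$d95_ref

  solve_at <- function(s, w_init) {
    fit <- solve_weights(inf, scale_let_penalties(objectives, s), rois,
                         init = w_init, max_iter = max_iter, factr = factr)
    c(fit, list(d95 = d95_of(fit$weights)))
  }

  best <- list(weights = base$weights, scale = 0, d95 = d95_ref,
               report = base$report)
  w <- base$weights
  lo <- 0; hi <- NA_real_
  for (s in scales) {
    fit <- solve_at(s, w)
    w <- fit$weights
    if (fit$d95 >= d95_keep * d95_ref) {
      best <- list(weights = w, scale = s, d95 = fit$d95, report = fit$report)
      lo <- s
    } else {
      hi <- s
      break
    }
  }
  if (!is.na(hi)) {
    for (b in seq_len(n_bisect)) {
      mid <- if (lo == 0) hi / 4 else sqrt(lo * hi)
      fit <- solve_at(mid, w)
      w <- fit$weights
      if (fit$d95 >= d95_keep * d95_ref) {
        best <- list(weights = w, scale = mid, d95 = fit$d95,
                     report = fit$report)
        lo <- mid
      } else hi <- mid
    }
  }
  best$d95_ref <- d95_ref
  best
}
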