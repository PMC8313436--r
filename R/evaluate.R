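#' Cumulative dose- or LET-volume histogram over an ROI
#'
#' The "volume receiving at least x" curve in percent of the ROI volume.
#' For LET_d maps a dose-reporting threshold restricts the histogram to
#' voxels receiving clinically meaningful dose, so the zero-dose LET_d = 0
#' convention does not distort the LVH.
#'
#' @param map a `value_map` from [accumulate_dose()] or [accumulate_letd()].
#' @param roi a non-empty `roi_mask` inside the scoring volume.
#' @param bin_width histogram bin width (default 0.1 Gy for dose, 0.05
#'   keV/um for LET_d).
#' @param dose_map optional dose `value_map` used to threshold an LVH.
#' @param dose_threshold minimum dose (Gy) for a voxel to enter an LVH.
#' @return a `histogram_curve` data frame (`value`, `volume_pct`): starts at
#'   100% at 0, monotone non-increasing, 0 beyond the maximum value.
#' @export
compute_histogram <- function(map, roi, bin_width = NULL, dose_map = NULL,
                              dose_threshold = 0) {
  if (!any(roi$mask)) stop("evaluation error: empty ROI")
  vals <- map_on_roi(map, roi)
  if (map$quantity == "letd" && !is.null(dose_map)) {
    d <- map_on_roi(dose_map, roi)
    vals <- vals[d >= dose_threshold]
    if (!length(vals))
      stop(sprintf("evaluation error: no ROI '%s' voxels above the dose threshold", roi$name))
  }
  if (is.null(bin_width)) bin_width <- if (map$quantity == "dose") 0.1 else 0.05
  edges <- seq(0, max(vals) + 2 * bin_width, by = bin_width)
  pct <- vapply(edges, function(e) 100 * mean(vals >= e), 0)
  structure(data.frame(value = edges, volume_pct = pct),
            quantity = map$quantity, roi = roi$name, bin_width = bin_width,
            class = c("histogram_curve", "data.frame"))
}

#' Per-ROI dose and LET_d summary
#'
#' Plain arithmetic statistics over the ROI voxels; `mean_letd` is the
#' unweighted average of voxel LET_d over the reported voxels (those at or
#' above the dose threshold).
#'
#' @param dose_map,let_map `value_map`s for the same weights.
#' @param roi a non-empty `roi_mask`.
#' @param dose_threshold reporting threshold for the LET_d statistics, Gy.
#' @return one-row data frame: `roi`, `mean_dose`, `d95`, `dmax`,
#'   `mean_letd`, `letd_max`, `n_voxels`.
#' @export
roi_summary <- function(dose_map, let_map, roi, dose_threshold = 0) {
  if (!any(roi$mask)) stop("evaluation error: empty ROI")
  d <- map_on_roi(dose_map, roi)
  l <- map_on_roi(let_map, roi)
  rep_vox <- d >= dose_threshold
  data.frame(roi = roi$name,
             mean_dose = mean(d),
             d95 = dose_percentile(d, 95),
             dmax = max(d),
             mean_letd = if (any(rep_vox)) mean(l[rep_vox]) else NA_real_,
             letd_max = if (any(rep_vox)) max(l[rep_vox]) else NA_real_,
             n_voxels = length(d))
}

#' Evaluate a plan: ROI summaries, DVH/LVH curves, delivery time
#'
#' @param plan a `proton_plan` carrying its influence matrix (plans read
#'   back from JSON need `phantom` to recompute it).
#' @param phantom the planning `voxel_phantom`.
#' @param rois named list of `roi_mask`; external `body` contours are
#'   skipped in the summaries.
#' @param delivery a [delivery_model()].
#' @param lvh_threshold_frac LVH/LET-reporting dose threshold as a fraction
#'   of the per-fraction prescription (default 1%).
#' @param dvh_bin,lvh_bin histogram bin widths.
#' @return a `plan_evaluation`: `summary` data frame, `dvh` and `lvh` curve
#'   lists, `delivery` (total seconds + breakdown), `rx_fx`.
#' @export
evaluate_plan <- function(plan, phantom, rois, delivery = delivery_model(),
                          lvh_threshold_frac = 0.01, dvh_bin = 0.1,
                          lvh_bin = 0.05) {
  inf <- plan$influence
  if (is.null(inf)) {
    scoring <- default_scoring(rois)
    inf <- compute_influence(phantom, plan$spots, plan$model, scoring)
  }
  w <- plan$spots$weight
  dose <- accumulate_dose(inf, w)
  letd <- accumulate_letd(inf, w)
  rx_fx <- plan$spec$rx_gy / plan$spec$fractions
  thr <- lvh_threshold_frac * rx_fx
  keep <- rois[vapply(rois, function(r) r$name != "body", TRUE)]
  summ <- do.call(rbind, lapply(keep, function(r)
    roi_summary(dose, letd, r, dose_threshold = thr)))
  rownames(summ) <- NULL
  dvh <- lapply(keep, function(r) compute_histogram(dose, r, dvh_bin))
  lvh <- lapply(keep, function(r)
    compute_histogram(letd, r, lvh_bin, dose_map = dose, dose_threshold = thr))
  dt <- plan_delivery_time(plan, delivery)
  structure(list(summary = summ, dvh = dvh, lvh = lvh, delivery = dt,
                 rx_fx = rx_fx, lvh_threshold = thr),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("<plan_evaluation> delivery %.1f s, LET_d reported above %.3g Gy\n",
              x$delivery$total_s, x$lvh_threshold))
  print(x$summary, digits = 3)
  invisible(x)
}

# shared helper for the experiment drivers: tune the LET penalties on a
# fixed geometry, make the result deliverable, and summarize the target ROI
tuned_deliverable <- function(inf, objectives, rois, target_roi, min_mu,
                              thr, scales = 8^(0:2), d95_keep = 0.99,
                              max_iter = 150, let_free = FALSE, base = NULL) {
  if (let_free) {
    fit <- solve_weights(inf, scale_let_penalties(objectives, 0), rois,
                         max_iter = max_iter)
    w <- fit$weights; scale <- 0
    obj_used <- scale_let_penalties(objectives, 0)
  } else {
    tuned <- tune_let_weights(inf, objectives, rois, scales = scales,
                              d95_keep = d95_keep, max_iter = max_iter,
                              base = base)
    w <- tuned$weights; scale <- tuned$scale
    obj_used <- scale_let_penalties(objectives, max(scale, 0))
  }
  post <- deliverable_postprocess(w, inf, obj_used, rois, min_mu = min_mu,
                                  max_iter = max_iter)
  w <- post$weights
  dose <- accumulate_dose(inf, w)
  letd <- accumulate_letd(inf, w)
  list(weights = w, scale = scale, dose = dose, letd = letd,
       summary = roi_summary(dose, letd, target_roi, dose_threshold = thr))
}

#' Beam-number sweep: target LET_d versus number of beams
#'
#' Reproduces the beam-count experiment on a packaged symmetric phantom:
#' LET-free 2-beam baseline, LET_d-optimized IMPT at each beam count
#' (equally spaced angles), and a SPArc plan, all at matched target
#' coverage (the LET penalty ramp stops before D95 degrades). Reports mean
#' target LET_d, D95, delivery time, and the percent change of mean LET_d
#' against the 2-beam LET-free baseline.
#'
#' @param phantom,rois,spec,objectives,model as in [plan_sparc()].
#' @param counts beam counts to sweep.
#' @param include_sparc add the SPArc row?
#' @param delivery a [delivery_model()].
#' @param schedule,keep_layers SPArc sequencing parameters.
#' @param target target ROI name.
#' @param scales,d95_keep LET penalty ramp.
#' @param sparc_plan optionally a prebuilt SPArc `proton_plan` (with
#'   influence) to reuse instead of running [plan_sparc()].
#' @param ... further arguments passed to [plan_impt()] / [plan_sparc()].
#' @return data frame with one row per plan.
#' @export
beam_number_experiment <- function(phantom, rois, spec, objectives = NULL,
                                   model = beam_model(),
                                   counts = c(2, 4, 6, 8),
                                   include_sparc = TRUE,
                                   delivery = delivery_model(),
                                   schedule = c(20, 10, 5, 2.5),
                                   keep_layers = 1, target = "ctv",
                                   scales = 8^(0:2), d95_keep = 0.99,
                                   sparc_plan = NULL, ...) {
  if (is.null(objectives)) objectives <- default_objectives(spec, rois)
  thr <- 0.01 * spec$rx_gy / spec$fractions
  troi <- rois[[target]]
  rows <- list()

  run_geometry <- function(plan, label, beams, let_free) {
    res <- tuned_deliverable(plan$influence, objectives, rois, troi,
                             plan$min_mu, thr, scales, d95_keep,
                             let_free = let_free)
    plan$spots$weight <- res$weights
    plan$influence$spots <- plan$spots
    dt <- plan_delivery_time(plan, delivery)
    data.frame(plan = label, beams = beams,
               mean_target_letd = res$summary$mean_letd,
               d95 = res$summary$d95,
               let_scale = res$scale,
               delivery_s = dt$total_s)
  }

  for (n in counts) {
    angles <- (90 + (seq_len(n) - 1) * 360 / n) %% 360
    geo <- plan_impt(phantom, rois, spec, angles, objectives, model,
                     let_opt = FALSE, target = target, ...)
    if (n == min(counts))
      rows[[length(rows) + 1L]] <-
        run_geometry(geo, sprintf("%dB w/o", n), n, let_free = TRUE)
    rows[[length(rows) + 1L]] <-
      run_geometry(geo, sprintf("%dB", n), n, let_free = FALSE)
  }
  if (include_sparc) {
    sp <- if (!is.null(sparc_plan)) sparc_plan
      else plan_sparc(phantom, rois, spec, objectives, model,
                      schedule = schedule, keep_layers = keep_layers,
                      target = target, ...)
    rows[[length(rows) + 1L]] <-
      run_geometry(sp, "SPArc", nrow(sp$control_points), let_free = FALSE)
  }
  out <- do.call(rbind, rows)
  base <- out$mean_target_letd[out$plan == sprintf("%dB w/o", min(counts))]
  out$pct_vs_baseline <- (out$mean_target_letd - base) / base * 100
  rownames(out) <- NULL
  out
}

#' SIB-volume sweep: achievable LET_d versus boost volume
#'
#' Shrinks the target by fixed metric steps to form a nested series of
#' simultaneous-integrated-boost (LET_d boost) volumes, then re-optimizes
#' the weights of a fixed SPArc geometry for each boost volume, maximizing
#' LET_d in the boost while the penalty ramp holds CTV coverage. The series
#' terminates when erosion empties the mask.
#'
#' @param phantom,rois,spec,objectives,model as in [plan_sparc()].
#' @param base_plan a SPArc `proton_plan` providing the arc geometry and
#'   influence (built with [plan_sparc()] if omitted).
#' @param step_mm shrink step (default 5 mm).
#' @param target target ROI to shrink.
#' @param scales,d95_keep LET penalty ramp.
#' @param ... passed to [plan_sparc()] when `base_plan` is omitted.
#' @return data frame: `volume_cc`, `mean_sib_letd`, `ctv_d95`, `let_scale`.
#' @export
sib_experiment <- function(phantom, rois, spec, objectives = NULL,
                           model = beam_model(), base_plan = NULL,
                           step_mm = 5, target = "ctv",
                           scales = 8^(0:2), d95_keep = 0.99,
                           max_iter = 150, ...) {
  if (is.null(objectives)) objectives <- default_objectives(spec, rois)
  if (is.null(base_plan))
    base_plan <- plan_sparc(phantom, rois, spec, objectives, model,
                            target = target, ...)
  thr <- 0.01 * spec$rx_gy / spec$fractions
  troi <- rois[[target]]
  inf <- base_plan$influence

  let_term_idx <- which(vapply(objectives$terms, function(t)
    t$quantity == "letd" && t$sense == "min", TRUE))
  if (!length(let_term_idx))
    stop("configuration error: need a target LET_d (min-bound) term to boost")

  # the dose-only reference is independent of the boost volume: solve once
  fit0 <- solve_weights(inf, scale_let_penalties(objectives, 0), rois,
                        max_iter = max_iter)
  d95_ref <- dose_percentile(map_on_roi(accumulate_dose(inf, fit0$weights),
                                        troi), 95)
  base <- list(weights = fit0$weights, d95_ref = d95_ref,
               report = fit0$report)

  rows <- list()
  sib <- troi
  margin <- 0
  repeat {
    if (!any(sib$mask)) break
    sib_name <- sprintf("sib_%gmm", margin)
    rois2 <- rois
    rois2[[sib_name]] <- structure(list(name = sib_name, mask = sib$mask,
                                        kind = "target"), class = "roi_mask")
    obj2 <- objectives
    for (k in let_term_idx) {
      t <- obj2$terms[[k]]
      # keep the per-voxel penalty weight constant as the boost ROI shrinks
      t$penalty <- t$penalty * sum(rois[[t$roi]]$mask) / sum(sib$mask)
      t$roi <- sib_name
      obj2$terms[[k]] <- t
    }
    res <- tuned_deliverable(inf, obj2, rois2, rois2[[sib_name]],
                             base_plan$min_mu, thr, scales, d95_keep,
                             base = base)
    rows[[length(rows) + 1L]] <- data.frame(
      shrink_mm = margin,
      volume_cc = roi_volume_cc(sib, phantom),
      mean_sib_letd = res$summary$mean_letd,
      ctv_d95 = dose_percentile(map_on_roi(res$dose, troi), 95),
      let_scale = res$scale)
    margin <- margin + step_mm
    sib <- suppressWarnings(shrink_roi(troi, margin, phantom))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario head-to-head: SPArc versus fixed-beam IMPT
#'
#' Runs the LET-free IMPT baseline, LET_d-optimized IMPT and a SPArc plan
#' on one scenario and tabulates per-ROI mean dose and mean LET_d with
#' percent changes against the LET-free baseline.
#'
#' @param phantom,rois,spec,objectives,model as in [plan_sparc()].
#' @param angles fixed IMPT beam angles.
#' @param target ROI whose LET_d is boosted (`"gtv"` for the liver-like
#'   scenario, `"ctv"` otherwise).
#' @param delivery a [delivery_model()].
#' @param sparc_plan optionally a prebuilt SPArc `proton_plan` to reuse.
#' @param schedule,keep_layers,scales,d95_keep,... as elsewhere.
#' @return data frame: one row per (plan, ROI).
#' @export
scenario_comparison <- function(phantom, rois, spec, angles,
                                objectives = NULL, model = beam_model(),
                                target = "ctv", delivery = delivery_model(),
                                schedule = c(20, 10, 5, 2.5),
                                keep_layers = 1,
                                scales = 8^(0:2), d95_keep = 0.99,
                                sparc_plan = NULL, ...) {
  if (is.null(objectives)) objectives <- default_objectives(spec, rois)
  thr <- 0.01 * spec$rx_gy / spec$fractions
  report_rois <- rois[vapply(rois, function(r) r$kind != "external", TRUE)]

  geo_impt <- plan_impt(phantom, rois, spec, angles, objectives, model,
                        let_opt = FALSE, ...)
  sp <- if (!is.null(sparc_plan)) sparc_plan
    else plan_sparc(phantom, rois, spec, objectives, model,
                    schedule = schedule, keep_layers = keep_layers, ...)

  one <- function(plan, label, let_free) {
    res <- tuned_deliverable(plan$influence, objectives, rois,
                             rois[[target]], plan$min_mu, thr,
                             scales, d95_keep, let_free = let_free)
    plan$spots$weight <- res$weights
    dt <- plan_delivery_time(plan, delivery)
    do.call(rbind, lapply(report_rois, function(r) {
      s <- roi_summary(res$dose, res$letd, r, dose_threshold = thr)
      data.frame(plan = label, roi = r$name, kind = r$kind,
                 mean_dose = s$mean_dose, d95 = s$d95,
                 mean_letd = s$mean_letd, delivery_s = dt$total_s)
    }))
  }
  base_label <- sprintf("%dB w/o", length(angles))
  out <- rbind(one(geo_impt, base_label, TRUE),
               one(geo_impt, sprintf("%dB", length(angles)), FALSE),
               one(sp, "SPArc", FALSE))
  base <- out[out$plan == base_label, c("roi", "mean_letd")]
  out$letd_pct_vs_baseline <-
    (out$mean_letd / base$mean_letd[match(out$roi, base$roi)] - 1) * 100
  rownames(out) <- NULL
  out
}
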