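#' Default objective set for a packaged scenario
#'
#' Builds the scenario's planning goals: a uniform per-fraction target dose
#' at the prescription, overdose bounds on the OARs and the conformity ring,
#' a min-bound LET_d boost on the boost target (GTV for the liver-like
#' scenario, CTV otherwise) and, for the brain-like scenario, max-bound
#' LET_d terms on every OAR. Penalties are normalized by ROI voxel count so
#' the balance between structures is resolution-independent; the LET_d base
#' penalties are deliberately gentle and are meant to be scaled by the
#' penalty ramp ([tune_let_weights()]).
#'
#' @param spec a [scenario_spec()].
#' @param rois the ROI list from [build_phantom()].
#' @return an [objective_set()].
#' @export
default_objectives <- function(spec, rois) {
  rx_fx <- spec$rx_gy / spec$fractions
  nv <- function(nm) sum(rois[[nm]]$mask)
  terms <- list(objective_term("ctv", "dose", "uniform", goal = rx_fx,
                               penalty = 100 / nv("ctv")))
  oars <- names(rois)[vapply(rois, function(r) r$kind == "oar", TRUE)]
  for (nm in oars) {
    frac <- if (nm == "liver") 0 else 0.6   # mean-dose push vs overdose bound
    pen <- if (nm == "liver") 2 else 30
    terms[[length(terms) + 1L]] <-
      objective_term(nm, "dose", "max", goal = frac * rx_fx,
                     penalty = pen / nv(nm))
  }
  if (!is.null(rois$ring))
    terms[[length(terms) + 1L]] <-
      objective_term("ring", "dose", "max", goal = 0.7 * rx_fx,
                     penalty = 10 / nv("ring"))
  boost <- if (!is.null(rois$gtv)) "gtv" else "ctv"
  terms[[length(terms) + 1L]] <-
    objective_term(boost, "letd", "min", goal = 12, penalty = 0.01 / nv(boost))
  if (spec$id == "brain-like")
    for (nm in oars)
      terms[[length(terms) + 1L]] <-
        objective_term(nm, "letd", "max", goal = 1.5, penalty = 0.01 / nv(nm))
  objective_set(terms)
}

#' Boost-target ROI name of a scenario
#'
#' @param rois ROI list from [build_phantom()].
#' @return `"gtv"` when present, else `"ctv"`.
#' @export
boost_target <- function(rois) if (!is.null(rois$gtv)) "gtv" else "ctv"
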