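#' Analytical proton pencil-beam model
#'
#' Defines the machine beam model used throughout planning: a range-energy
#' power law `R = alpha * E^p` (cm of water), an analytic Bragg depth-dose
#' curve (cell-averaged electronic stopping power smeared with a Gaussian
#' range-straggling/distal-falloff kernel), a matching depth-LET_d curve
#' (dose-weighted residual-energy stopping power), and a single-Gaussian
#' lateral spot model whose sigma grows linearly with depth
#' (multiple-Coulomb-scattering term added in quadrature to the in-air sigma).
#'
#' The LET of a proton with residual energy below `let_cap_energy` is capped
#' at the stopping power evaluated at that energy; this bounds the scored
#' LET_d in the distal falloff the way a finite scoring cutoff does in
#' Monte Carlo engines.
#'
#' @param energy_min,energy_max machine energy span, MeV.
#' @param alpha,p range-energy power-law coefficients (`R[cm] = alpha * E^p`).
#'   The defaults give R(160 MeV) = 17.5 cm of water.
#' @param sigma0 in-air lateral spot sigma at isocenter, mm.
#' @param sigma_growth lateral sigma growth per mm of water-equivalent depth
#'   (dimensionless); added in quadrature to `sigma0`.
#' @param distal_falloff 80%-20% distal dose falloff floor, mm; combined in
#'   quadrature with energy-dependent range straggling.
#' @param let_cap_energy residual energy (MeV) at which the LET curve is
#'   capped.
#' @param dose_per_mu calibration: central-axis Bragg-peak dose of a
#'   unit-weight (1 MU) spot, Gy.
#' @param z_step depth-grid resolution for the tabulated curves, cm.
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(energy_min = 70, energy_max = 230,
                       alpha = 0.0022, p = 1.77,
                       sigma0 = 4, sigma_growth = 0.035,
                       distal_falloff = 3, let_cap_energy = 2,
                       dose_per_mu = 0.005, z_step = 0.05) {
  stopifnot(energy_min > 0, energy_max > energy_min, alpha > 0, p > 1,
            sigma0 > 0, sigma_growth >= 0, distal_falloff > 0,
            let_cap_energy > 0, dose_per_mu > 0, z_step > 0)
  zmax <- alpha * energy_max^p + 3
  model <- list(
    energy_min = energy_min, energy_max = energy_max,
    alpha = alpha, p = p,
    sigma0 = sigma0, sigma_growth = sigma_growth,
    distal_falloff = distal_falloff,
    let_cap_energy = let_cap_energy,
    dose_per_mu = dose_per_mu,
    z_step = z_step,
    zgrid = seq(0, zmax, by = z_step),
    cache = new.env(parent = emptyenv())
  )
  class(model) <- "beam_model"
  model
}

#' @export
print.beam_model <- function(x, ...) {
  cat("<beam_model>\n")
  cat(sprintf("  energies: %.0f-%.0f MeV (ranges %.1f-%.1f cm water)\n",
              x$energy_min, x$energy_max,
              proton_range(x, x$energy_min), proton_range(x, x$energy_max)))
  cat(sprintf("  lateral sigma: %.1f mm in air + %.3f/mm depth growth\n",
              x$sigma0, x$sigma_growth))
  cat(sprintf("  distal falloff floor: %.1f mm (80-20)\n", x$distal_falloff))
  invisible(x)
}

#' Proton range in water from the power-law fit
#'
#' @param model a `beam_model`.
#' @param energy nominal energy, MeV (vectorized).
#' @return range, cm of water.
#' @export
proton_range <- function(model, energy) model$alpha * energy^model$p

#' Nominal energy whose range equals a given water-equivalent depth
#'
#' Inverse of [proton_range()].
#' @param model a `beam_model`.
#' @param range_cm range, cm of water (vectorized).
#' @return energy, MeV.
#' @export
range_to_energy <- function(model, range_cm) (range_cm / model$alpha)^(1 / model$p)

#' Electronic stopping power of water from the power-law fit
#'
#' `S = dE/dz = 1 / (alpha * p * E^(p-1))` MeV/cm, returned in keV/um
#' (1 MeV/cm in unit-density water = 0.1 keV/um).
#' @param model a `beam_model`.
#' @param energy proton energy, MeV (vectorized).
#' @return stopping power, keV/um.
#' @export
stopping_power <- function(model, energy) {
  0.1 / (model$alpha * model$p * energy^(model$p - 1))
}

check_energy <- function(model, energy) {
  if (any(energy < model$energy_min - 1e-9) || any(energy > model$energy_max + 1e-9))
    stop(sprintf("physics-model error: energy %.1f MeV outside machine span [%g, %g]",
                 energy[which(energy < model$energy_min | energy > model$energy_max)[1]],
                 model$energy_min, model$energy_max))
  invisible(TRUE)
}

# Depth sigma (cm) of the Gaussian range-smearing kernel for range R (cm):
# quadrature of the configured distal-falloff floor and range straggling.
range_sigma <- function(model, R) {
  sig_floor <- model$distal_falloff / 1.683 / 10   # 80-20 distance -> sigma, cm
  sig_strag <- 0.012 * R^0.935
  sqrt(sig_floor^2 + sig_strag^2)
}

# Tabulated pristine depth curves for one energy, on the model z grid.
# ddd: Gy per MU (peak = dose_per_mu); letd: keV/um dose-averaged LET.
# Cell-averaged stopping power (exact integral of the integrable
# (R - z)^(1/p - 1) singularity over each cell) convolved with the Gaussian
# kernel; letd is conv(S*L)/conv(S) with L the capped residual-energy
# stopping power.
beam_curve <- function(model, energy) {
  check_energy(model, energy)
  key <- sprintf("E%.3f", energy)
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)

  z <- model$zgrid
  dz <- model$z_step
  R <- proton_range(model, energy)
  a <- model$alpha; p <- model$p
  lo <- pmin(pmax(R - (z - dz / 2), 0), R)   # residual range at cell end
  hi <- pmin(pmax(R - (z + dz / 2), 0), R)   # residual range at cell start
  # integral of S over the cell = (lo^(1/p) - hi^(1/p)) / a^(1/p); mean = /dz
  sbar <- (lo^(1 / p) - hi^(1 / p)) / a^(1 / p) / dz

  # capped LET of the residual-energy proton at each depth
  res <- pmax(R - z, 0)
  r_cap <- proton_range(model, model$let_cap_energy)
  e_res <- range_to_energy(model, pmax(res, r_cap))
  lcurve <- stopping_power(model, e_res)

  sigma <- range_sigma(model, R)
  half <- max(1L, ceiling(4 * sigma / dz))
  off <- (-half):half
  kern <- stats::dnorm(off * dz, sd = sigma) * dz
  kern <- kern / sum(kern)

  convolve_same <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(0, half))
    out <- stats::filter(xp, kern, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  d_s <- convolve_same(sbar)
  m_s <- convolve_same(sbar * lcurve)
  letd <- ifelse(d_s > max(d_s) * 1e-9, m_s / d_s, max(lcurve))
  ddd <- d_s / max(d_s) * model$dose_per_mu

  cur <- list(z = z, ddd = ddd, letd = letd, energy = energy, range = R)
  model$cache[[key]] <- cur
  cur
}

interp_curve <- function(zgrid, y, depth) {
  out <- stats::approx(zgrid, y, xout = depth, rule = 2)$y
  out[depth > max(zgrid)] <- 0
  out
}

#' Pristine Bragg depth-dose curve
#'
#' Central-axis dose per unit spot weight (MU) at a water-equivalent depth.
#'
#' @param model a `beam_model`.
#' @param energy nominal energy, MeV (scalar, must be inside the machine span).
#' @param depth water-equivalent depth, cm (vectorized, `>= 0`).
#' @return dose, Gy per MU.
#' @export
depth_dose <- function(model, energy, depth) {
  stopifnot(all(depth >= 0))
  cur <- beam_curve(model, energy)
  interp_curve(cur$z, cur$ddd, depth)
}

#' Pristine depth-LET_d curve
#'
#' Dose-averaged LET of a single pencil beam at a water-equivalent depth:
#' monotonically non-decreasing from the entrance value (the beam's stopping
#' power at nominal energy) through the distal falloff, where it saturates at
#' the capped end-of-range value.
#'
#' @inheritParams depth_dose
#' @return LET_d, keV/um.
#' @export
depth_let <- function(model, energy, depth) {
  stopifnot(all(depth >= 0))
  cur <- beam_curve(model, energy)
  n <- length(cur$z)
  out <- stats::approx(cur$z, cur$letd, xout = depth, rule = 2)$y
  out
}

# Shared curve tables for a set of energies, as matrices on the model z grid
# (the layout the compiled influence kernel consumes).
curve_tables <- function(model, energies) {
  z <- model$zgrid
  ddd <- matrix(0, length(z), length(energies))
  letd <- matrix(0, length(z), length(energies))
  for (k in seq_along(energies)) {
    cur <- beam_curve(model, energies[k])
    ddd[, k] <- cur$ddd
    letd[, k] <- cur$letd
  }
  list(z = z, ddd = ddd, letd = letd)
}
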