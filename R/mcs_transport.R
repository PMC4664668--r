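# Multiple-Coulomb-scattering broadening of a single minibeam with depth:
# scattering power, Fermi-Eyges second-moment propagation, width curves,
# width -> depth inversion, and a Monte Carlo cross-check of the moments.

.FWHM_SIGMA <- 2 * sqrt(2 * log(2)) # 2.3548..., FWHM of a unit-sigma Gaussian

# transport is stopped at this fraction of the CSDA range: end-of-range
# straggling and large-angle single scattering are outside the model
.RANGE_FRACTION <- 0.95

#' Minibeam specification
#'
#' Describes a single minibeam or a regular minibeam array: ion species,
#' kinetic energy, incident geometry (planar sheet or pencil), incident
#' width, angular divergence, and the on-center spacing and lattice of the
#' array. `spacing_on_center = 0` means a single beam.
#'
#' @param species An [ion_species()] or a species name.
#' @param energy Kinetic energy in MeV per nucleon, or an [energy_spec()].
#' @param shape `"planar"` (sheet beams in a comb) or `"pencil"`
#'   (round beams on a square lattice).
#' @param incident_width_fwhm Incident beam FWHM in mm (default 0.3 mm,
#'   the standard minibeam size).
#' @param spacing_on_center Array spacing in mm; 0 for a single beam.
#' @param angular_divergence_rms Incident angular divergence in mrad
#'   (default 0; the collimator optics are not modelled).
#' @param lattice `"none"`, `"comb"` or `"square"`; defaults to the lattice
#'   implied by `shape` when a spacing is given.
#' @param incident_profile `"gaussian"` (default) treats the incident slit
#'   profile as a Gaussian of equal FWHM; `"tophat"` convolves a flat slit
#'   with the scattering kernel instead (differs by under 5% near merge).
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec("proton", 109, shape = "pencil")
#' beam_spec("lithium7", energy_for_range(ion_species("li7"), 10),
#'           shape = "planar", spacing_on_center = 1.0)
#' @export
beam_spec <- function(species, energy, shape = c("pencil", "planar"),
                      incident_width_fwhm = 0.3, spacing_on_center = 0,
                      angular_divergence_rms = 0,
                      lattice = NULL,
                      incident_profile = c("gaussian", "tophat")) {
  if (!inherits(species, "ion_species")) species <- ion_species(species)
  if (!inherits(energy, "energy_spec")) energy <- energy_spec(energy)
  shape <- match.arg(shape)
  incident_profile <- match.arg(incident_profile)
  if (incident_width_fwhm <= 0)
    stop("incident width must be positive", call. = FALSE)
  if (spacing_on_center != 0 && spacing_on_center < incident_width_fwhm)
    stop("array spacing must be 0 or at least the incident width",
         call. = FALSE)
  if (is.null(lattice))
    lattice <- if (spacing_on_center == 0) "none"
               else if (shape == "planar") "comb" else "square"
  lattice <- match.arg(lattice, c("none", "comb", "square"))
  if (spacing_on_center > 0) {
    ok <- (shape == "planar" && lattice == "comb") ||
          (shape == "pencil" && lattice == "square")
    if (!ok) stop("planar arrays use a comb lattice, pencil arrays a square ",
                  "lattice", call. = FALSE)
  }
  structure(list(species = species, energy = energy, shape = shape,
                 incident_width_fwhm = incident_width_fwhm,
                 spacing_on_center = spacing_on_center,
                 angular_divergence_rms = angular_divergence_rms,
                 lattice = lattice, incident_profile = incident_profile),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> %s %.6g MeV/u, %s, incident FWHM %.3g mm%s\n",
    x$species$name, x$energy$kinetic_energy_per_nucleon, x$shape,
    x$incident_width_fwhm,
    if (x$spacing_on_center > 0)
      sprintf(", %.3g mm on-center (%s)", x$spacing_on_center, x$lattice)
    else " (single beam)"))
  invisible(x)
}

#' Differential Highland scattering power
#'
#' Rate of growth of the angular variance per unit path,
#' `T = (14.1 z / (p beta c))^2 / X0 * f(L)`, where the Highland logarithmic
#' correction `f(L) = (1 + log10(L/X0)/9)^2` is evaluated at the cumulative
#' water-equivalent thickness `L` traversed so far (not at the local step),
#' clamped to `[0.25, 1]`. Per-step evaluation of the Highland formula would
#' underestimate the beam spread.
#'
#' @inheritParams stopping_power
#' @param residual_E Residual kinetic energy in MeV per nucleon.
#' @param cumulative_thickness Path length traversed so far in mm.
#' @return Scattering power in rad^2/mm. Vectorised over `residual_E` and
#'   `cumulative_thickness`.
#' @export
scattering_power <- function(species, residual_E, cumulative_thickness,
                             material = water_material()) {
  stopifnot(inherits(species, "ion_species"))
  residual_E <- .as_energy(residual_E)
  if (any(residual_E < .E_MIN))
    stop("beam stopped: residual energy below the stopping-model floor",
         call. = FALSE)
  X0_mm <- material$radiation_length / material$density * 10 # mm
  corr <- (1 + log10(pmax(cumulative_thickness, 1e-9) / X0_mm) / 9)^2
  corr <- pmin(pmax(corr, 0.25), 1.0)
  (14.1 * species$z / momentum_beta(species, residual_E))^2 / X0_mm * corr
}

# incident positional variance (mm^2) implied by the incident profile
.incident_variance <- function(beam) {
  w <- beam$incident_width_fwhm
  if (beam$incident_profile == "tophat") w^2 / 12
  else (w / .FWHM_SIGMA)^2
}

#' Fermi-Eyges moment propagation
#'
#' Propagates the second moments of the beam phase space (angular variance
#' A0, position-angle covariance A1, positional variance A2) through water,
#' updating the residual energy from the CSDA range table at each step.
#' The moment recursion is the trapezoidal form of
#' `A0' = T, A1' = A0, A2' = 2 A1`, with the scattering power evaluated at
#' the mid-step energy and cumulative thickness.
#'
#' @param beam A [beam_spec()].
#' @param z_grid Depths in mm at which to report the state (defaults to a
#'   uniform grid of step `dz` up to `z_max`). Must stay below 95% of the
#'   CSDA range.
#' @param z_max Maximum depth in mm when `z_grid` is not given.
#' @param dz Integration step in mm (default 0.1).
#' @param material A [material()]; defaults to water.
#' @param scattering_power_fn Optional replacement for [scattering_power()]
#'   with the same signature (used for closed-form checks).
#' @return A data frame of class `transport_state` with columns `depth`
#'   (mm), `A0` (rad^2), `A1` (rad mm), `A2` (mm^2, including the incident
#'   variance) and `residual_energy` (MeV/u).
#' @export
propagate_moments <- function(beam, z_grid = NULL, z_max = NULL, dz = 0.1,
                              material = water_material(),
                              scattering_power_fn = NULL) {
  stopifnot(inherits(beam, "beam_spec"))
  E0 <- beam$energy$kinetic_energy_per_nucleon
  R_mm <- csda_range(beam$species, E0, material) * 10
  if (is.null(z_grid)) {
    if (is.null(z_max)) stop("give either z_grid or z_max", call. = FALSE)
    z_grid <- seq(0, z_max, by = dz)
  }
  z_grid <- sort(unique(c(0, z_grid)))
  if (max(z_grid) > .RANGE_FRACTION * R_mm)
    stop(sprintf(paste0("depth %.1f mm beyond %.0f%% of the CSDA range ",
                        "(%.1f mm): near-peak scattering is not modelled"),
                 max(z_grid), 100 * .RANGE_FRACTION, R_mm), call. = FALSE)
  # fine internal grid containing every requested depth
  zf <- sort(unique(c(seq(0, max(z_grid), by = dz), z_grid)))
  n <- length(zf)
  rt <- .range_tables(beam$species, material)
  E_mid <- rt$R_to_E(pmax(R_mm / 10 - (zf[-1] + zf[-n]) / 2 / 10, 0))
  Tfun <- if (is.null(scattering_power_fn)) scattering_power
          else scattering_power_fn
  T_mid <- Tfun(beam$species, E_mid, (zf[-1] + zf[-n]) / 2, material)
  h <- diff(zf)
  A0 <- c(0, cumsum(T_mid * h)) + (beam$angular_divergence_rms * 1e-3)^2
  A1 <- c(0, cumsum((A0[-1] + A0[-n]) / 2 * h))
  A2 <- c(0, cumsum((A1[-1] + A1[-n]) * h)) + .incident_variance(beam)
  E_res <- rt$R_to_E(pmax(R_mm / 10 - zf / 10, 0))
  out <- data.frame(depth = zf, A0 = A0, A1 = A1, A2 = A2,
                    residual_energy = E_res)
  out <- out[match(z_grid, zf), ]
  rownames(out) <- NULL
  structure(out, class = c("transport_state", "data.frame"), beam = beam)
}

# FWHM of a top-hat of full width w convolved with a Gaussian of sd s
.tophat_gauss_fwhm <- function(w, s) {
  if (s < 1e-9) return(w)
  f <- function(x) pnorm((x + w / 2) / s) - pnorm((x - w / 2) / s)
  peak <- f(0)
  2 * stats::uniroot(function(x) f(x) - peak / 2, c(0, w / 2 + 10 * s),
                     tol = 1e-9)$root
}

# total lateral FWHM (mm) from a transport state
.fwhm_from_state <- function(state, beam) {
  v_inc <- .incident_variance(beam)
  v_mcs <- pmax(state$A2 - v_inc, 0)
  if (beam$incident_profile == "gaussian") {
    sqrt(beam$incident_width_fwhm^2 + .FWHM_SIGMA^2 * v_mcs)
  } else {
    vapply(v_mcs, function(v)
      .tophat_gauss_fwhm(beam$incident_width_fwhm, sqrt(v)), numeric(1))
  }
}

#' Beam-width (FWHM) versus depth
#'
#' Total lateral FWHM of a single minibeam as a function of water depth:
#' the incident width combined in quadrature with the Gaussian
#' multiple-scattering spread from [propagate_moments()] (for a top-hat
#' incident profile the convolution is evaluated numerically). Planar beams
#' use the 1-D variance; a pencil beam's transverse FWHM of the radial
#' profile is identical because the scattering kernel is isotropic.
#'
#' @inheritParams propagate_moments
#' @param z_max Maximum depth in mm.
#' @return An object of class `width_curve`: a data frame with columns
#'   `depth` (mm) and `fwhm` (mm), with the generating beam attached as an
#'   attribute.
#' @examples
#' wc <- width_curve(beam_spec("proton", 109), z_max = 40)
#' head(wc)
#' @export
width_curve <- function(beam, z_max, dz = 0.1, material = water_material()) {
  st <- propagate_moments(beam, z_max = z_max, dz = dz, material = material)
  out <- data.frame(depth = st$depth, fwhm = .fwhm_from_state(st, beam))
  structure(out, class = c("width_curve", "data.frame"),
            beam = beam, dz = dz)
}

#' @export
print.width_curve <- function(x, ...) {
  b <- attr(x, "beam")
  cat(sprintf("<width_curve> %s %.6g MeV/u: %d depths, %.3g -> %.3g mm FWHM\n",
              b$species$name, b$energy$kinetic_energy_per_nucleon,
              nrow(x), x$fwhm[1], x$fwhm[nrow(x)]))
  invisible(x)
}

#' @export
plot.width_curve <- function(x, ...) {
  graphics::plot(x$depth, x$fwhm, type = "l", xlab = "depth in water (mm)",
                 ylab = "beam FWHM (mm)", ...)
  invisible(x)
}

# condition helper: width/merge not reached before the transport limit
.not_reached <- function(what, limit_mm) {
  warning(sprintf("%s not reached before %.1f mm (95%% of range)",
                  what, limit_mm),
          call. = FALSE)
  NA_real_
}

#' Depth at which a beam reaches a target width
#'
#' Inverts the (monotone) width curve by bisection on a monotone spline.
#' Returns `NA` with a warning when the width is not reached before 95% of
#' the CSDA range.
#'
#' @inheritParams propagate_moments
#' @param target_fwhm Target total FWHM in mm; must be at least the
#'   incident width.
#' @return Depth in mm.
#' @examples
#' depth_for_width(beam_spec("proton", 109), 0.7)
#' @export
depth_for_width <- function(beam, target_fwhm, dz = 0.1,
                            material = water_material()) {
  stopifnot(inherits(beam, "beam_spec"))
  if (target_fwhm < beam$incident_width_fwhm)
    stop("target width below the incident width", call. = FALSE)
  if (target_fwhm == beam$incident_width_fwhm) return(0)
  R_mm <- csda_range(beam$species, beam$energy, material) * 10
  z_lim <- .RANGE_FRACTION * R_mm
  wc <- width_curve(beam, z_max = z_lim, dz = dz, material = material)
  if (max(wc$fwhm) < target_fwhm)
    return(.not_reached(sprintf("FWHM %.3g mm", target_fwhm), z_lim))
  sp <- stats::splinefun(wc$depth, wc$fwhm, method = "hyman")
  stats::uniroot(function(z) sp(z) - target_fwhm, range(wc$depth),
                 tol = 1e-7)$root
}

#' Monte Carlo transport oracle
#'
#' Condensed-history random walk through water: at each step the particle
#' receives a Gaussian angular kick with variance `T * dz` (scattering power
#' at the mid-step energy and cumulative thickness) and then drifts. This
#' discretisation matches the trapezoidal Fermi-Eyges recursion of
#' [propagate_moments()] to second order in the step, so the sampled lateral
#' spread checks the moment transport independently of its closed-form
#' bookkeeping. One transverse coordinate is simulated; the scattering
#' kernel is isotropic, so the transverse FWHM of a pencil beam's radial
#' profile equals the planar 1-D FWHM.
#'
#' @inheritParams propagate_moments
#' @param n_histories Number of particle histories (at least 1000).
#' @param seed Integer seed; the same seed reproduces the samples
#'   bit-for-bit. The caller's RNG state is left untouched.
#' @param z_planes Depths in mm at which lateral positions are recorded.
#' @return An object of class `mc_transport`: a list with `z_planes`,
#'   `samples` (matrix, histories x planes, lateral position in mm
#'   relative to the beam axis, incident width included), `fwhm`
#'   (Gaussian-equivalent empirical FWHM per plane) and `fwhm_se`
#'   (its standard error), plus the seed and beam as attributes.
#' @export
mc_transport <- function(beam, n_histories, seed, z_planes, dz = 0.05,
                         material = water_material()) {
  stopifnot(inherits(beam, "beam_spec"), n_histories >= 1000)
  z_planes <- sort(z_planes)
  E0 <- beam$energy$kinetic_energy_per_nucleon
  R_mm <- csda_range(beam$species, E0, material) * 10
  if (max(z_planes) > .RANGE_FRACTION * R_mm)
    stop("plane beyond 95% of the CSDA range", call. = FALSE)
  # align the step grid with the requested planes
  zf <- sort(unique(c(seq(0, max(z_planes), by = dz), z_planes)))
  n <- length(zf)
  rt <- .range_tables(beam$species, material)
  mid <- (zf[-1] + zf[-n]) / 2
  E_mid <- rt$R_to_E(pmax(R_mm / 10 - mid / 10, 0))
  T_mid <- scattering_power(beam$species, E_mid, mid, material)
  h <- diff(zf)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  x <- rnorm(n_histories, 0, sqrt(.incident_variance(beam)))
  theta <- rnorm(n_histories, 0, beam$angular_divergence_rms * 1e-3)
  samples <- matrix(NA_real_, n_histories, length(z_planes))
  plane_idx <- match(z_planes, zf)
  next_plane <- 1L
  if (plane_idx[1] == 1L) { samples[, 1] <- x; next_plane <- 2L }
  for (i in seq_len(n - 1)) {
    theta <- theta + rnorm(n_histories, 0, sqrt(T_mid[i] * h[i]))
    x <- x + theta * h[i]
    while (next_plane <= length(z_planes) && plane_idx[next_plane] == i + 1L) {
      samples[, next_plane] <- x
      next_plane <- next_plane + 1L
    }
  }
  sds <- apply(samples, 2, stats::sd)
  structure(list(z_planes = z_planes, samples = samples,
                 fwhm = .FWHM_SIGMA * sds,
                 fwhm_se = .FWHM_SIGMA * sds / sqrt(2 * n_histories)),
            class = "mc_transport", beam = beam, seed = as.integer(seed),
            dz = dz)
}

#' @export
print.mc_transport <- function(x, ...) {
  cat(sprintf("<mc_transport> %d histories, %d planes, seed %d\n",
              nrow(x$samples), length(x$z_planes), attr(x, "seed")))
  cat("  FWHM (mm):", paste(sprintf("%.3f", x$fwhm), collapse = ", "), "\n")
  invisible(x)
}
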