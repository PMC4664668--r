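# Central-axis depth-dose: analytic pristine Bragg curves, spread-out Bragg
# peak (SOBP) construction by nonnegative energy-layer weighting, a textbook
# megavoltage photon comparison curve, and the three-curve comparison that
# contrasts a solid-beam SOBP with the estimated biological dose of a
# merging minibeam array.

# range-straggling sigma (mm) for a given CSDA range (cm); the proton
# coefficient sigma_R = 0.012 * R^0.935 is scaled by 1/sqrt(a) for heavier
# ions (straggling variance per unit energy loss falls with mass)
.straggling_sigma_mm <- function(species, R_cm) {
  0.012 * R_cm^0.935 * 10 / sqrt(species$a)
}

#' Depth-dose curve container
#'
#' @param depths Depths in mm.
#' @param dose Relative dose (>= 0).
#' @param label Curve label.
#' @return An object of class `depth_dose_curve` (a data frame).
#' @export
depth_dose_curve <- function(depths, dose, label = "") {
  stopifnot(length(depths) == length(dose), all(dose >= -1e-12))
  structure(data.frame(depth = depths, dose = pmax(dose, 0)),
            class = c("depth_dose_curve", "data.frame"), label = label)
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> '%s': %d depths, peak %.3g at %.1f mm\n",
              attr(x, "label"), nrow(x), max(x$dose),
              x$depth[which.max(x$dose)]))
  invisible(x)
}

#' @export
plot.depth_dose_curve <- function(x, ...) {
  graphics::plot(x$depth, x$dose, type = "l", xlab = "depth (mm)",
                 ylab = "relative dose", ...)
  invisible(x)
}

#' Pristine Bragg curve
#'
#' Central-axis depth dose proportional to the stopping power at the
#' residual energy, convolved with a Gaussian range-straggling kernel
#' (sigma_R = 0.012 R^0.935 cm for protons, scaled by 1/sqrt(a) for
#' heavier ions). An explicit beam energy spread (FWHM in MeV/u) widens the
#' kernel via the range-energy slope. Nuclear fragmentation tails are not
#' modelled. The curve is normalised to a peak dose of 1.
#'
#' @inheritParams stopping_power
#' @param E Kinetic energy in MeV/u or an [energy_spec()].
#' @param z_grid Depths in mm; defaults to `[0, range + 5 mm]` in 0.1-mm
#'   steps.
#' @return A [depth_dose_curve()].
#' @export
bragg_curve <- function(species, E, z_grid = NULL,
                        material = water_material()) {
  stopifnot(inherits(species, "ion_species"))
  if (!inherits(E, "energy_spec")) E <- energy_spec(E)
  E0 <- E$kinetic_energy_per_nucleon
  R_cm <- csda_range(species, E0, material)
  R_mm <- R_cm * 10
  if (is.null(z_grid)) z_grid <- seq(0, R_mm + 5, by = 0.1)
  dz <- 0.1
  zf <- seq(0, max(z_grid) + 1, by = dz)
  rt <- .range_tables(species, material)
  res_R <- R_cm - zf / 10
  raw <- numeric(length(zf))
  live <- res_R > rt$E_to_R(.E_MIN + 1e-9)
  raw[live] <- stopping_power(species, rt$R_to_E(res_R[live]), material)
  sigma <- .straggling_sigma_mm(species, R_cm)
  if (E$energy_spread_fwhm > 0) {
    # convert energy spread to range spread via dR/dE
    dRdE <- (rt$E_to_R(E0 + 0.5) - rt$E_to_R(E0 - 0.5)) * 10 # mm per MeV/u
    sigma <- sqrt(sigma^2 + (E$energy_spread_fwhm / .FWHM_SIGMA * dRdE)^2)
  }
  kx <- seq(-4 * sigma, 4 * sigma, by = dz)
  kern <- stats::dnorm(kx, 0, sigma); kern <- kern / sum(kern)
  pad <- length(kx) %/% 2
  ext <- c(rep(raw[1], pad), raw, rep(0, pad))
  smooth <- stats::filter(ext, kern, sides = 2)[(pad + 1):(pad + length(zf))]
  dose <- stats::approx(zf, smooth, z_grid, yleft = smooth[1], yright = 0)$y
  dose[z_grid > R_mm + 4 * sigma] <- 0
  depth_dose_curve(z_grid, dose / max(dose),
                   label = sprintf("%s %.5g MeV/u", species$name, E0))
}

#' Spread-out Bragg peak construction
#'
#' Builds an SOBP covering `[proximal, distal]` mm: layer energies are
#' chosen so the pristine peaks (CSDA ranges) are equally spaced across the
#' span, and layer weights are solved by nonnegative least squares so the
#' plateau is flat. If the flatness target `(max - min)/mean <= 3%` cannot
#' be met with the requested number of layers, the best-achieved flatness
#' is reported with a warning.
#'
#' @inheritParams stopping_power
#' @param proximal,distal Plateau span in mm (`distal > proximal`).
#' @param n_layers Number of energy layers (>= 2; 1 gives the pristine
#'   distal curve).
#' @param z_grid Depths in mm for the composite curve; defaults to
#'   `[0, distal + 10 mm]` in 0.2-mm steps.
#' @param flatness_target Plateau flatness goal (default 0.03).
#' @return An object of class `sobp`: a list with `species`, `energies`
#'   (MeV/u), `weights` (nonnegative, plateau mean normalised to 1),
#'   `curve` (a [depth_dose_curve()]), `flatness`, `proximal`, `distal`.
#' @examples
#' s <- build_sobp(ion_species("proton"), 55, 80, n_layers = 17)
#' s$flatness
#' @export
build_sobp <- function(species, proximal, distal, n_layers = 17,
                       z_grid = NULL, flatness_target = 0.03,
                       material = water_material()) {
  stopifnot(inherits(species, "ion_species"), distal > proximal,
            n_layers >= 1)
  peaks_mm <- seq(proximal, distal, length.out = max(n_layers, 2))
  if (n_layers == 1) peaks_mm <- distal
  if (is.null(z_grid)) z_grid <- seq(0, distal + 10, by = 0.2)
  # straggling pulls the dose maximum upstream of the CSDA range; place the
  # layers by their actual peak positions with one corrective pass
  ranges_mm <- peaks_mm
  spacing <- if (length(peaks_mm) > 1) min(diff(peaks_mm)) else Inf
  tol <- max(0.2 * spacing, min(diff(z_grid)))
  layers <- NULL
  energies <- NULL
  best_err <- Inf
  for (pass in 1:4) {
    e_try <- energy_for_range(species, ranges_mm / 10, material)
    l_try <- vapply(e_try, function(e)
      bragg_curve(species, e, z_grid, material)$dose,
      numeric(length(z_grid)))
    found <- z_grid[apply(l_try, 2, which.max)]
    err <- max(abs(found - peaks_mm))
    if (err < best_err) {
      best_err <- err
      energies <- e_try
      layers <- l_try
    }
    if (err < tol) break
    ranges_mm <- ranges_mm + (peaks_mm - found)
  }
  if (n_layers == 1) {
    w <- 1
    dose <- layers[, 1]
  } else {
    plateau <- z_grid >= proximal & z_grid <= distal
    A <- layers[plateau, , drop = FALSE]
    w <- pracma::lsqnonneg(A, rep(1, nrow(A)))$x
    dose <- as.numeric(layers %*% w)
  }
  plateau <- z_grid >= proximal & z_grid <= distal
  pl <- dose[plateau]
  flat <- (max(pl) - min(pl)) / mean(pl)
  if (flat > flatness_target)
    warning(sprintf(paste0("plateau flatness %.1f%% misses the %.0f%% ",
                           "target with %d layers"),
                    100 * flat, 100 * flatness_target, n_layers),
            call. = FALSE)
  # normalise the plateau mean to 1
  sc <- 1 / mean(pl)
  structure(list(species = species, energies = energies, weights = w * sc,
                 curve = depth_dose_curve(z_grid, dose * sc,
                                          label = sprintf("%s SOBP %g-%g mm",
                                                          species$name,
                                                          proximal, distal)),
                 flatness = flat, proximal = proximal, distal = distal),
            class = "sobp")
}

#' @export
print.sobp <- function(x, ...) {
  cat(sprintf(paste0("<sobp> %s, plateau %g-%g mm, %d layers ",
                     "(%.4g-%.4g MeV/u), flatness %.2f%%\n"),
              x$species$name, x$proximal, x$distal, length(x$energies),
              min(x$energies), max(x$energies), 100 * x$flatness))
  invisible(x)
}

#' Megavoltage photon depth dose
#'
#' Textbook build-up-plus-exponential model for a 10-MV x-ray beam,
#' `D(z) = (1 - exp(-b z)) exp(-mu z)`, with the build-up coefficient
#' solved so the maximum sits at `d_max` (default 25 mm) and an effective
#' attenuation `mu_eff` of 0.0045/mm, normalised to 1 at `d_max`. Only the
#' 10-MV dialect is supported.
#'
#' @param nominal_energy Nominal accelerating potential in MV (must be 10).
#' @param z_grid Depths in mm.
#' @param d_max Build-up depth in mm (default 25).
#' @param mu_eff Effective attenuation coefficient in 1/mm
#'   (default 0.0045).
#' @return A [depth_dose_curve()].
#' @export
photon_depth_dose <- function(nominal_energy = 10, z_grid,
                              d_max = 25, mu_eff = 0.0045) {
  if (nominal_energy != 10)
    stop("only the 10-MV photon model is supported", call. = FALSE)
  # solve the build-up coefficient for the stated d_max
  b <- stats::uniroot(function(b)
    b * exp(-b * d_max) - mu_eff * (1 - exp(-b * d_max)),
    c(1e-4, 2), tol = 1e-10)$root
  d <- (1 - exp(-b * z_grid)) * exp(-mu_eff * z_grid)
  dmaxval <- (1 - exp(-b * d_max)) * exp(-mu_eff * d_max)
  depth_dose_curve(z_grid, d / dmaxval, label = "10-MV x-rays")
}

#' Three-curve depth-dose comparison
#'
#' Composes the comparison of (a) a 10-MV photon beam, (b) a solid ion
#' beam with the given SOBP, and (c) the estimated biological dose of a
#' minibeam array that merges into a solid beam proximal to the target and
#' undergoes the same Bragg-peak spreading. Proximal to the merge depth the
#' minibeam curve is the physical curve scaled by the biological entrance
#' ratio, ramped linearly to 1 at the merge depth (the endpoints are the
#' modelled quantities; the ramp shape is a presentation choice); beyond
#' the merge depth the two ion curves coincide. All three curves are
#' normalised to a mean of 1 over the SOBP plateau.
#'
#' @param sobp A [build_sobp()] result.
#' @param beam A [beam_spec()] describing the minibeam array (its merge
#'   depth must be proximal to the SOBP).
#' @param sparing_factor Tissue-sparing factor (default 7).
#' @param merge_rule Merge rule passed to [merge_depth()].
#' @param material A [material()].
#' @return A list of class `depth_dose_comparison` with elements `photon`,
#'   `solid`, `minibeam` (three [depth_dose_curve()]s on the SOBP grid),
#'   `merge_depth_mm` and `entrance_ratio`.
#' @export
compose_depth_dose_comparison <- function(sobp, beam, sparing_factor = 7,
                                          merge_rule = "valley_peak_threshold",
                                          material = water_material()) {
  stopifnot(inherits(sobp, "sobp"), inherits(beam, "beam_spec"))
  md <- merge_depth(beam, rule = merge_rule, material = material)
  zm <- md$merge_depth
  if (!is.finite(zm) || zm >= sobp$proximal)
    stop("planning error: minibeam merge depth must be proximal to the ",
         "SOBP", call. = FALSE)
  f <- incident_dose_factor(beam$shape, beam$incident_width_fwhm,
                            beam$spacing_on_center)
  r <- biological_entrance_ratio(round(f, 1), sparing_factor)
  z <- sobp$curve$depth
  ramp <- ifelse(z >= zm, 1, r + (1 - r) * z / zm)
  photon <- photon_depth_dose(10, z)
  pl <- z >= sobp$proximal & z <= sobp$distal
  photon$dose <- photon$dose / mean(photon$dose[pl])
  solid <- sobp$curve
  mini <- depth_dose_curve(z, solid$dose * ramp,
                           label = "minibeam array (estimated biological)")
  structure(list(photon = photon, solid = solid, minibeam = mini,
                 merge_depth_mm = zm, entrance_ratio = r),
            class = "depth_dose_comparison")
}

#' @export
print.depth_dose_comparison <- function(x, ...) {
  cat(sprintf(paste0("<depth_dose_comparison> merge at %.1f mm, entrance ",
                     "ratio %.2f\n"), x$merge_depth_mm, x$entrance_ratio))
  invisible(x)
}

#' @export
plot.depth_dose_comparison <- function(x, ...) {
  rng <- range(x$photon$dose, x$solid$dose, x$minibeam$dose)
  graphics::plot(x$solid$depth, x$solid$dose, type = "l", ylim = rng,
                 xlab = "depth (mm)", ylab = "relative dose", ...)
  graphics::lines(x$photon$depth, x$photon$dose, lty = 2)
  graphics::lines(x$minibeam$depth, x$minibeam$dose, lty = 3)
  graphics::legend("topleft", c("solid ion SOBP", "10-MV x-rays",
                                "minibeam (biological)"), lty = 1:3,
                   bty = "n")
  invisible(x)
}
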