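# Array-level dosimetry: lateral dose profiles of minibeam combs and
# lattices, peak-to-valley dose ratio, merge depth, and the collimator-yield
# and incident-dose bookkeeping used to estimate biological entrance doses.

#' Lateral dose profile of a minibeam array
#'
#' Superposes per-beam lateral kernels (Gaussians whose FWHM comes from
#' [width_curve()] at the requested depth) at comb sites (planar arrays) or
#' square-lattice sites (pencil arrays). Planar profiles are evaluated
#' along the periodicity axis; pencil profiles along a lattice row, with
#' off-row lattice sites included. Profiles are normalised so a single
#' beam's central-axis entrance dose equals 1, which makes the per-beam
#' amplitude decay like the inverse (planar) or inverse-squared (pencil)
#' width ratio as the beams broaden: scattering redistributes dose
#' laterally without absorbing it.
#'
#' @param beam A [beam_spec()] with a positive `spacing_on_center` (unless
#'   `n_beams = 1`).
#' @param depth Depth in mm (within transport validity).
#' @param n_beams Number of beams (comb) or lattice columns (square);
#'   odd, at least 3, so one beam is centred (1 gives a single beam).
#' @param grid_resolution Lateral grid step in mm (default 0.01).
#' @param material A [material()]; defaults to water.
#' @return An object of class `lateral_profile`: a data frame with columns
#'   `position` (mm) and `dose` (relative), with `depth`, `spacing` and the
#'   beam attached as attributes.
#' @export
array_profile <- function(beam, depth, n_beams = 15, grid_resolution = 0.01,
                          material = water_material()) {
  stopifnot(inherits(beam, "beam_spec"))
  if (n_beams != 1 && (n_beams < 3 || n_beams %% 2 == 0))
    stop("n_beams must be 1 or an odd number >= 3", call. = FALSE)
  s <- beam$spacing_on_center
  if (n_beams > 1 && s <= 0)
    stop("array profile needs a positive on-center spacing", call. = FALSE)
  st <- propagate_moments(beam, z_grid = depth, dz = 0.1, material = material)
  fw <- .fwhm_from_state(st, beam)[nrow(st)]
  sigma <- fw / .FWHM_SIGMA
  sigma0 <- beam$incident_width_fwhm / .FWHM_SIGMA
  half_span <- if (n_beams == 1) 4 * fw else (n_beams - 1) / 2 * s + 2 * fw
  x <- seq(-half_span, half_span, by = grid_resolution)
  k <- if (n_beams == 1) 0 else seq(-(n_beams - 1) / 2, (n_beams - 1) / 2)
  if (beam$shape == "planar" || n_beams == 1) {
    amp <- if (beam$shape == "planar") sigma0 / sigma else (sigma0 / sigma)^2
    dose <- rowSums(vapply(k, function(j)
      amp * exp(-(x - j * s)^2 / (2 * sigma^2)), numeric(length(x))))
  } else {
    # square lattice: evaluate along the central row, summing lattice rows
    amp <- (sigma0 / sigma)^2
    nrow_lat <- ceiling(6 * sigma / s)
    rows <- seq(-nrow_lat, nrow_lat)
    row_w <- exp(-(rows * s)^2 / (2 * sigma^2))
    dose <- rowSums(vapply(k, function(j)
      amp * exp(-(x - j * s)^2 / (2 * sigma^2)), numeric(length(x))))
    dose <- dose * sum(row_w)
  }
  structure(data.frame(position = x, dose = dose),
            class = c("lateral_profile", "data.frame"),
            depth = depth, spacing = s, beam = beam,
            grid_resolution = grid_resolution)
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf("<lateral_profile> depth %.2f mm, %d points, peak %.4g\n",
              attr(x, "depth"), nrow(x), max(x$dose)))
  invisible(x)
}

#' @export
plot.lateral_profile <- function(x, ...) {
  graphics::plot(x$position, x$dose, type = "l",
                 xlab = "lateral position (mm)", ylab = "relative dose", ...)
  invisible(x)
}

#' Peak-to-valley dose ratio
#'
#' Mean interior peak dose over mean interior valley (midpoint between
#' neighbouring peaks) dose, measured on the three central periods of the
#' array only, to avoid edge effects. A merged profile (no modulation above
#' grid noise) returns 1 with attribute `merged = TRUE`.
#'
#' @param profile A [array_profile()] result with at least 3 interior peaks.
#' @return A number >= 1 of class `numeric`, with attribute `merged`.
#' @export
pvdr <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  s <- attr(profile, "spacing")
  if (s <= 0) stop("PVDR needs an array profile", call. = FALSE)
  at <- function(x0) {
    # max/min within a small window centred on the nominal site
    w <- which(abs(profile$position - x0) <= s / 4)
    c(max(profile$dose[w]), min(profile$dose[w]))
  }
  peaks <- vapply(c(-1, 0, 1) * s, function(x0) at(x0)[1], numeric(1))
  valleys <- vapply(c(-1.5, -0.5, 0.5, 1.5) * s,
                    function(x0) at(x0)[2], numeric(1))
  p <- mean(peaks); v <- mean(valleys)
  if (p - v <= 1e-6 * p)
    return(structure(1.0, merged = TRUE))
  structure(max(p / v, 1.0), merged = FALSE)
}

#' Merge depth of a minibeam array
#'
#' Depth at which the broadened minibeams form an effectively solid field.
#' Both operational rules are computed and returned: the valley rule (the
#' default: smallest depth where the valley-to-peak ratio of the lateral
#' profile reaches `threshold`, found by bisection) and the FWHM rule
#' (depth where the single-beam FWHM equals the on-center spacing, via
#' [depth_for_width()]). `rule` selects which one populates `merge_depth`.
#'
#' @inheritParams array_profile
#' @param rule `"valley_peak_threshold"` (default) or
#'   `"fwhm_equals_spacing"`.
#' @param threshold Valley/peak ratio defining "merged" (default 0.95).
#' @param n_beams Beams used for the valley-rule profiles.
#' @return An object of class `merge_report`: a list with `merge_depth`
#'   (mm, under the selected rule), `merge_depth_fwhm_rule`,
#'   `merge_depth_valley_rule`, `rule` and `criterion_parameters`.
#'   Depths are `NA` (with a warning) when not reached before 95% of range.
#' @examples
#' b <- beam_spec("proton", energy_for_range(ion_species("proton"), 10),
#'                shape = "planar", spacing_on_center = 1.0)
#' merge_depth(b)
#' @export
merge_depth <- function(beam, rule = c("valley_peak_threshold",
                                       "fwhm_equals_spacing"),
                        threshold = 0.95, n_beams = 15,
                        material = water_material()) {
  stopifnot(inherits(beam, "beam_spec"))
  rule <- match.arg(rule)
  s <- beam$spacing_on_center
  if (s <= 0) stop("merge depth needs a positive spacing", call. = FALSE)
  z_lim <- .RANGE_FRACTION * csda_range(beam$species, beam$energy,
                                        material) * 10
  d_fwhm <- if (s <= beam$incident_width_fwhm) 0
            else depth_for_width(beam, s, material = material)
  vp <- function(z) {
    r <- pvdr(array_profile(beam, z, n_beams = n_beams,
                            material = material))
    1 / as.numeric(r)
  }
  d_valley <- if (vp(0) >= threshold) 0
  else if (vp(z_lim) < threshold)
    .not_reached(sprintf("valley/peak %.2f", threshold), z_lim)
  else stats::uniroot(function(z) vp(z) - threshold, c(0, z_lim),
                      tol = 0.01)$root
  structure(list(
    merge_depth = if (rule == "valley_peak_threshold") d_valley else d_fwhm,
    merge_depth_fwhm_rule = d_fwhm,
    merge_depth_valley_rule = d_valley,
    rule = rule,
    criterion_parameters = list(valley_peak_threshold = threshold)),
    class = "merge_report", beam = beam)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("<merge_report> merge depth %.1f mm (%s)\n",
                     "  fwhm-equals-spacing rule: %.1f mm\n",
                     "  valley/peak >= %.2f rule: %.1f mm\n"),
              x$merge_depth, x$rule, x$merge_depth_fwhm_rule,
              x$criterion_parameters$valley_peak_threshold,
              x$merge_depth_valley_rule))
  invisible(x)
}

#' Collimator yield
#'
#' Geometric open-area fraction of the collimator producing the array:
#' `width/spacing` for a multislit (planar) collimator and
#' `pi (width/2)^2 / spacing^2` for a pinhole lattice (pencil beams on a
#' square lattice).
#'
#' @param shape `"planar"` or `"pencil"`.
#' @param width Beam (slit or pinhole) width in mm.
#' @param spacing On-center spacing in mm (must be >= width).
#' @return The open fraction in (0, 1].
#' @examples
#' collimator_yield("pencil", 0.3, 0.5) # 28.3%
#' collimator_yield("pencil", 0.3, 0.7) # 14.4%
#' @export
collimator_yield <- function(shape = c("planar", "pencil"), width, spacing) {
  shape <- match.arg(shape)
  if (width <= 0 || spacing < width)
    stop("need spacing >= width > 0", call. = FALSE)
  if (shape == "planar") width / spacing
  else pi * (width / 2)^2 / spacing^2
}

#' Incident-dose factor of a minibeam array
#'
#' Factor by which the in-beam incident dose must exceed a solid beam's to
#' deliver the same field-averaged dose: the reciprocal of the collimator
#' yield. Exact value returned; [dose_bookkeeping()] rounds to one decimal
#' for reporting.
#'
#' @inheritParams collimator_yield
#' @return The dimensionless factor `1/yield`.
#' @examples
#' incident_dose_factor("planar", 0.3, 0.7) # 2.33
#' @export
incident_dose_factor <- function(shape = c("planar", "pencil"), width,
                                 spacing) {
  1 / collimator_yield(shape, width, spacing)
}

#' Estimated biological entrance-dose ratio
#'
#' The minibeam array's estimated biological entrance dose relative to a
#' solid beam delivering the same target dose: the incident-dose factor
#' divided by the tissue-sparing factor. The ratio applies proximal to the
#' merge depth; beyond it the field is solid and the ratio is 1.
#'
#' @param factor Incident-dose factor (from [incident_dose_factor()]).
#' @param sparing_factor Tissue-sparing factor (tolerated minibeam dose
#'   over tolerated solid-beam dose; must be >= 1, default 7).
#' @return The dimensionless ratio.
#' @examples
#' biological_entrance_ratio(2.3, 7.0) # 0.33
#' @export
biological_entrance_ratio <- function(factor, sparing_factor = 7) {
  if (sparing_factor < 1)
    stop("sparing factor must be >= 1", call. = FALSE)
  factor / sparing_factor
}

#' Incident-dose bookkeeping for a minibeam array
#'
#' Collects the closed-form dose arithmetic for one array geometry:
#' collimator yield, incident-dose factor, broadening dilution
#' (spacing/width), sparing factor and the biological entrance ratio.
#' The `report` element rounds factors to one decimal and the entrance
#' ratio to two, the precision used when quoting them.
#'
#' @inheritParams collimator_yield
#' @param sparing_factor Tissue-sparing factor (default 7).
#' @return An object of class `dose_bookkeeping`: exact values plus a
#'   one-decimal `report` list.
#' @examples
#' dose_bookkeeping("planar", 0.3, 0.7)
#' @export
dose_bookkeeping <- function(shape = c("planar", "pencil"), width, spacing,
                             sparing_factor = 7) {
  shape <- match.arg(shape)
  y <- collimator_yield(shape, width, spacing)
  f <- 1 / y
  out <- list(
    collimator_yield = y,
    incident_dose_factor = f,
    dilution_factor = spacing / width,
    sparing_factor = sparing_factor,
    biological_entrance_ratio = f / sparing_factor)
  f1 <- round(f, 1)
  out$report <- list(
    collimator_yield_pct = round(100 * y, 1),
    incident_dose_factor = f1,
    dilution_factor = round(spacing / width, 2),
    biological_entrance_ratio = round(f1 / sparing_factor, 2))
  structure(out, class = "dose_bookkeeping", shape = shape,
            width = width, spacing = spacing)
}

#' @export
print.dose_bookkeeping <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<dose_bookkeeping> %s, %.2g mm / %.2g mm on-center\n",
                     "  collimator yield:        %.1f%%\n",
                     "  incident-dose factor:    %.1f\n",
                     "  broadening dilution:     %.2f\n",
                     "  sparing factor:          %.1f\n",
                     "  biological entrance ratio: %.2f\n"),
              attr(x, "shape"), attr(x, "width"), attr(x, "spacing"),
              r$collimator_yield_pct, r$incident_dose_factor,
              r$dilution_factor, x$sparing_factor,
              r$biological_entrance_ratio))
  invisible(x)
}

#' Array dose map (depth x lateral)
#'
#' Stacks [array_profile()] slices over a grid of depths into a 2-D
#' relative dose map.
#'
#' @inheritParams array_profile
#' @param depths Depths in mm.
#' @return An object of class `array_dose_map`: a list with `depths`,
#'   `positions` and a `dose` matrix (depths x positions).
#' @export
array_dose_map <- function(beam, depths, n_beams = 15,
                           grid_resolution = 0.05,
                           material = water_material()) {
  profs <- lapply(depths, function(d)
    array_profile(beam, d, n_beams = n_beams,
                  grid_resolution = grid_resolution, material = material))
  # common lateral grid: widest profile's grid
  pos <- profs[[which.max(vapply(profs, nrow, integer(1)))]]$position
  dose <- t(vapply(profs, function(p)
    approx(p$position, p$dose, pos, yleft = 0, yright = 0)$y,
    numeric(length(pos))))
  structure(list(depths = depths, positions = pos, dose = dose),
            class = "array_dose_map", beam = beam)
}

#' @export
print.array_dose_map <- function(x, ...) {
  cat(sprintf("<array_dose_map> %d depths x %d lateral points\n",
              length(x$depths), length(x$positions)))
  invisible(x)
}

#' @export
plot.array_dose_map <- function(x, ...) {
  graphics::image(x$depths, x$positions, x$dose,
                  xlab = "depth (mm)", ylab = "lateral position (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
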