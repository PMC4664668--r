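# Geometry and dose bookkeeping for interleaved minibeam arrays: coverage
# verification at the target-proximal edge, maximum allowable proximal
# depth, composite 2-D dose maps, and the carbon incident-dose factor pair.

.DIRECTIONS <- c("+x", "-x", "+y", "-y")

#' Interleaved minibeam-array treatment plan
#'
#' Describes 2- or 4-directional interleaving of planar minibeam arrays in
#' an axial plane: opposing pairs enter along +x/-x and +y/-y, and within
#' each 90-degree pair one array's minibeam planes are offset by half the
#' other's on-center spacing so the planes interleave at the target. The
#' beam energy of each array is set so its range equals the distance from
#' its entry surface to the distal face of the target box (the distal SOBP
#' layer; all shallower layers traverse the proximal edge at no greater
#' width).
#'
#' @param species An [ion_species()] or name (carbon-12 for the reference
#'   geometry).
#' @param target_center `(x, y)` centre of the target box in mm (axial
#'   plane coordinates, phantom centred at the origin).
#' @param target_size `(dx, dy)` full widths of the target box in mm.
#' @param phantom_half_size Distance from the phantom centre to each entry
#'   surface in mm.
#' @param incident_width_fwhm Incident minibeam FWHM in mm (default 0.3).
#' @param spacing_on_center On-center plane spacing in mm (default 1.05).
#' @param directions Subset of `c("+x","-x","+y","-y")`; both members of a
#'   90-degree pair are `(+x, +y)` and `(-x, -y)`.
#' @param pedestal_dose_gy Incident in-beam ("pedestal") physical dose per
#'   array in Gy (default 14).
#' @param pedestal_to_sobp_ratio SOBP plateau dose delivered per
#'   interleaved 90-degree pair, as a multiple of the pedestal dose
#'   (default 20/14; this depends on the SOBP weighting and is a plan
#'   input, not computed).
#' @param rbe Scalar relative biological effectiveness at the target
#'   (default 3).
#' @param width_limit Maximum tolerable minibeam width at the
#'   target-proximal edge in mm (default 0.7, where the tissue-sparing
#'   effect starts to fade).
#' @param abut_tolerance Fractional tolerance on the abutment criterion:
#'   planes count as abutting when the beam FWHM at the proximal edge is at
#'   least `(1 - abut_tolerance) * spacing/2` (default 0.05); overlap
#'   beyond `(1 + overlap_tolerance) * spacing/2` is flagged as an
#'   over-dose seam.
#' @param overlap_tolerance Fractional overlap allowance (default 0.10).
#' @return An object of class `interleave_plan`.
#' @examples
#' rabbit_plan <- interleave_plan("carbon12", target_size = c(6.5, 6.5),
#'                                phantom_half_size = 39.25)
#' @export
interleave_plan <- function(species, target_center = c(0, 0),
                            target_size = c(6.5, 6.5),
                            phantom_half_size = 39.25,
                            incident_width_fwhm = 0.3,
                            spacing_on_center = 1.05,
                            directions = c("+x", "-x", "+y", "-y"),
                            pedestal_dose_gy = 14,
                            pedestal_to_sobp_ratio = 20 / 14,
                            rbe = 3.0, width_limit = 0.7,
                            abut_tolerance = 0.05,
                            overlap_tolerance = 0.10) {
  if (!inherits(species, "ion_species")) species <- ion_species(species)
  directions <- match.arg(directions, .DIRECTIONS, several.ok = TRUE)
  pairs <- list(c("+x", "+y"), c("-x", "-y"))
  pairs <- Filter(function(p) all(p %in% directions), pairs)
  if (length(pairs) == 0)
    stop("directions must contain at least one orthogonal pair ",
         "(+x with +y, or -x with -y)", call. = FALSE)
  stopifnot(spacing_on_center >= 2 * incident_width_fwhm)
  structure(list(species = species, target_center = target_center,
                 target_size = target_size,
                 phantom_half_size = phantom_half_size,
                 incident_width_fwhm = incident_width_fwhm,
                 spacing_on_center = spacing_on_center,
                 directions = directions, pairs = pairs,
                 pedestal_dose_gy = pedestal_dose_gy,
                 pedestal_to_sobp_ratio = pedestal_to_sobp_ratio,
                 rbe = rbe, width_limit = width_limit,
                 abut_tolerance = abut_tolerance,
                 overlap_tolerance = overlap_tolerance),
            class = "interleave_plan")
}

#' @export
print.interleave_plan <- function(x, ...) {
  cat(sprintf(paste0("<interleave_plan> %s, %.2g-mm beams %.3g mm ",
                     "on-center, %d directions (%d pair%s)\n",
                     "  target %g x %g mm at (%g, %g), surfaces at ",
                     "+/-%g mm\n"),
              x$species$name, x$incident_width_fwhm, x$spacing_on_center,
              length(x$directions), length(x$pairs),
              if (length(x$pairs) > 1) "s" else "",
              x$target_size[1], x$target_size[2],
              x$target_center[1], x$target_center[2], x$phantom_half_size))
  invisible(x)
}

# per-direction geometry: depth of the proximal and distal target faces
# from that direction's entry surface
.direction_depths <- function(plan, dir) {
  hc <- plan$phantom_half_size
  cx <- plan$target_center; sz <- plan$target_size
  switch(dir,
    "+x" = c(prox = hc - (cx[1] + sz[1] / 2), dist = hc - cx[1] + sz[1] / 2),
    "-x" = c(prox = hc + (cx[1] - sz[1] / 2), dist = hc + cx[1] + sz[1] / 2),
    "+y" = c(prox = hc - (cx[2] + sz[2] / 2), dist = hc - cx[2] + sz[2] / 2),
    "-y" = c(prox = hc + (cx[2] - sz[2] / 2), dist = hc + cx[2] + sz[2] / 2))
}

# beam_spec for one array direction: range set to the distal target face
.direction_beam <- function(plan, dir, material = water_material()) {
  d <- .direction_depths(plan, dir)
  E <- energy_for_range(plan$species, d[["dist"]] / 10, material)
  beam_spec(plan$species, E, shape = "planar",
            incident_width_fwhm = plan$incident_width_fwhm,
            spacing_on_center = plan$spacing_on_center)
}

#' Coverage check of an interleave plan
#'
#' Computes the minibeam width at the target-proximal edge of every array
#' (via [width_curve()], with the beam range set to the distal target
#' face) and verifies the interleave contract: within each 90-degree pair
#' the interleaved planes (effective spacing = half the on-center spacing)
#' must abut or overlap across the target span, and the width must not
#' exceed the width limit.
#'
#' @param plan An [interleave_plan()].
#' @param material A [material()]; defaults to water.
#' @return An object of class `plan_report` with fields
#'   `width_at_proximal_edge` (mm, per direction), `covered`, `reason`
#'   (`"ok"`, `"gaps"`, `"width limit"` or `"overlap seam"`),
#'   `max_proximal_depth` (mm) and the plan's dose bookkeeping left `NA`
#'   until [compose_interleaved_dose()] fills it.
#' @export
check_coverage <- function(plan, material = water_material()) {
  stopifnot(inherits(plan, "interleave_plan"))
  widths <- vapply(plan$directions, function(dir) {
    d <- .direction_depths(plan, dir)
    b <- .direction_beam(plan, dir, material)
    R_mm <- csda_range(b$species, b$energy, material) * 10
    if (d[["prox"]] > .RANGE_FRACTION * R_mm)
      stop("target proximal edge beyond transport validity", call. = FALSE)
    wc <- width_curve(b, z_max = d[["prox"]], dz = 0.1, material = material)
    wc$fwhm[nrow(wc)]
  }, numeric(1))
  gap_target <- plan$spacing_on_center / 2
  w <- max(widths)
  if (w > plan$width_limit) {
    covered <- FALSE; reason <- "width limit"
  } else if (any(widths < (1 - plan$abut_tolerance) * gap_target)) {
    covered <- FALSE; reason <- "gaps"
  } else if (all(widths > (1 + plan$overlap_tolerance) * gap_target)) {
    covered <- TRUE; reason <- "overlap seam"
  } else {
    covered <- TRUE; reason <- "ok"
  }
  structure(list(width_at_proximal_edge = widths, covered = covered,
                 reason = reason,
                 target_physical_dose = NA_real_, target_gye = NA_real_,
                 incident_dose_factor_range = carbon_incident_factor(
                   plan$incident_width_fwhm, plan$spacing_on_center,
                   min(w, plan$width_limit)),
                 max_proximal_depth = max_proximal_depth(
                   plan$species, plan$incident_width_fwhm,
                   plan$width_limit, material = material)),
            class = "plan_report", plan = plan)
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf(paste0("<plan_report> covered: %s (%s)\n",
                     "  width at proximal edge: %s mm\n",
                     "  max allowable proximal depth: %.0f mm\n"),
              x$covered, x$reason,
              paste(sprintf("%.3f", x$width_at_proximal_edge),
                    collapse = ", "),
              x$max_proximal_depth))
  if (is.finite(x$target_physical_dose))
    cat(sprintf("  target dose: %.1f Gy physical = %.1f GyE\n",
                x$target_physical_dose, x$target_gye))
  invisible(x)
}

#' Maximum allowable depth of the target-proximal edge
#'
#' The largest depth `d` at which a minibeam whose range is `d + margin`
#' (the margin accommodating the target span) still has a FWHM no larger
#' than the width limit at `d`. Solved by bisection over `d`, re-choosing
#' the beam energy for each candidate depth.
#'
#' @inheritParams stopping_power
#' @param incident_width Incident FWHM in mm (default 0.3).
#' @param width_limit Width limit in mm (default 0.7).
#' @param margin Extra range beyond the proximal edge in mm (default 20).
#' @return Depth in mm.
#' @examples
#' \donttest{max_proximal_depth(ion_species("carbon12"))}
#' @export
max_proximal_depth <- function(species, incident_width = 0.3,
                               width_limit = 0.7, margin = 20,
                               material = water_material()) {
  if (!inherits(species, "ion_species")) species <- ion_species(species)
  if (width_limit < incident_width)
    stop("width limit below the incident width", call. = FALSE)
  if (width_limit == incident_width) return(0)
  g <- function(d) {
    E <- energy_for_range(species, (d + margin) / 10, material)
    b <- beam_spec(species, E, incident_width_fwhm = incident_width)
    wc <- width_curve(b, z_max = d, dz = 0.2, material = material)
    wc$fwhm[nrow(wc)] - width_limit
  }
  stats::uniroot(g, c(5, 380 - margin), tol = 0.05)$root
}

#' Carbon interleaved incident-dose factor pair
#'
#' Bounds on how much larger the incident in-beam dose of interleaved
#' minibeam pairs must be than a solid beam delivering the same target
#' dose from the same two directions. The upper bound,
#' `2 * spacing / width`, combines the pair non-additivity factor 2
#' (orthogonal arrays of a pair do not sum outside the target) with the
#' maximal broadening dilution; the lower bound uses the dilution already
#' realised at the target, `2 * spacing / width_at_target`. Both are
#' rounded to one decimal.
#'
#' @param width Incident width in mm.
#' @param spacing On-center spacing in mm.
#' @param width_at_target Beam width just proximal to the target in mm
#'   (in `[width, spacing]`).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' carbon_incident_factor(0.3, 0.7, 0.7) # upper 4.7
#' @export
carbon_incident_factor <- function(width, spacing, width_at_target) {
  if (width_at_target < width || width_at_target > spacing)
    stop("width_at_target must lie in [width, spacing]", call. = FALSE)
  c(lower = round(2 * spacing / width_at_target, 1),
    upper = round(2 * spacing / width, 1))
}

#' Composite interleaved dose map
#'
#' Builds the 2-D physical dose map of the axial mid-plane: outside the
#' target box each 90-degree pair contributes the comb dose of at most one
#' of its arrays (doses of the two arrays of a pair do not add up outside
#' the interleaved plateau, so pair members combine by per-voxel maximum),
#' each comb diluting with depth as the beams broaden and stopping at the
#' distal target face; inside the target each pair deposits its SOBP
#' plateau dose (`pedestal * pedestal_to_sobp_ratio`), and pairs sum.
#'
#' @param plan An [interleave_plan()].
#' @param lateral_res Lateral grid step in mm (default 0.05).
#' @param depth_res Depth sampling of the width curves in mm
#'   (default 0.5).
#' @param material A [material()].
#' @return A list of class `interleave_dose_map` with `x`, `y` (mm), a
#'   `dose` matrix in Gy (x by y), per-voxel `n_contributing` (arrays
#'   contributing to the composed dose: at most one per 90-degree pair
#'   outside the target), and the completed `plan_report`.
#' @export
compose_interleaved_dose <- function(plan, lateral_res = 0.05,
                                     depth_res = 0.5,
                                     material = water_material()) {
  stopifnot(inherits(plan, "interleave_plan"))
  report <- check_coverage(plan, material)
  if (!report$covered)
    stop("refusing to compose dose: coverage check failed (",
         report$reason, ")", call. = FALSE)
  hc <- plan$phantom_half_size
  x <- seq(-hc, hc, by = lateral_res)
  y <- seq(-hc, hc, by = lateral_res)
  cx <- plan$target_center; sz <- plan$target_size
  in_tx <- abs(x - cx[1]) <= sz[1] / 2
  in_ty <- abs(y - cx[2]) <= sz[2] / 2
  in_target <- outer(in_tx, in_ty, "&")
  s <- plan$spacing_on_center
  ped <- plan$pedestal_dose_gy
  sigma0 <- plan$incident_width_fwhm / .FWHM_SIGMA

  # comb dose of one planar array travelling along `axis` from direction
  # sign `sgn`, with plane offset `off` (mm) across the other axis
  array_dose <- function(dir, off) {
    axis <- if (dir %in% c("+x", "-x")) "x" else "y"
    sgn <- if (dir %in% c("+x", "+y")) 1 else -1
    d <- .direction_depths(plan, dir)
    b <- .direction_beam(plan, dir, material)
    travel <- if (axis == "x") x else y
    lat <- if (axis == "x") y else x
    depth <- if (sgn > 0) hc - travel else hc + travel
    R_mm <- csda_range(b$species, b$energy, material) * 10
    # widths over the final 5% of range (inside the target) are held at
    # the last transported value
    z_cap <- min(max(depth), d[["dist"]], .RANGE_FRACTION * R_mm - 1e-6)
    wc <- width_curve(b, z_max = z_cap, dz = depth_res,
                      material = material)
    sig <- stats::approx(wc$depth, wc$fwhm / .FWHM_SIGMA, pmin(depth,
                         max(wc$depth)), rule = 2)$y
    stopped <- depth > d[["dist"]] + 1e-9
    # the comb is periodic: fold the lateral coordinate into one period
    u <- (lat - off) %% s
    u <- ifelse(u > s / 2, u - s, u)
    comb <- function(sg) {
      prof <- numeric(length(lat))
      for (k in -3:3)
        prof <- prof + exp(-(u - k * s)^2 / (2 * sg^2))
      prof
    }
    m <- matrix(0, length(travel), length(lat))
    for (i in seq_along(travel)) {
      if (stopped[i]) next
      m[i, ] <- ped * (sigma0 / sig[i]) * comb(sig[i])
    }
    if (axis == "x") m else t(m)
  }

  dose <- matrix(0, length(x), length(y))
  n_contrib <- matrix(0L, length(x), length(y))
  pair_dose <- ped * plan$pedestal_to_sobp_ratio
  for (p in plan$pairs) {
    # second member of each pair offset by half the spacing
    d1 <- array_dose(p[1], 0)
    d2 <- array_dose(p[2], s / 2)
    outside <- pmax(d1, d2)
    dose <- dose + ifelse(in_target, pair_dose, outside)
    # the pair's contribution outside the target is the comb of at most
    # one of its arrays (the per-voxel maximum), never their sum
    thr <- 0.01 * ped
    n_contrib <- n_contrib + ifelse(!in_target, as.integer(outside > thr), 0L)
  }
  report$target_physical_dose <- pair_dose * length(plan$pairs)
  report$target_gye <- report$target_physical_dose * plan$rbe
  structure(list(x = x, y = y, dose = dose, n_contributing = n_contrib,
                 report = report),
            class = "interleave_dose_map", plan = plan)
}

#' @export
print.interleave_dose_map <- function(x, ...) {
  cat(sprintf("<interleave_dose_map> %d x %d voxels, target %.1f Gy (%.0f GyE)\n",
              length(x$x), length(x$y), x$report$target_physical_dose,
              x$report$target_gye))
  invisible(x)
}

#' @export
plot.interleave_dose_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$dose, xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}
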