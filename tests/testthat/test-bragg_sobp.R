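# Pristine Bragg curves, SOBP construction, the photon comparison curve
# and the three-curve depth-dose comparison.

test_that("the Bragg curve peaks near the range with a low entrance dose", {
  p <- ion_species("proton")
  bc <- bragg_curve(p, 109)
  expect_equal(max(bc$dose), 1, tolerance = 1e-9)
  R_mm <- csda_range(p, 109) * 10
  peak_z <- bc$depth[which.max(bc$dose)]
  expect_lt(abs(peak_z - R_mm), 3)
  expect_lt(bc$dose[1], 0.5)
  expect_true(all(bc$dose[bc$depth > R_mm + 3] < 0.05))
})

test_that("the Bragg peak depth is monotone in energy", {
  p <- ion_species("proton")
  pk <- vapply(c(80, 109, 140), function(E) {
    bc <- bragg_curve(p, E)
    bc$depth[which.max(bc$dose)]
  }, numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("an explicit energy spread widens the peak", {
  c12 <- ion_species("carbon12")
  narrow <- bragg_curve(c12, energy_spec(130, 0))
  wide <- bragg_curve(c12, energy_spec(130, 2))
  width80 <- function(bc) {
    above <- bc$depth[bc$dose >= 0.8]
    diff(range(above))
  }
  expect_gt(width80(wide), width80(narrow))
})

test_that("the proton SOBP plateau is flat to 3 percent", {
  s <- build_sobp(ion_species("proton"), 55, 80, n_layers = 17)
  expect_lte(s$flatness, 0.03)
  pl <- s$curve$dose[s$curve$depth >= 55 & s$curve$depth <= 80]
  expect_equal(mean(pl), 1, tolerance = 1e-9)
  expect_true(all(s$weights >= 0))
  # distal falloff
  expect_lt(s$curve$dose[s$curve$depth == 88], 0.1)
})

test_that("the carbon SOBP over the rabbit target is flat to 3 percent", {
  s <- build_sobp(ion_species("carbon12"), 37.84, 43.94, n_layers = 40,
                  z_grid = seq(0, 54, by = 0.05))
  expect_lte(s$flatness, 0.03)
  expect_true(all(s$energies >= 120 & s$energies <= 140))
})

test_that("too few layers warns honestly about ripple", {
  expect_warning(
    build_sobp(ion_species("carbon12"), 37.84, 43.94, n_layers = 8),
    "flatness")
})

test_that("a one-layer SOBP is the pristine distal curve", {
  p <- ion_species("proton")
  zg <- seq(0, 90, by = 0.2)
  s <- suppressWarnings(build_sobp(p, 55, 80, n_layers = 1, z_grid = zg))
  expect_length(s$energies, 1)
  bc <- bragg_curve(p, s$energies, zg)
  expect_equal(s$curve$dose / max(s$curve$dose), bc$dose,
               tolerance = 1e-9)
})

test_that("SOBP construction is deterministic", {
  s1 <- build_sobp(ion_species("proton"), 55, 80, n_layers = 17)
  s2 <- build_sobp(ion_species("proton"), 55, 80, n_layers = 17)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$curve$dose, s2$curve$dose)
})

test_that("the 10-MV photon curve builds up to 25 mm and attenuates", {
  z <- seq(0, 200, by = 0.5)
  ph <- photon_depth_dose(10, z)
  expect_equal(ph$depth[which.max(ph$dose)], 25, tolerance = 1)
  expect_equal(max(ph$dose), 1, tolerance = 1e-6)
  d150 <- ph$dose[ph$depth == 150]
  expect_gt(d150, 0.5)
  expect_lt(d150, 0.8)
  expect_error(photon_depth_dose(6, z), "10-MV")
})

test_that("the three-curve comparison honours its contracts", {
  sp <- ion_species("proton")
  s <- build_sobp(sp, 55, 80, n_layers = 17)
  beam <- beam_spec(sp, energy_for_range(sp, 10), shape = "planar",
                    spacing_on_center = 0.7)
  cmp <- compose_depth_dose_comparison(s, beam, sparing_factor = 7)
  expect_equal(cmp$entrance_ratio, 2.3 / 7, tolerance = 1e-9)
  z <- cmp$solid$depth
  expect_equal(cmp$minibeam$dose[1] / cmp$solid$dose[1], 2.3 / 7,
               tolerance = 1e-9)
  beyond <- z >= cmp$merge_depth_mm
  expect_equal(cmp$minibeam$dose[beyond], cmp$solid$dose[beyond],
               tolerance = 1e-12)
  before <- z < cmp$merge_depth_mm & cmp$solid$dose > 0
  expect_true(all(cmp$minibeam$dose[before] <=
                    cmp$solid$dose[before] + 1e-12))
  pl <- z >= 55 & z <= 80
  expect_equal(mean(cmp$photon$dose[pl]), 1, tolerance = 1e-9)
})

test_that("the comparison refuses a merge depth inside the plateau", {
  sp <- ion_species("proton")
  s <- suppressWarnings(build_sobp(sp, 30, 40, n_layers = 10,
                                   z_grid = seq(0, 50, by = 0.2)))
  beam <- beam_spec(sp, energy_for_range(sp, 10), shape = "planar",
                    spacing_on_center = 1.0)
  expect_error(compose_depth_dose_comparison(s, beam),
               "proximal to the")
})
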