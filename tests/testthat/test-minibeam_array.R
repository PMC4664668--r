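# Array profiles, PVDR, merge depth and the dose-bookkeeping arithmetic.

test_that("a single beam enters with unit central-axis dose", {
  b <- fx_proton_pencil_109()
  pr <- array_profile(b, depth = 0, n_beams = 1)
  expect_equal(max(pr$dose), 1, tolerance = 1e-6)
})

test_that("entrance array peaks are disjoint with near-unit peak dose", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  pr <- array_profile(b, depth = 0, n_beams = 15)
  expect_equal(max(pr$dose), 1, tolerance = 1e-3)
  r <- pvdr(pr)
  expect_gt(as.numeric(r), 1e3)
  expect_false(attr(r, "merged"))
})

test_that("array_profile validates its inputs", {
  b <- fx_planar_10cm("proton")
  expect_error(array_profile(b, 10, n_beams = 4), "odd")
  b0 <- beam_spec("proton", 109)
  expect_error(array_profile(b0, 10, n_beams = 15), "spacing")
})

test_that("PVDR decreases with depth and reaches merged", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  r <- vapply(c(5, 15, 25), function(z)
    as.numeric(pvdr(array_profile(b, z))), numeric(1))
  expect_true(all(diff(r) < 0))
  deep <- pvdr(array_profile(b, 60))
  expect_lt(as.numeric(deep), 1.01)
})

test_that("scattering redistributes but conserves the period-average dose", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  avg <- function(z) {
    pr <- array_profile(b, z, n_beams = 15, grid_resolution = 0.005)
    keep <- abs(pr$position) <= 0.5
    mean(pr$dose[keep])
  }
  a0 <- avg(0)
  expect_lt(abs(avg(20) - a0) / a0, 0.005)
  expect_lt(abs(avg(40) - a0) / a0, 0.005)
})

test_that("the two merge rules agree to within 15 percent", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  md <- merge_depth(b)
  expect_s3_class(md, "merge_report")
  expect_identical(md$merge_depth, md$merge_depth_valley_rule)
  d1 <- md$merge_depth_valley_rule
  d2 <- md$merge_depth_fwhm_rule
  expect_lt(abs(d1 - d2) / d2, 0.15)
  md2 <- merge_depth(b, rule = "fwhm_equals_spacing")
  expect_identical(md2$merge_depth, md2$merge_depth_fwhm_rule)
})

test_that("beyond the merge depth the valley criterion holds", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  md <- merge_depth(b)
  pr <- array_profile(b, md$merge_depth + 2)
  expect_gt(1 / as.numeric(pvdr(pr)), 0.95 - 0.01)
})

test_that("merge depth needs an array", {
  expect_error(merge_depth(beam_spec("proton", 109)), "spacing")
})

test_that("collimator yields match the closed forms", {
  expect_equal(collimator_yield("planar", 0.3, 0.7), 3 / 7,
               tolerance = 1e-12)
  expect_equal(collimator_yield("pencil", 0.3, 0.5),
               pi * 0.15^2 / 0.25, tolerance = 1e-12)
  expect_equal(round(100 * collimator_yield("pencil", 0.3, 0.5), 1), 28.3)
  expect_equal(round(100 * collimator_yield("pencil", 0.3, 0.7), 1), 14.4)
  expect_error(collimator_yield("planar", 0.5, 0.3), "spacing >= width")
})

test_that("incident-dose factor is the reciprocal yield", {
  for (sh in c("planar", "pencil")) {
    expect_equal(incident_dose_factor(sh, 0.3, 0.7) *
                   collimator_yield(sh, 0.3, 0.7), 1, tolerance = 1e-12)
  }
  expect_equal(round(incident_dose_factor("planar", 0.3, 0.7), 1), 2.3)
  expect_equal(round(incident_dose_factor("pencil", 0.3, 0.7), 1), 6.9)
  expect_equal(round(incident_dose_factor("pencil", 0.3, 0.5), 1), 3.5)
})

test_that("biological entrance ratio divides by the sparing factor", {
  expect_equal(biological_entrance_ratio(2.3, 7), 2.3 / 7,
               tolerance = 1e-12)
  expect_equal(round(biological_entrance_ratio(2.3, 7), 2), 0.33)
  expect_error(biological_entrance_ratio(2.3, 0.5), ">= 1")
})

test_that("dose_bookkeeping reports at the quoted precision", {
  bk <- dose_bookkeeping("planar", 0.3, 0.7)
  expect_equal(bk$report$incident_dose_factor, 2.3)
  expect_equal(bk$report$biological_entrance_ratio, 0.33)
  expect_equal(bk$report$collimator_yield_pct, 42.9)
  bk2 <- dose_bookkeeping("pencil", 0.3, 0.7)
  expect_equal(bk2$report$incident_dose_factor, 6.9)
  bk3 <- dose_bookkeeping("pencil", 0.3, 0.5)
  expect_equal(bk3$report$incident_dose_factor, 3.5)
  expect_equal(bk3$report$collimator_yield_pct, 28.3)
})

test_that("array_dose_map stacks profiles consistently", {
  b <- fx_planar_10cm("proton", spacing = 1.0)
  am <- array_dose_map(b, depths = c(5, 20), grid_resolution = 0.05)
  expect_equal(dim(am$dose), c(2, length(am$positions)))
  pr <- array_profile(b, 20, grid_resolution = 0.05)
  mid <- stats::approx(pr$position, pr$dose, am$positions,
                       yleft = 0, yright = 0)$y
  expect_equal(am$dose[2, ], mid, tolerance = 1e-8)
})
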