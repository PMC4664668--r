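# Interleave-plan geometry, coverage verification, maximum proximal depth,
# the carbon incident-dose factor pair and the composite dose map.

test_that("plan construction enforces pairing and spacing", {
  expect_s3_class(fx_rabbit_plan(), "interleave_plan")
  expect_error(interleave_plan("carbon12", directions = c("+x", "-y")),
               "orthogonal pair")
  expect_error(interleave_plan("carbon12", spacing_on_center = 0.5))
  two <- interleave_plan("carbon12", directions = c("+x", "+y"))
  expect_length(two$pairs, 1)
})

test_that("the rabbit plan is covered with ~0.53-mm beams at 36 mm", {
  rep <- check_coverage(fx_rabbit_plan())
  expect_true(rep$covered)
  expect_identical(rep$reason, "ok")
  w <- rep$width_at_proximal_edge
  expect_length(w, 4)
  expect_lt(max(abs(w - 0.525)) / 0.525, 0.15)
  # centred target: all four directions equivalent
  expect_lt(diff(range(w)), 1e-9)
})

test_that("a surface target is not covered (no broadening yet)", {
  plan <- fx_rabbit_plan(phantom_half_size = 3.25)
  rep <- check_coverage(plan)
  expect_false(rep$covered)
  expect_identical(rep$reason, "gaps")
  expect_equal(unname(rep$width_at_proximal_edge), rep(0.3, 4),
               tolerance = 1e-6)
})

test_that("a deep proximal edge trips the width limit", {
  plan <- fx_rabbit_plan(phantom_half_size = 80)
  rep <- check_coverage(plan)
  expect_false(rep$covered)
  expect_identical(rep$reason, "width limit")
  expect_error(compose_interleaved_dose(plan), "coverage")
})

test_that("max proximal depth: boundary and species ordering", {
  c12 <- ion_species("carbon12")
  expect_equal(max_proximal_depth(c12, 0.3, width_limit = 0.3), 0)
  expect_error(max_proximal_depth(c12, 0.3, width_limit = 0.2),
               "below the incident width")
  d <- vapply(c("carbon12", "lithium7", "proton"), function(nm)
    max_proximal_depth(ion_species(nm)), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("carbon incident-dose factor pair matches its conventions", {
  f <- carbon_incident_factor(0.3, 0.7, 0.7)
  expect_equal(unname(f), c(2.0, 4.7))
  expect_named(f, c("lower", "upper"))
  # no dilution left: both endpoints collapse to the pair factor 2
  expect_equal(unname(carbon_incident_factor(0.5, 0.5, 0.5)), c(2, 2))
  expect_error(carbon_incident_factor(0.3, 0.7, 0.8), "width_at_target")
})

test_that("the composed rabbit map delivers 40 Gy / 120 GyE", {
  map <- compose_interleaved_dose(fx_rabbit_plan(), lateral_res = 0.25)
  rep <- map$report
  expect_equal(rep$target_physical_dose, 40, tolerance = 1e-9)
  expect_equal(rep$target_gye, 120, tolerance = 1e-9)
  expect_equal(rep$target_gye, rep$target_physical_dose * 3,
               tolerance = 1e-12)
  in_t <- abs(map$x) <= 3.25
  inside <- map$dose[in_t, in_t]
  # target uniformity within 5%
  expect_lte((max(inside) - min(inside)) / mean(inside), 0.05)
})

test_that("outside the target each pair contributes at most one array", {
  map <- compose_interleaved_dose(fx_rabbit_plan(), lateral_res = 0.25)
  out_mask <- !(outer(abs(map$x) <= 3.25, abs(map$y) <= 3.25, "&"))
  expect_true(all(map$n_contributing[out_mask] <= 2))  # one per pair
  expect_true(all(map$n_contributing[!out_mask] == 0))
  # composite outside dose never exceeds the sum of per-pair single-array
  # maxima (14-Gy pedestal each, mildly diluted with depth)
  expect_lt(max(map$dose[out_mask]), 2 * 14 * 1.05)
  expect_lt(max(map$dose[out_mask]), map$report$target_physical_dose)
})

test_that("one pair delivers half the four-direction target dose", {
  plan2 <- fx_rabbit_plan(directions = c("+x", "+y"))
  map2 <- compose_interleaved_dose(plan2, lateral_res = 0.25)
  expect_equal(map2$report$target_physical_dose, 20, tolerance = 1e-9)
  expect_equal(map2$report$target_gye, 60, tolerance = 1e-9)
})
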