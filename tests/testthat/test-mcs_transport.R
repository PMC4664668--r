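# Scattering power, Fermi-Eyges moment propagation, width curves and the
# Monte Carlo transport oracle.

test_that("beam_spec validates geometry", {
  b <- beam_spec("proton", 109)
  expect_s3_class(b, "beam_spec")
  expect_equal(b$incident_width_fwhm, 0.3)
  expect_error(beam_spec("proton", 109, incident_width_fwhm = 0),
               "positive")
  expect_error(beam_spec("proton", 109, spacing_on_center = 0.1),
               "spacing")
  expect_error(beam_spec("proton", 109, shape = "planar",
                         spacing_on_center = 1, lattice = "square"),
               "lattice")
})

test_that("scattering power is positive and falls with energy", {
  p <- ion_species("proton")
  T1 <- scattering_power(p, c(50, 100, 200), 10)
  expect_true(all(T1 > 0))
  expect_true(all(diff(T1) < 0))
  expect_error(scattering_power(p, 0.5, 10), "stopped")
})

test_that("logarithmic thickness correction clamps to [0.25, 1]", {
  p <- ion_species("proton")
  X0_mm <- 36.08 * 10
  # tiny thickness: correction at the 0.25 floor
  ratio <- scattering_power(p, 100, 1e-9) /
    scattering_power(p, 100, X0_mm)
  expect_equal(ratio, 0.25, tolerance = 1e-9)
  # beyond one radiation length the correction stays at 1
  expect_equal(scattering_power(p, 100, 2 * X0_mm),
               scattering_power(p, 100, X0_mm), tolerance = 1e-12)
})

test_that("constant scattering power reproduces the closed-form moments", {
  Tc <- 1e-4
  b <- beam_spec("proton", 109, incident_width_fwhm = 0.3)
  st <- propagate_moments(
    b, z_max = 40, dz = 0.05,
    scattering_power_fn = function(sp, E, L, mat) rep(Tc, length(E)))
  z <- st$depth
  v0 <- (0.3 / (2 * sqrt(2 * log(2))))^2
  expect_equal(st$A0, Tc * z, tolerance = 1e-10)
  expect_equal(st$A1, Tc * z^2 / 2, tolerance = 1e-6)
  expect_equal(st$A2, Tc * z^3 / 3 + v0, tolerance = 1e-4)
})

test_that("moments satisfy the Cauchy-Schwarz inequality", {
  st <- propagate_moments(fx_proton_pencil_109(), z_max = 60, dz = 0.1)
  v0 <- st$A2[1]
  expect_true(all(st$A1^2 <= st$A0 * (st$A2 - v0) * (1 + 1e-9) + 1e-18))
})

test_that("transport refuses depths beyond 95% of range", {
  expect_error(propagate_moments(fx_proton_pencil_109(), z_max = 88),
               "95%")
  expect_error(propagate_moments(fx_proton_pencil_109()),
               "z_grid or z_max")
})

test_that("width curve starts at the incident width and grows", {
  wc <- width_curve(fx_proton_pencil_109(), z_max = 60, dz = 0.1)
  expect_equal(wc$fwhm[1], 0.3, tolerance = 1e-9)
  expect_true(all(diff(wc$fwhm) >= -1e-12))
})

test_that("width curve is converged in the integration step", {
  b <- fx_proton_pencil_109()
  w1 <- width_curve(b, z_max = 30, dz = 0.1)
  w2 <- width_curve(b, z_max = 30, dz = 0.05)
  f1 <- w1$fwhm[w1$depth == 30]
  f2 <- w2$fwhm[w2$depth == 30]
  expect_lt(abs(f1 - f2) / f2, 0.002)
})

test_that("planar and pencil beams share the same transverse FWHM", {
  sp <- ion_species("proton")
  b1 <- beam_spec(sp, 109, shape = "pencil")
  b2 <- beam_spec(sp, 109, shape = "planar")
  w1 <- width_curve(b1, z_max = 40, dz = 0.1)
  w2 <- width_curve(b2, z_max = 40, dz = 0.1)
  expect_equal(w1$fwhm, w2$fwhm, tolerance = 1e-12)
})

test_that("tophat incident profile agrees with gaussian near merge", {
  sp <- ion_species("proton")
  bt <- beam_spec(sp, 109, incident_profile = "tophat")
  bg <- beam_spec(sp, 109, incident_profile = "gaussian")
  wt <- width_curve(bt, z_max = 30, dz = 0.1)
  wg <- width_curve(bg, z_max = 30, dz = 0.1)
  expect_equal(wt$fwhm[1], 0.3, tolerance = 1e-6)
  i <- wt$depth == 30
  expect_lt(abs(wt$fwhm[i] - wg$fwhm[i]) / wg$fwhm[i], 0.05)
})

test_that("depth_for_width inverts the width curve", {
  b <- fx_proton_pencil_109()
  d <- depth_for_width(b, 0.7)
  wc <- width_curve(b, z_max = ceiling(d) + 1, dz = 0.1)
  w_at_d <- stats::spline(wc$depth, wc$fwhm, xout = d)$y
  expect_lt(abs(w_at_d - 0.7), 1e-3)
  expect_equal(depth_for_width(b, 0.3), 0)
  expect_error(depth_for_width(b, 0.2), "below the incident width")
  expect_warning(d_na <- depth_for_width(b, 50), "not reached")
  expect_true(is.na(d_na))
})

test_that("the MC oracle is seed-reproducible and leaves the RNG alone", {
  b <- fx_proton_pencil_109()
  set.seed(99)
  before <- .Random.seed
  m1 <- mc_transport(b, 2000, seed = 7, z_planes = c(10, 30))
  expect_identical(.Random.seed, before)
  m2 <- mc_transport(b, 2000, seed = 7, z_planes = c(10, 30))
  expect_identical(m1$samples, m2$samples)
  m3 <- mc_transport(b, 2000, seed = 8, z_planes = c(10, 30))
  expect_false(identical(m1$samples, m3$samples))
})

test_that("MC samples are symmetric about the axis", {
  m <- mc_transport(fx_proton_pencil_109(), 20000, seed = 11,
                    z_planes = 30)
  x <- m$samples[, 1]
  expect_lt(abs(mean(x)) / stats::sd(x), 0.03)
})

test_that("MC FWHM agrees with Fermi-Eyges within statistics", {
  b <- fx_proton_pencil_109()
  planes <- c(15, 25, 35)
  m <- mc_transport(b, 20000, seed = 3, z_planes = planes, dz = 0.05)
  wc <- width_curve(b, z_max = 35, dz = 0.05)
  fe <- wc$fwhm[match(planes, wc$depth)]
  expect_true(all(abs(m$fwhm - fe) <= 3 * m$fwhm_se))
})

test_that("broadening at fixed range orders proton > d > He-4 > Li-7", {
  w50 <- vapply(c("proton", "deuteron", "helium4", "lithium7"),
                function(nm) {
                  b <- fx_planar_10cm(nm, spacing = 0)
                  wc <- width_curve(b, z_max = 50, dz = 0.2)
                  wc$fwhm[nrow(wc)]
                }, numeric(1))
  expect_true(all(diff(w50) < 0))
})

test_that("width curves curve upward over the final third of the track", {
  for (nm in c("proton", "lithium7")) {
    b <- fx_planar_10cm(nm, spacing = 0)
    wc <- width_curve(b, z_max = 94, dz = 0.2)
    last3 <- wc[wc$depth >= 94 * 2 / 3, ]
    expect_true(all(diff(diff(last3$fwhm)) > -1e-9))
  }
})
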