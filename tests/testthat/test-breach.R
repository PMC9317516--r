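# Breach simulation: bisection vs brute force, closed forms, symmetry,
# monotonicity, and population margins.

coax <- function(R = 3.5, r = 1.75, L = 30) {
  list(screw = trajectory(c(0, 0, 0), c(0, 0, 1), L, r),
       ped = pedicle_model(trajectory(c(0, 0, 0), c(0, 0, 1), L, R), radius = R))
}

test_that("coaxial breach angle matches the brute-force scan and is azimuth invariant", {
  cx <- coax()
  b0 <- max_rotation_to_breach(cx$screw, cx$ped, azimuth_deg = 0)
  expect_lt(abs(b0 - oracle_breach_scan(cx$screw, cx$ped, 0)), 0.01)
  angs <- vapply(seq(0, 330, by = 30), function(a)
    max_rotation_to_breach(cx$screw, cx$ped, a), numeric(1))
  expect_lt(diff(range(angs)), 0.02)
  # regression: pinned value for the coaxial reference configuration
  # (first derived by brute force; agrees with the thin-screw slab
  # estimate asin((R - r)/L) to ~0.1 degree)
  expect_equal(b0, 3.3481, tolerance = 0.01 / 3.3481)
  expect_lt(abs(b0 - asin((3.5 - 1.75) / 30) * 180 / pi), 0.15)
})

test_that("zero-slack and invalid configurations are handled", {
  tight <- coax(R = 1.75)
  expect_lt(max_rotation_to_breach(tight$screw, tight$ped, 0), 0.01)
  expect_lt(max_translation_to_breach(tight$screw, tight$ped, 0), 1e-5)
  fat <- coax(R = 1.5)
  expect_error(max_rotation_to_breach(fat$screw, fat$ped, 0),
               class = "spineaccInvalidConfiguration")
})

test_that("translation slack hits the closed forms", {
  cx <- coax()
  expect_equal(max_translation_to_breach(cx$screw, cx$ped, 0), 3.5 - 1.75,
               tolerance = 1e-5)
  ell <- pedicle_model(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 4),
                       semi_axes = c(4, 2.8))
  # azimuth 90 shifts along the tube frame's v axis (the minor semi-axis)
  expect_equal(max_translation_to_breach(cx$screw, ell, 90), 2.8 - 1.75,
               tolerance = 1e-5)
  expect_equal(max_translation_to_breach(cx$screw, ell, 0), 4 - 1.75,
               tolerance = 1e-5)
})

test_that("translation breach from a tilted initial pose matches brute force", {
  set.seed(41)
  for (i in 1:3) {
    screw <- spineacc:::tilt_screw(
      trajectory(c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), 0), c(0, 0, 1), 28, 1.5),
      runif(1, 0, 360), runif(1, 0, 1))
    ped <- pedicle_model(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 3.5), radius = 3.5)
    az <- runif(1, 0, 360)
    got <- max_translation_to_breach(screw, ped, az)
    # scan oracle, 0.001 mm steps
    s <- 0
    fr <- spineacc:::make_frame(screw$direction)
    wdir <- cos(az * pi / 180) * fr$u + sin(az * pi / 180) * fr$v
    repeat {
      sh <- trajectory(screw$entry + (s + 0.001) * wdir, screw$direction, 28, 1.5)
      if (!spineacc:::screw_in_pedicle(sh, ped)) break
      s <- s + 0.001
    }
    expect_lt(abs(got - s), 0.005)
  }
})

test_that("breach angle is monotone in the pedicle and screw geometry", {
  base <- coax()
  by_R <- vapply(c(2.5, 3, 3.5, 4, 4.5), function(R)
    max_rotation_to_breach(coax(R = R)$screw, coax(R = R)$ped, 0), numeric(1))
  expect_true(all(diff(by_R) > 0))
  by_r <- vapply(c(1, 1.5, 2, 2.5), function(r)
    max_rotation_to_breach(coax(r = r)$screw, coax(r = r)$ped, 0), numeric(1))
  expect_true(all(diff(by_r) < 0))
  by_L <- vapply(c(20, 25, 30, 35), function(L)
    max_rotation_to_breach(coax(L = L)$screw, coax(L = L)$ped, 0), numeric(1))
  expect_true(all(diff(by_L) < 0))
})

test_that("population margins reduce to quantiles of the per-screw worst cases", {
  cx <- coax()
  pop_same <- replicate(8, list(screw = cx$screw, pedicle = cx$ped), simplify = FALSE)
  common <- max_rotation_to_breach(cx$screw, cx$ped, 0)
  m <- breach_margin(pop_same, coverage = 0.99, n_azimuth = 8)
  expect_equal(as.numeric(m), common, tolerance = 0.01 / common)
  pop <- simulate_breach_population(40, seed = 55)
  m99 <- breach_margin(pop, coverage = 0.99, n_azimuth = 8)
  m50 <- breach_margin(pop, coverage = 0.5, n_azimuth = 8)
  angles <- attr(m99, "breach_angles")
  expect_equal(as.numeric(m99),
               unname(quantile(angles, probs = 0.01, type = 7)),
               tolerance = 1e-12)
  expect_equal(as.numeric(m50), unname(median(angles)), tolerance = 1e-12)
  expect_lte(as.numeric(m99), as.numeric(m50))
  expect_error(breach_margin(list(), 0.99), "empty")
})

test_that("worst-case profile agrees with its azimuth grid", {
  set.seed(56)
  pop <- simulate_breach_population(1, tilt_sd = 1, offset_sd = 0.4, seed = 9)
  br <- breach_profile(pop[[1]]$screw, pop[[1]]$pedicle, n_azimuth = 12)
  expect_equal(br$max_rotation, min(br$azimuth_profile$breach_deg))
  expect_equal(br$max_translation, min(br$azimuth_profile$breach_mm))
})
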