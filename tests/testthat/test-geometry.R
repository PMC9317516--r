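# Geometry primitives: angles, rigid transforms, cylinder containment.

test_that("angle_between handles identity, orthogonality, and small constructed rotations", {
  expect_equal(angle_between(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angle_between(c(0, 0, 1), c(1, 0, 0)), 90)
  th <- 3 * pi / 180
  expect_equal(angle_between(c(0, 0, 1), c(sin(th), 0, cos(th))), 3, tolerance = 1e-9)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("angle_between is symmetric and scale invariant, and matches rotation magnitude", {
  set.seed(4)
  for (i in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(angle_between(u, v), angle_between(v, u), tolerance = 1e-12)
    expect_equal(angle_between(3.7 * u, v), angle_between(u, 0.01 * v), tolerance = 1e-9)
    # rotating u about a perpendicular axis by a known angle
    ax <- spineacc:::cross3(u, rnorm(3))
    ang <- runif(1, 0, 180)
    R <- spineacc:::rotation_matrix(ax, ang)
    expect_equal(angle_between(u, as.vector(R %*% u)), ang, tolerance = 1e-9)
  }
})

test_that("rigid transforms compose, invert, and preserve distances", {
  expect_equal(apply_transform(rt_identity(), c(1, 2, 3)), c(1, 2, 3))
  r90 <- rt_from_axis_angle(c(0, 0, 1), 90)
  expect_equal(apply_transform(r90, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    tr <- random_rigid_transform(180, 50)
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(spineacc:::vnorm(apply_transform(tr, p) - apply_transform(tr, q)),
                 spineacc:::vnorm(p - q), tolerance = 1e-9)
    # inverse composes to identity
    e <- rt_compose(tr, rt_invert(tr))
    expect_lt(rt_angle(e), 1e-9)
    expect_lt(spineacc:::vnorm(e$translation), 1e-9)
    # angles invariant under a common transform
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(angle_between(tr$rotation %*% u, tr$rotation %*% v),
                 angle_between(u, v), tolerance = 1e-9)
  }
  # composition is associative
  set.seed(6)
  a <- random_rigid_transform(40, 5); b <- random_rigid_transform(40, 5)
  cc <- random_rigid_transform(40, 5)
  l <- rt_compose(rt_compose(a, b), cc); r <- rt_compose(a, rt_compose(b, cc))
  expect_equal(l$rotation, r$rotation, tolerance = 1e-12)
  expect_equal(l$translation, r$translation, tolerance = 1e-12)
  expect_error(rigid_transform(matrix(2 * diag(3), 3), c(0, 0, 0)), "orthonormal")
})

test_that("cylinder_contains decides the coaxial cases and validates sampling", {
  tube <- trajectory(c(0, 0, 0), c(0, 0, 1), length = 30, radius = 3.5)
  expect_true(cylinder_contains(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 1.75), tube))
  expect_true(cylinder_contains(trajectory(c(0, 0, 5), c(0, 0, 1), 20, 3.5), tube))
  expect_false(cylinder_contains(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 3.6), tube))
  expect_false(cylinder_contains(trajectory(c(0, 0, 0), c(0, 0, 1), 31, 1.0), tube))
  expect_error(cylinder_contains(tube, tube, n_axial = 1), "n_axial")
  expect_error(cylinder_contains(tube, tube, n_circ = 4), "n_circ")
})

test_that("containment flip angle matches a dense point-sampling oracle", {
  # screw inset from the tube ends so the axial constraint binds away from 0
  tube <- trajectory(c(0, 0, 0), c(0, 0, 1), length = 40, radius = 4)
  screw <- trajectory(c(0, 0, 8), c(0, 0, 1), length = 24, radius = 1.5)
  flip_at <- function(contains) {
    lo <- 0; hi <- 20
    while (hi - lo > 0.005) {
      mid <- (lo + hi) / 2
      if (contains(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  tilted <- function(th) spineacc:::tilt_screw(screw, 35, th)
  t_pkg <- flip_at(function(th) cylinder_contains(tilted(th), tube))
  # oracle: 1e6 lateral-surface samples, direct predicate
  t_orc <- flip_at(function(th) {
    s <- tilted(th)
    P <- spineacc:::cylinder_surface_points(s, 1000, 1000)
    z <- P[, 3]
    all(z >= -1e-9 & z <= 40 + 1e-9 & P[, 1]^2 + P[, 2]^2 <= 16 + 1e-9)
  })
  expect_lt(abs(t_pkg - t_orc), 0.05)
  # monotone: once breached, stays breached at larger tilts
  was_contained <- TRUE
  for (th in seq(0, 15, by = 0.5)) {
    ok <- cylinder_contains(tilted(th), tube)
    if (!was_contained) expect_false(ok)
    was_contained <- ok
  }
})

test_that("trajectory validates and normalizes its inputs", {
  tr <- trajectory(c(0, 0, 0), c(0, 0, 10), 30, 1.75)
  expect_equal(spineacc:::vnorm(tr$direction), 1, tolerance = 1e-12)
  expect_error(trajectory(c(0, 0, 0), c(0, 0, 0), 30, 1.75), "non-zero")
  expect_error(trajectory(c(0, 0, 0), c(0, 0, 1), -1, 1.75), "positive")
  expect_error(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 0), "positive")
})
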