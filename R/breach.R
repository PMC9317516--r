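# Pedicle breach simulation: the largest screw rotation (about the entry
# point) or lateral translation tolerated before the screw surface exits
# the pedicle wall, and population coverage margins derived from it.

#' Pedicle model: a circular or elliptic tube
#'
#' @param axis A `trajectory` giving the tube axis: entry point, direction
#'   and length. The trajectory's own radius is ignored.
#' @param radius Circular tube radius (mm); give either this or
#'   `semi_axes`.
#' @param semi_axes Length-2 semi-axes (mm) of an elliptic cross-section;
#'   the first lies along the tube frame's `u` axis (see details).
#' @param length Tube length (mm); defaults to the axis trajectory length.
#' @return An object of class `pedicle_model`. The cross-section frame
#'   `(u, v)` is the deterministic orthonormal frame of the axis
#'   direction.
#' @export
pedicle_model <- function(axis, radius = NULL, semi_axes = NULL, length = NULL) {
  if (!inherits(axis, "trajectory")) stop("axis must be a trajectory", call. = FALSE)
  if (is.null(radius) == is.null(semi_axes))
    stop("give exactly one of radius or semi_axes", call. = FALSE)
  if (!is.null(radius)) {
    if (radius <= 0) stop("pedicle radius must be positive", call. = FALSE)
    semi <- c(radius, radius)
  } else {
    semi <- as.numeric(semi_axes)
    if (length(semi) != 2L || any(semi <= 0))
      stop("semi_axes must be two positive lengths", call. = FALSE)
  }
  len <- length %||% axis$length
  if (len <= 0) stop("pedicle length must be positive", call. = FALSE)
  fr <- make_frame(axis$direction)
  structure(list(entry = axis$entry, direction = axis$direction,
                 length = len, semi_axes = semi, u = fr$u, v = fr$v,
                 circular = semi[1L] == semi[2L]),
            class = "pedicle_model")
}

#' @export
print.pedicle_model <- function(x, ...) {
  cat(sprintf("pedicle model: %s, L = %.1f mm\n",
              if (x$circular) sprintf("circular r = %.2f mm", x$semi_axes[1])
              else sprintf("elliptic %.2f x %.2f mm", x$semi_axes[1], x$semi_axes[2]),
              x$length))
  invisible(x)
}

# TRUE iff no lateral-surface sample of the screw violates the tube wall.
# The tube ends are open: samples beyond the axial span are ignored,
# since the screw legitimately enters at one end and exits into the
# vertebral body at the other; only the pedicle wall can be breached.
screw_in_pedicle <- function(screw, pedicle, n_axial = 50L, n_circ = 64L,
                             lateral_only = TRUE) {
  fr <- make_frame(screw$direction)
  screw_tube_contained_cpp(screw$entry, screw$direction, fr$u, fr$v,
                           screw$length, screw$radius,
                           as.integer(n_axial), as.integer(n_circ),
                           pedicle$entry, pedicle$direction,
                           pedicle$u, pedicle$v,
                           pedicle$semi_axes[1L], pedicle$semi_axes[2L],
                           pedicle$length, lateral_only)
}

# tilt the screw by theta degrees about its entry point, in the plane
# selected by the azimuth (degrees, measured in the screw's (u, v) frame)
tilt_screw <- function(screw, azimuth_deg, theta_deg) {
  fr <- make_frame(screw$direction)
  az <- azimuth_deg * pi / 180
  w <- cos(az) * fr$u + sin(az) * fr$v
  R <- rotation_matrix(cross3(screw$direction, w), theta_deg)
  trajectory(screw$entry, as.vector(R %*% screw$direction),
             screw$length, screw$radius, id = screw$id)
}

#' Maximum screw rotation before pedicle wall breach
#'
#' Finds by bisection the largest tilt (degrees) of the screw about its
#' entry point, in the plane selected by `azimuth_deg`, for which the
#' screw still lies entirely inside the pedicle.
#'
#' @param screw A `trajectory`; must be contained at zero tilt.
#' @param pedicle A `pedicle_model`.
#' @param azimuth_deg Tilt-plane azimuth in degrees (0 = the screw
#'   frame's `u` axis).
#' @param tol Bisection tolerance (degrees).
#' @param theta_max Search upper bound (degrees); the result is capped
#'   here if no breach occurs.
#' @param n_axial,n_circ Containment sampling density.
#' @return Breach angle in degrees.
#' @export
max_rotation_to_breach <- function(screw, pedicle, azimuth_deg = 0, tol = 0.01,
                                   theta_max = 45, n_axial = 50L, n_circ = 64L) {
  contained <- function(th)
    screw_in_pedicle(tilt_screw(screw, azimuth_deg, th), pedicle, n_axial, n_circ)
  if (!contained(0))
    err("screw is not contained in the pedicle at zero tilt", "spineaccInvalidConfiguration")
  if (contained(theta_max)) return(theta_max)
  lo <- 0; hi <- theta_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (contained(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximum lateral screw translation before pedicle wall breach
#'
#' As [max_rotation_to_breach()], but for a pure lateral shift of the
#' screw axis (perpendicular to the screw direction, in the azimuth
#' plane). For a coaxial screw in a circular pedicle the answer is the
#' radial slack `R - r`.
#'
#' @inheritParams max_rotation_to_breach
#' @param tol Bisection tolerance (mm).
#' @param s_max Search upper bound (mm).
#' @return Breach translation in mm.
#' @export
max_translation_to_breach <- function(screw, pedicle, azimuth_deg = 0,
                                      tol = 1e-6, s_max = NULL,
                                      n_axial = 50L, n_circ = 64L) {
  fr <- make_frame(screw$direction)
  az <- azimuth_deg * pi / 180
  w <- cos(az) * fr$u + sin(az) * fr$v
  shift <- function(s) trajectory(screw$entry + s * w, screw$direction,
                                  screw$length, screw$radius, id = screw$id)
  contained <- function(s) screw_in_pedicle(shift(s), pedicle, n_axial, n_circ)
  if (!contained(0))
    err("screw is not contained in the pedicle at zero shift", "spineaccInvalidConfiguration")
  hi <- s_max %||% (2 * max(pedicle$semi_axes))
  if (contained(hi)) return(hi)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (contained(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Worst-case breach profile of one screw/pedicle pair
#'
#' Evaluates the breach angle over a grid of tilt azimuths and returns the
#' worst case together with the full profile.
#'
#' @inheritParams max_rotation_to_breach
#' @param n_azimuth Number of equally spaced azimuths.
#' @return A list of class `breach_result`: `max_rotation` (degrees, the
#'   minimum over azimuths), `max_translation` (mm, worst case), and
#'   `azimuth_profile` (data.frame of azimuth and breach angle).
#' @export
breach_profile <- function(screw, pedicle, n_azimuth = 24, tol = 0.01,
                           theta_max = 45) {
  az <- seq(0, 360, length.out = n_azimuth + 1L)[-(n_azimuth + 1L)]
  ang <- vapply(az, function(a)
    max_rotation_to_breach(screw, pedicle, a, tol = tol, theta_max = theta_max),
    numeric(1))
  trn <- vapply(az, function(a)
    max_translation_to_breach(screw, pedicle, a), numeric(1))
  structure(list(max_rotation = min(ang), max_translation = min(trn),
                 azimuth_profile = data.frame(azimuth_deg = az, breach_deg = ang,
                                              breach_mm = trn)),
            class = "breach_result")
}

#' @export
print.breach_result <- function(x, ...) {
  cat(sprintf("breach result: max rotation %.3f deg, max translation %.3f mm (worst of %d azimuths)\n",
              x$max_rotation, x$max_translation, nrow(x$azimuth_profile)))
  invisible(x)
}

#' Population breach margin
#'
#' For a population of screw/pedicle pairs, computes each pair's
#' worst-case breach angle over an azimuth grid and summarizes the
#' rotation tolerated by a given fraction of the population: either the
#' empirical `(1 - coverage)` quantile (default) or a normal-theory
#' `mean + z_(1-coverage) * sd` bound.
#'
#' @param population List of pairs, each a list with elements `screw`
#'   (`trajectory`) and `pedicle` (`pedicle_model`).
#' @param coverage Fraction of screws that must remain contained (e.g.
#'   0.99).
#' @param n_azimuth Azimuth grid size for the per-screw worst case.
#' @param method `"quantile"` (empirical, default) or `"normal"`.
#' @param azimuth_policy `"worst"` (default) uses each pair's worst-case
#'   azimuth; `"mean"` averages over azimuths.
#' @return Margin in degrees, with the per-pair breach angles attached as
#'   attribute `breach_angles`.
#' @export
breach_margin <- function(population, coverage = 0.99, n_azimuth = 24,
                          method = c("quantile", "normal"),
                          azimuth_policy = c("worst", "mean")) {
  method <- match.arg(method)
  azimuth_policy <- match.arg(azimuth_policy)
  if (!length(population)) stop("population is empty", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)", call. = FALSE)
  az <- seq(0, 360, length.out = n_azimuth + 1L)[-(n_azimuth + 1L)]
  angles <- vapply(population, function(pair) {
    a <- vapply(az, function(x)
      max_rotation_to_breach(pair$screw, pair$pedicle, x), numeric(1))
    if (azimuth_policy == "worst") min(a) else mean(a)
  }, numeric(1))
  m <- switch(method,
              quantile = unname(stats::quantile(angles, probs = 1 - coverage, type = 7)),
              normal = mean(angles) + stats::qnorm(1 - coverage) * stats::sd(angles))
  attr(m, "breach_angles") <- angles
  m
}

#' Simulate a population of screw/pedicle pairs
#'
#' Draws pedicle radii from a truncated Gaussian (truncated above the
#' screw radius plus a small clearance) and gives each screw a small
#' random initial tilt and lateral offset, redrawn until the screw is
#' contained. A parametric stand-in for patient-derived pedicle models.
#'
#' @param n Number of pairs.
#' @param screw_radius,screw_length Screw dimensions (mm).
#' @param pedicle_radius_mean,pedicle_radius_sd Pedicle radius
#'   distribution (mm).
#' @param pedicle_length Tube length (mm).
#' @param tilt_sd Initial screw tilt sd (degrees).
#' @param offset_sd Initial lateral offset sd (mm).
#' @param seed Optional seed.
#' @return A list of `list(screw, pedicle)` pairs.
#' @export
simulate_breach_population <- function(n, screw_radius = 1.75, screw_length = 30,
                                       pedicle_radius_mean = 3.5,
                                       pedicle_radius_sd = 0.5,
                                       pedicle_length = 30,
                                       tilt_sd = 0.5, offset_sd = 0.2,
                                       seed = NULL) {
  draw <- function() {
    lapply(seq_len(n), function(i) {
      r <- -Inf
      while (r < screw_radius + 0.2)
        r <- stats::rnorm(1, pedicle_radius_mean, pedicle_radius_sd)
      axis <- trajectory(c(0, 0, 0), c(0, 0, 1), length = pedicle_length, radius = r)
      ped <- pedicle_model(axis, radius = r)
      repeat {
        off <- stats::rnorm(2, 0, offset_sd)
        base <- trajectory(c(off[1], off[2], 0), c(0, 0, 1),
                           length = screw_length, radius = screw_radius)
        sc <- tilt_screw(base, stats::runif(1, 0, 360), abs(stats::rnorm(1, 0, tilt_sd)))
        if (screw_in_pedicle(sc, ped)) break
      }
      list(screw = sc, pedicle = ped)
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
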