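# Independent reference implementations used as oracles. They share no
# code with the package paths they check.

# Grid-search cylinder fit: scan axis directions on a 1-degree grid
# around the cloud's first principal axis, solving the in-plane circle
# by the Kasa algebraic fit, then polish the best direction with
# Nelder-Mead on the geometric objective.
oracle_fit_cylinder <- function(P, half_range_deg = 10, step_deg = 1) {
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  d0 <- eigen(cov(Pc), symmetric = TRUE)$vectors[, 1]
  fr <- spineacc:::make_frame(d0)
  obj <- function(ab) {
    d <- d0 + ab[1] * fr$u + ab[2] * fr$v
    d <- d / sqrt(sum(d^2))
    e1 <- spineacc:::make_frame(d)$u
    e2 <- spineacc:::cross3(d, e1)
    x <- Pc %*% e1
    y <- Pc %*% e2
    # Kasa: minimize ||x^2+y^2 - 2ax - 2by - c||
    A <- cbind(2 * x, 2 * y, 1)
    z <- x^2 + y^2
    sol <- qr.solve(A, z)
    rho <- sqrt((x - sol[1])^2 + (y - sol[2])^2)
    list(val = sum((rho - mean(rho))^2), radius = mean(rho),
         center2d = sol[1:2], d = d, e1 = e1, e2 = e2)
  }
  grid <- expand.grid(a = tan(seq(-half_range_deg, half_range_deg, by = step_deg) * pi / 180),
                      b = tan(seq(-half_range_deg, half_range_deg, by = step_deg) * pi / 180))
  vals <- apply(grid, 1, function(ab) obj(ab)$val)
  best <- as.numeric(grid[which.min(vals), ])
  ref <- optim(best, function(ab) obj(ab)$val, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 500))
  res <- obj(ref$par)
  axis_point <- ctr + res$center2d[1] * res$e1 + res$center2d[2] * res$e2
  list(axis_direction = res$d, radius = res$radius, axis_point = axis_point,
       rss = res$val)
}

# Brute-force breach scan: step the tilt until containment first fails.
oracle_breach_scan <- function(screw, pedicle, azimuth_deg, step = 0.001,
                               theta_max = 45) {
  th <- 0
  while (th + step <= theta_max) {
    if (!spineacc:::screw_in_pedicle(spineacc:::tilt_screw(screw, azimuth_deg, th + step),
                                     pedicle))
      return(th)
    th <- th + step
  }
  theta_max
}

# Textbook t-interval, written out from the closed form.
oracle_t_interval <- function(x, conf = 0.95) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  half <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  c(m - half, m + half)
}
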