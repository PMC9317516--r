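# Trial statistics: randomization, descriptives, pairing, the
# non-inferiority t analysis, sample size and simulated power.

test_that("block randomization balances every complete block", {
  s <- randomize_sides(10, block_size = 2, seed = 1)
  for (b in 1:5)
    expect_setequal(s$side_3dpg[s$block == b], c("left", "right"))
  s9 <- randomize_sides(9, block_size = 4, seed = 2)
  for (b in 1:2)
    expect_equal(sum(s9$side_3dpg[s9$block == b] == "left"), 2)
  expect_equal(nrow(s9), 9)
  expect_identical(randomize_sides(10, 2, seed = 7), randomize_sides(10, 2, seed = 7))
  expect_error(randomize_sides(10, block_size = 3), "even")
})

test_that("describe_deviation returns linear-interpolation median and IQR", {
  expect_equal(describe_deviation(1:5)[c("median", "q1", "q3")],
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(unname(describe_deviation(7)[1:3]), c(7, 7, 7))
  expect_error(describe_deviation(numeric(0)), "no values")
  # lognormal quantiles against the closed form
  set.seed(71)
  x <- rlnorm(1e4, meanlog = 0.3, sdlog = 0.6)
  d <- describe_deviation(x)
  nm <- c("0.25" = "q1", "0.5" = "median", "0.75" = "q3")
  for (p in c(0.25, 0.5, 0.75)) {
    qth <- qlnorm(p, 0.3, 0.6)
    se <- sqrt(p * (1 - p) / 1e4) / dlnorm(qth, 0.3, 0.6)
    expect_lt(abs(d[[nm[[as.character(p)]]]] - qth), 3 * se)
  }
})

test_that("paired differences follow per-protocol semantics", {
  rec <- data.frame(patient = rep(1:3, each = 2), level = 1,
                    arm = rep(c("3DPG", "CAS"), 3),
                    entry_mm = c(2.0, 1.5, 1.2, 1.0, 3.0, NA))
  d <- paired_differences(rec, "entry_mm")
  expect_equal(as.numeric(d), c(0.5, 0.2))
  expect_length(attr(d, "excluded"), 1)
  dup <- rbind(rec, rec[1, ])
  expect_error(paired_differences(dup, "entry_mm"), class = "spineaccDataIntegrity")
  # count conservation: 30 complete pairs give 30 differences
  rec30 <- data.frame(patient = rep(1:10, each = 6), level = rep(rep(1:3, each = 2), 10),
                      arm = rep(c("3DPG", "CAS"), 30),
                      entry_mm = runif(60))
  expect_length(paired_differences(rec30, "entry_mm"), 30)
})

test_that("the t interval matches the closed form to 1e-12 and decisions are dual to p-values", {
  set.seed(72)
  for (i in 1:25) {
    d <- rnorm(sample(5:40, 1), runif(1, -1, 1), runif(1, 0.2, 2))
    r <- noninferiority_test(d, margin = 1)
    ci <- oracle_t_interval(d, 0.95)
    expect_equal(c(r$ci_low, r$ci_high), ci, tolerance = 1e-12)
    expect_lte(r$ci_low, r$mean_diff); expect_gte(r$ci_high, r$mean_diff)
    # duality: CI rule at two-sided 95% == one-sided test at 2.5%
    expect_identical(r$non_inferior, r$p_noninferiority < 0.025)
  }
  z <- noninferiority_test(rep(0, 10), margin = 1)
  expect_equal(z$mean_diff, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_true(z$non_inferior)
  expect_lt(z$p_noninferiority, 1e-10)
  expect_error(noninferiority_test(0.4, margin = 1), class = "spineaccInsufficientData")
})

test_that("sample size degenerates, scales, and matches simulated power", {
  expect_equal(as.integer(sample_size_noninferiority(0, 1)), 2L)
  # doubling the margin-to-truth gap shrinks the size roughly fourfold
  # (exactly fourfold in the normal approximation; the t iteration adds
  # a few back at small n)
  nh <- as.integer(sample_size_noninferiority(1, 0.5, alpha = 0.05, power = 0.9))
  nf <- as.integer(sample_size_noninferiority(1, 1.0, alpha = 0.05, power = 0.9))
  expect_gt(nh / nf, 2.8); expect_lt(nh / nf, 4.5)
  n <- sample_size_noninferiority(sd = 1, margin = 0.5, alpha = 0.05, power = 0.9)
  expect_equal(as.integer(n), 36L)  # the classic one-sided 5%, 90% power size
  sim <- power_by_simulation(as.integer(n), 1, 0.5, 0, alpha = 0.05,
                             reps = 4000, seed = 73)
  expect_lt(abs(sim$power - attr(n, "power")), 3 * sim$se)
  expect_error(sample_size_noninferiority(1, margin = 0.2, true_diff = 0.5),
               class = "spineaccInfeasibleDesign")
})

test_that("the simulated test has the right size and approaches full power", {
  sz <- power_by_simulation(20, 1, margin = 0.5, true_diff = 0.5, alpha = 0.025,
                            reps = 5000, seed = 74)
  expect_lt(abs(sz$power - 0.025), 3 * sqrt(0.025 * 0.975 / 5000))
  hi <- power_by_simulation(200, 0.5, margin = 1, true_diff = 0, alpha = 0.025,
                            reps = 2000, seed = 75)
  expect_gt(hi$power, 0.999)
})

test_that("analyze_trial assembles descriptives and both non-inferiority tests", {
  set.seed(76)
  rec <- data.frame(patient = rep(1:10, each = 6), level = rep(rep(1:3, each = 2), 10),
                    arm = rep(c("3DPG", "CAS"), 30),
                    entry_mm = abs(rnorm(60, 1.8, 0.8)),
                    angle_deg = abs(rnorm(60, 5.5, 2)))
  an <- analyze_trial(rec)
  expect_s3_class(an$results$entry_mm, "noninferiority_result")
  expect_equal(an$results$entry_mm$n_pairs, 30)
  expect_equal(an$results$angle_deg$margin, 3)
  expect_equal(unname(an$descriptives[["entry_mm.3DPG"]]["n"]), 30)
  expect_output(print(an), "Non-inferiority")
})
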