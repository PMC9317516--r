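# Trial statistics: block-balanced side randomization, descriptive
# summaries, level-paired differences, one-sample t non-inferiority
# inference, sample size and simulated power.

#' Block-balanced side randomization
#'
#' Assigns the 3DPG technique to the left or right side of each patient
#' (the other side receives CAS), constrained so that within every
#' complete block of `block_size` patients exactly half have 3DPG on the
#' left. A trailing partial block takes the first entries of one more
#' balanced permutation.
#'
#' @param n_patients Number of patients.
#' @param block_size Even block size (>= 2).
#' @param seed Integer seed; the scheme is reproducible from it.
#' @return A data.frame of class `randomization_scheme` with columns
#'   `patient`, `block`, `side_3dpg`.
#' @export
randomize_sides <- function(n_patients, block_size = 2, seed = 1) {
  if (block_size < 2 || block_size %% 2 != 0)
    stop("block_size must be an even integer >= 2", call. = FALSE)
  if (n_patients < 1) stop("need at least one patient", call. = FALSE)
  n_blocks <- ceiling(n_patients / block_size)
  sides <- with_seed(seed, unlist(lapply(seq_len(n_blocks), function(b)
    sample(rep(c("left", "right"), block_size / 2)))))
  out <- data.frame(patient = seq_len(n_patients),
                    block = rep(seq_len(n_blocks), each = block_size)[seq_len(n_patients)],
                    side_3dpg = sides[seq_len(n_patients)],
                    stringsAsFactors = FALSE)
  class(out) <- c("randomization_scheme", "data.frame")
  out
}

#' Median and interquartile range
#'
#' Descriptive summary used for non-normally distributed accuracy
#' metrics: the median and the 25th/75th percentiles
#' (linear-interpolation quantiles).
#'
#' @param values Non-empty numeric vector.
#' @return A named numeric vector: `median`, `q1`, `q3`, `n`.
#' @export
describe_deviation <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to describe", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(values))
}

#' Level-paired differences between the study arms
#'
#' For every (patient, level) with both a 3DPG and a CAS screw measured,
#' returns the difference 3DPG - CAS of the chosen metric. Levels missing
#' either arm (screw failed or not measured) are excluded and reported,
#' matching per-protocol analysis semantics.
#'
#' @param records Deviation records from [run_pipeline()] (or any
#'   data.frame with columns `patient`, `level`, `arm` and the metric).
#' @param metric Column to difference, e.g. `"entry_mm"` or `"angle_deg"`.
#' @return Numeric vector of paired differences, with the excluded
#'   (patient, level) keys in attribute `excluded`.
#' @export
paired_differences <- function(records, metric = "entry_mm") {
  if (!metric %in% names(records)) stop("unknown metric: ", metric, call. = FALSE)
  key <- interaction(records$patient, records$level, drop = TRUE)
  if (anyDuplicated(paste(key, records$arm)))
    err("duplicate (patient, level, arm) records", "spineaccDataIntegrity")
  diffs <- numeric(0)
  excluded <- character(0)
  for (k in levels(key)) {
    sub <- records[key == k, ]
    v3 <- sub[[metric]][sub$arm == "3DPG"]
    vc <- sub[[metric]][sub$arm == "CAS"]
    if (length(v3) == 1L && length(vc) == 1L && !is.na(v3) && !is.na(vc)) {
      diffs <- c(diffs, v3 - vc)
    } else {
      excluded <- c(excluded, k)
    }
  }
  attr(diffs, "excluded") <- excluded
  diffs
}

#' One-sample t non-inferiority test
#'
#' Computes the mean paired difference (test minus control) with its
#' two-sided `(1 - alpha)` t confidence interval, declares non-inferiority
#' when the CI upper bound lies below the margin, and reports the
#' one-sided p-value for H0: mean difference >= margin. With a two-sided
#' 95% CI the CI rule is equivalent to a one-sided test at level 0.025.
#'
#' @param diffs Numeric vector of paired differences (n >= 2).
#' @param margin Non-inferiority margin, in the metric's units (> 0).
#' @param alpha Two-sided CI level is `1 - alpha` (default 0.05).
#' @param metric Optional label carried into the result.
#' @return An object of class `noninferiority_result`: `metric`,
#'   `n_pairs`, `mean_diff`, `ci_low`, `ci_high`, `margin`,
#'   `non_inferior`, `p_noninferiority`.
#' @export
noninferiority_test <- function(diffs, margin, alpha = 0.05, metric = NULL) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L) err("need at least 2 paired differences", "spineaccInsufficientData")
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    m <- mean(diffs)
    ci <- c(m, m)
    p <- if (m < margin) 0 else 1
  } else {
    tt <- stats::t.test(diffs, conf.level = 1 - alpha)
    ci <- as.numeric(tt$conf.int)
    m <- unname(tt$estimate)
    p <- stats::t.test(diffs, mu = margin, alternative = "less")$p.value
  }
  structure(list(metric = metric, n_pairs = length(diffs), mean_diff = m,
                 ci_low = ci[1L], ci_high = ci[2L], margin = margin,
                 alpha = alpha,
                 non_inferior = noninferiority_decision(ci[2L], margin),
                 p_noninferiority = p),
            class = "noninferiority_result")
}

#' Non-inferiority decision rule
#'
#' The CI-crossing rule: the test arm is non-inferior when the upper
#' bound of the confidence interval for (test - control) stays below the
#' margin. Smaller values mean better accuracy, so crossing the margin
#' would leave a clinically relevant disadvantage plausible.
#'
#' @param ci_high Upper CI bound for the mean difference (test - control).
#' @param margin Non-inferiority margin (> 0), same units.
#' @return Logical.
#' @export
noninferiority_decision <- function(ci_high, margin) {
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  ci_high < margin
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf("Non-inferiority test%s (n = %d pairs)\n",
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]"), x$n_pairs))
  cat(sprintf("  mean difference (test - control): %.3f\n", x$mean_diff))
  cat(sprintf("  %d%% CI: (%.3f, %.3f); margin: %.3f\n",
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$margin))
  cat(sprintf("  %s (one-sided p = %.4g)\n",
              if (x$non_inferior) "NON-INFERIOR: CI upper bound below margin"
              else "not non-inferior: CI upper bound crosses margin",
              x$p_noninferiority))
  invisible(x)
}

# analytic power of the one-sided noninferiority t-test at sample size n
noninf_power_t <- function(n, sd, margin, true_diff, alpha) {
  ncp <- (true_diff - margin) * sqrt(n) / sd
  stats::pt(stats::qt(alpha, df = n - 1), df = n - 1, ncp = ncp)
}

#' Sample size for a non-inferiority trial
#'
#' Smallest number of paired differences giving at least the target power
#' for the one-sided test of H0: mean >= margin, assuming Gaussian
#' differences with the given sd and true mean. Starts from the
#' normal-approximation size `((z_(1-alpha) + z_(power)) * sd /
#' (margin - true_diff))^2` and iterates on the noncentral t
#' distribution.
#'
#' @param sd Standard deviation of the paired differences.
#' @param margin Non-inferiority margin (> `true_diff`).
#' @param true_diff Assumed true mean difference (default 0).
#' @param alpha One-sided significance level (default 0.025, matching the
#'   two-sided 95% CI rule).
#' @param power Target power.
#' @return Integer sample size (>= 2), with the achieved analytic power
#'   as attribute `power`.
#' @export
sample_size_noninferiority <- function(sd, margin, true_diff = 0, alpha = 0.025,
                                       power = 0.9) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (margin <= true_diff)
    err("infeasible design: margin must exceed the true difference", "spineaccInfeasibleDesign")
  if (sd == 0) return(structure(2L, power = 1))
  n0 <- ((stats::qnorm(1 - alpha) + stats::qnorm(power)) * sd / (margin - true_diff))^2
  n <- max(2L, floor(n0) - 2L)
  while (noninf_power_t(n, sd, margin, true_diff, alpha) < power) n <- n + 1L
  while (n > 2L && noninf_power_t(n - 1L, sd, margin, true_diff, alpha) >= power)
    n <- n - 1L
  structure(as.integer(n), power = noninf_power_t(n, sd, margin, true_diff, alpha))
}

#' Simulated power of the non-inferiority test
#'
#' Monte-Carlo power: the fraction of simulated trials (Gaussian paired
#' differences) in which [noninferiority_test()] rejects, i.e. the CI
#' upper bound at the matching two-sided level stays below the margin.
#'
#' @param n Paired differences per trial.
#' @param sd,true_diff Gaussian difference model.
#' @param margin Non-inferiority margin.
#' @param alpha One-sided level (the CI used is two-sided `1 - 2 alpha`).
#' @param reps Number of simulated trials (>= 1000).
#' @param seed Optional seed.
#' @return A list: `power`, `se` (binomial standard error), `reps`.
#' @export
power_by_simulation <- function(n, sd, margin, true_diff = 0, alpha = 0.025,
                                reps = 10000, seed = NULL) {
  if (reps < 1000) stop("need reps >= 1000", call. = FALSE)
  run <- function() {
    x <- matrix(stats::rnorm(reps * n, true_diff, sd), reps, n)
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (n - 1))
    tcrit <- stats::qt(1 - alpha, df = n - 1)
    mean(m + tcrit * s / sqrt(n) < margin)
  }
  pw <- if (is.null(seed)) run() else with_seed(seed, run())
  list(power = pw, se = sqrt(pw * (1 - pw) / reps), reps = reps)
}

#' Full trial analysis of deviation records
#'
#' Per-arm descriptive statistics (median, IQR) and the level-paired
#' non-inferiority analysis for both accuracy metrics.
#'
#' @param records Deviation records from [run_pipeline()].
#' @param margins Named margins: `entry_mm` (mm) and `angle_deg`
#'   (degrees).
#' @param alpha Two-sided CI level is `1 - alpha`.
#' @return An object of class `trial_analysis`: per-metric
#'   `noninferiority_result`s, descriptives, and exclusion counts.
#' @export
analyze_trial <- function(records, margins = c(entry_mm = 1, angle_deg = 3),
                          alpha = 0.05) {
  stopifnot(all(c("entry_mm", "angle_deg") %in% names(margins)))
  res <- list()
  desc <- list()
  for (metric in c("entry_mm", "angle_deg")) {
    d <- paired_differences(records, metric)
    res[[metric]] <- noninferiority_test(d, margins[[metric]], alpha = alpha,
                                         metric = metric)
    res[[metric]]$excluded <- attr(d, "excluded")
    for (arm in c("3DPG", "CAS"))
      desc[[paste(metric, arm, sep = ".")]] <-
        describe_deviation(records[[metric]][records$arm == arm])
  }
  structure(list(results = res, descriptives = desc,
                 n_screws = nrow(records),
                 n_measured = sum(!is.na(records$entry_mm))),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Split-spine trial analysis: %d screws, %d measured\n\n",
              x$n_screws, x$n_measured))
  for (metric in names(x$results)) {
    for (arm in c("3DPG", "CAS")) {
      d <- x$descriptives[[paste(metric, arm, sep = ".")]]
      cat(sprintf("  %s %-4s median %.2f (IQR %.2f-%.2f, n=%d)\n",
                  metric, arm, d["median"], d["q1"], d["q3"], d["n"]))
    }
    print(x$results[[metric]])
    cat("\n")
  }
  invisible(x)
}
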