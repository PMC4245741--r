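test_that("endpoint and AUC QALYs follow the stated conversions", {
  expect_equal(endpoint_qaly(0.447), 0.11175) # reported as 0.112
  expect_equal(endpoint_qaly(0), 0)
  expect_equal(endpoint_qaly(0.654), 0.1635)
  expect_equal(auc_qaly(0.5, 0.5), 0.125)
  expect_equal(auc_qaly(0.513, 0.447), 0.12)
  expect_equal(auc_qaly(0, 1, horizon_years = 1), 0.5)
  # the two methods coincide when utility is flat
  u <- seq(-0.5, 1, by = 0.25)
  expect_equal(auc_qaly(u, u), endpoint_qaly(u))
})

test_that("extrapolation maintains the 3-month difference, costs untouched", {
  expect_equal(extrapolate_qaly(0.120, 0.447, 0), 0.120)
  expect_equal(extrapolate_qaly(0.120, 0.447, 3), 0.23175) # reported 0.231
  expect_equal(extrapolate_qaly(0.120, 0.447, 9), 0.455250) # reported 0.454
  expect_error(extrapolate_qaly(0.1, 0.4, 4), "unsupported horizon")
  # between-arm difference is affine in extra months with slope du/12
  q <- c(control = 0.120, intervention = 0.156)
  u <- c(control = 0.447, intervention = 0.654)
  for (extra in c(0, 3, 6, 9)) {
    d <- extrapolate_qaly(q[2], u[2], extra) - extrapolate_qaly(q[1], u[1],
                                                                extra)
    expect_equal(unname(d), unname(q[2] - q[1] + (u[2] - u[1]) * extra / 12))
  }
})

test_that("baseline adjustment equals a hand-coded normal-equations solve", {
  set.seed(7)
  n <- 24
  rec <- data.frame(
    arm = rep(c("control", "intervention"), each = n / 2),
    u_baseline = runif(n, 0.3, 0.8))
  rec$u_3month <- 0.2 + 0.6 * rec$u_baseline +
    0.05 * (rec$arm == "intervention") + rnorm(n, 0, 0.05)
  adj <- baseline_adjusted_diff(rec)
  # independent oracle: explicit (X'X)^-1 X'y and conventional SE
  y <- auc_qaly(rec$u_baseline, rec$u_3month)
  X <- cbind(1, rec$arm == "intervention", rec$u_baseline)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - 3)
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  expect_equal(adj$mean_diff, beta[2], tolerance = 1e-10)
  expect_equal(adj$se_diff, se, tolerance = 1e-10)
})

test_that("with balanced baselines the adjusted diff is the crude diff", {
  base <- rep(c(0.4, 0.5, 0.6, 0.7), 2) # identical baseline sets per arm
  rec <- data.frame(arm = rep(c("control", "intervention"), each = 4),
                    u_baseline = base)
  rec$qaly <- c(0.10, 0.11, 0.12, 0.13, 0.14, 0.16, 0.15, 0.17)
  rec$u_3month <- rec$qaly * 4
  adj <- baseline_adjusted_diff(rec)
  crude <- mean(rec$qaly[5:8]) - mean(rec$qaly[1:4])
  expect_equal(adj$mean_diff, crude, tolerance = 1e-10)
})

test_that("adjusted regression recovers a known effect under confounding", {
  set.seed(42)
  n <- 400
  rec <- data.frame(arm = rep(c("control", "intervention"), each = n / 2))
  # deliberate baseline imbalance between arms
  rec$u_baseline <- rnorm(n, ifelse(rec$arm == "intervention", 0.60, 0.50),
                          0.08)
  rec$u_3month <- 0.1 + 0.7 * rec$u_baseline +
    0.05 * (rec$arm == "intervention") + rnorm(n, 0, 0.06)
  adj <- baseline_adjusted_diff(rec, qaly_method = "endpoint")
  expect_lt(abs(adj$mean_diff - 0.05 * 0.25), 2 * adj$se_diff)
})

test_that("adjusted-diff contracts: completeness, arm counts, degeneracy", {
  rec <- data.frame(arm = rep(c("control", "intervention"), each = 5),
                    u_baseline = runif(10, 0.4, 0.7),
                    u_3month = runif(10, 0.4, 0.7))
  rec$u_3month[1] <- NA
  expect_message(baseline_adjusted_diff(rec), "1 incomplete")
  expect_error(baseline_adjusted_diff(rec[c(1:3, 6:10), ]), "at least 3")
  degenerate <- rec
  degenerate$u_baseline <- as.numeric(degenerate$arm == "intervention")
  expect_error(suppressMessages(baseline_adjusted_diff(degenerate)),
               "degenerate design")
})

test_that("adjusted horizons extend linearly in the utility difference", {
  adj <- structure(list(horizon_months = 3, mean_diff = 0.008,
                        se_diff = 0.009, u_mean_diff = 0.06,
                        u_se_diff = 0.072, n = 36), class = "adjusted_diff")
  tab <- adjusted_diff_table(adj)
  expect_equal(tab$mean_diff, 0.008 + 0.06 * c(0, 3, 6, 9) / 12)
  expect_equal(tab$se_diff, 0.009 + 0.072 * c(0, 3, 6, 9) / 12)
})

test_that("the UK tariff anchors, single-decrement states and monotonicity hold", {
  vs <- load_eq5d_value_set()
  expect_equal(eq5d_utility(c(1, 1, 1, 1, 1), vs), 1)
  expect_equal(eq5d_utility(c(3, 3, 3, 3, 3), vs), -0.594)
  # one level-2 dimension: 1 - constant - that decrement
  expect_equal(eq5d_utility(c(2, 1, 1, 1, 1), vs),
               1 - vs[["constant"]] - vs[["mobility_2"]])
  expect_equal(eq5d_utility(c(1, 1, 1, 2, 1), vs),
               1 - vs[["constant"]] - vs[["pain_discomfort_2"]])
  # exhaustive: all 243 profiles in range, weakly monotone per dimension
  grid <- as.matrix(expand.grid(rep(list(1:3), 5)))
  u <- eq5d_utility(grid, vs)
  expect_true(all(u >= -0.594 & u <= 1))
  for (j in 1:5) {
    for (lev in 1:2) {
      lower <- grid[grid[, j] == lev, , drop = FALSE]
      worse <- lower; worse[, j] <- lev + 1
      expect_true(all(eq5d_utility(worse, vs) <= eq5d_utility(lower, vs)))
    }
  }
  expect_error(eq5d_utility(c(0, 1, 1, 1, 1), vs), "malformed profile")
  expect_error(eq5d_utility(c(1, 1, 1, 1), vs), "malformed profile")
})
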