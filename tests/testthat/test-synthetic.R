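test_that("the generator is seed-deterministic and honours dropout", {
  cfg <- generator_config(seed = 12, targets = trial_inputs)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  none <- generate_cohort(generator_config(seed = 12, dropout_rate = 0,
                                           targets = trial_inputs))
  expect_equal(sum(!none$dropout), 36)
  expect_equal(sum(none$arm == "intervention"), 20)
  expect_equal(sum(none$arm == "control"), 16)
  # dropouts carry no follow-up data
  cohort <- generate_cohort(generator_config(seed = 4, dropout_rate = 0.5,
                                             targets = trial_inputs))
  dropped <- cohort[cohort$dropout, ]
  expect_true(all(is.na(dropped$u_3month)))
  expect_true(all(is.na(dropped$count_gp_appointment)))
})

test_that("generated values respect their supports", {
  cohort <- generate_cohort(generator_config(
    n_per_arm = c(control = 300, intervention = 300), seed = 2,
    targets = trial_inputs))
  counts <- as.matrix(cohort[grep("^count_", names(cohort))])
  counts <- counts[!is.na(counts)]
  expect_true(all(counts >= 0 & counts == floor(counts)))
  u <- c(cohort$u_baseline, cohort$u_3month)
  u <- u[!is.na(u)]
  expect_true(all(u >= -0.594 & u <= 1))
})

test_that("large cohorts recover the target summaries within 2%", {
  cohort <- generate_cohort(generator_config(
    n_per_arm = c(control = 10000, intervention = 10000), seed = 27,
    dropout_rate = 0, targets = trial_inputs))
  gp <- cohort$count_gp_appointment[cohort$arm == "control"]
  expect_lt(abs(mean(gp) - 1.56) / 1.56, 0.02)
  rt <- roundtrip_summary(cohort)
  expect_lt(abs(rt$control$utility_mean - 0.447) / 0.447, 0.02)
  expect_lt(abs(rt$intervention$utility_mean - 0.654) / 0.654, 0.02)
  for (a in c("control", "intervention")) {
    target <- trial_inputs$arms[[a]]$usage
    got <- rt[[a]]$usage
    shared <- intersect(target$category, got$category)
    expect_setequal(shared, target$category)
    for (cat in shared) {
      m_t <- target$mean[target$category == cat]
      m_g <- got$mean[got$category == cat]
      # 2% or, for small-mean categories where 2% is under the Monte-Carlo
      # resolution at n = 10,000, four standard errors
      mc_se <- sqrt(got$variance[got$category == cat] / 10000)
      expect_lt(abs(m_g - m_t), max(0.02 * m_t, 4 * mc_se))
    }
  }
  # end-to-end: the endpoint QALY arm effect is recovered within 2%
  dq <- endpoint_qaly(rt$intervention$utility_mean) -
    endpoint_qaly(rt$control$utility_mean)
  expect_lt(abs(dq - (0.654 - 0.447) * 0.25) / ((0.654 - 0.447) * 0.25), 0.02)
})

test_that("trial-scale cohorts show baseline imbalance across seeds", {
  imbalance <- vapply(1:15, function(s) {
    ch <- generate_cohort(generator_config(seed = s, targets = trial_inputs))
    mean(ch$u_baseline[ch$arm == "intervention"]) -
      mean(ch$u_baseline[ch$arm == "control"])
  }, numeric(1))
  expect_gt(sd(imbalance), 0.005) # the adjustment path has work to do
  expect_gt(max(abs(imbalance)), 0.02)
})

test_that("roundtrip and generator contracts error as specified", {
  cohort <- generate_cohort(generator_config(seed = 3,
                                             targets = trial_inputs))
  expect_error(roundtrip_summary(cohort[cohort$arm == "control", ]),
               "insufficient data|fewer than 2")
  zero <- data.frame(arm = rep(c("control", "intervention"), each = 3),
                     u_3month = runif(6, 0.4, 0.6),
                     count_gp_appointment = 0L)
  expect_equal(roundtrip_summary(zero)$control$usage$mean, 0)
  # utility variance too large for a beta on the tariff range
  bad <- trial_inputs
  bad$arms$control$utility_variance <- 5
  expect_error(generate_cohort(generator_config(targets = bad)),
               "unreachable")
})

test_that("written cohorts are byte-identical under one seed", {
  cfg <- generator_config(seed = 8, targets = trial_inputs)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$seed, 8)
  expect_equal(manifest$n_generated, 36)
})
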