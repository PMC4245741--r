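test_that("the engine is a deterministic function of seed and config", {
  cfg <- scenario_config(n_sims = 500, seed = 99)
  expect_identical(run_psa(cfg, trial_inputs), run_psa(cfg, trial_inputs))
  other <- run_psa(scenario_config(n_sims = 500, seed = 100), trial_inputs)
  expect_false(identical(other$cost_control,
                         run_psa(cfg, trial_inputs)$cost_control))
})

test_that("point-mass distributions reproduce the deterministic limit", {
  inp <- trial_inputs
  for (a in c("control", "intervention")) {
    inp$arms[[a]]$usage$variance <- 0
    inp$arms[[a]]$utility_variance <- 0
  }
  cfg <- scenario_config(qaly_method = "endpoint", n_sims = 1, seed = 1,
                         mff = mff_spec(1, 1),
                         parameter_mode = "table2-moments")
  d <- run_psa(cfg, inp)
  expect_equal(d$cost_control,
               attr(deterministic_cost(trial_inputs$arms$control,
                                       trial_inputs$unit_costs), "total"))
  expect_equal(d$cost_intervention,
               attr(deterministic_cost(trial_inputs$arms$intervention,
                                       trial_inputs$unit_costs), "total"))
  expect_equal(d$qaly_control, 0.447 * 0.25)
  expect_equal(d$qaly_intervention, 0.654 * 0.25)
})

test_that("mean incremental QALYs in endpoint mode is du * 0.25 in both modes", {
  for (mode in c("table2-moments", "ci-implied")) {
    d <- run_psa(scenario_config("endpoint", n_sims = 20000, seed = 5,
                                 parameter_mode = mode), trial_inputs)
    target <- if (mode == "table2-moments") (0.654 - 0.447) * 0.25 else 0.052
    inc <- incremental(d)
    expect_lt(abs(mean(inc$dq) - target),
              3 * sd(inc$dq) / sqrt(length(inc$dq)) + 1e-4)
  }
})

test_that("each parameter draws from its own substream", {
  cfg <- scenario_config(n_sims = 200, seed = 21)
  base <- run_psa(cfg, trial_inputs)
  # re-including the bundled intervention categories must not perturb the
  # control-arm cost draws or any QALY draws
  full <- run_psa(cfg, load_trial_inputs(bundled = character(0)))
  expect_identical(base$cost_control, full$cost_control)
  expect_identical(base$qaly_control, full$qaly_control)
  expect_identical(base$qaly_intervention, full$qaly_intervention)
  expect_true(all(full$cost_intervention > base$cost_intervention))
  # substream labels map to distinct seeds
  labels <- c("mff", "utility/control", "utility/intervention",
              paste0("cost/control/",
                     trial_inputs$arms$control$usage$category),
              paste0("cost/intervention/",
                     trial_inputs$arms$intervention$usage$category))
  seeds <- vapply(labels, function(l) hospicecua:::stream_seed(21, l),
                  integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("baseline-adjusted mode samples the QALY difference directly", {
  d <- run_psa(scenario_config("baseline_adjusted", n_sims = 20000, seed = 3),
               trial_inputs)
  expect_true("qaly_diff" %in% names(d))
  expect_lt(abs(mean(d$qaly_diff) - 0.008), 3 * 0.009 / sqrt(20000))
  expect_lt(abs(sd(d$qaly_diff) - 0.009), 0.0005)
  d6 <- run_psa(scenario_config("baseline_adjusted", horizon_months = 6,
                                n_sims = 5000, seed = 3), trial_inputs)
  expect_lt(abs(mean(d6$qaly_diff) - 0.023), 3 * 0.027 / sqrt(5000))
})

test_that("summaries use arithmetic means and empirical percentile intervals", {
  const <- manual_draws(dc = rep(50, 10), dq = rep(0.01, 10))
  s <- summarise_psa(const)
  expect_equal(s$incremental_cost$ci, c(50, 50))
  half <- manual_draws(dc = rep(c(0, 1), 50), dq = rep(0.01, 100))
  expect_equal(summarise_psa(half)$incremental_cost$mean, 0.5)
  # sort-based oracle for the percentile interval
  set.seed(8)
  dc <- rgamma(4001, 2, scale = 100)
  s2 <- summarise_psa(manual_draws(dc = dc, dq = rep(0.01, 4001)))
  srt <- sort(dc)
  expect_equal(s2$incremental_cost$ci,
               unname(quantile(srt, c(0.025, 0.975))))
  expect_error(summarise_psa(manual_draws(dc = 1, dq = 1)), "at least 2")
})

test_that("scenario configs validate their fields and round-trip via JSON", {
  expect_error(scenario_config(horizon_months = 5), "horizon")
  expect_error(scenario_config(n_sims = 0), "n_sims")
  expect_error(scenario_config(wtp_grid = c(5, 1)), "ascending")
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(qaly_method = "auc", horizon_months = 6,
                            n_sims = 123, seed = 9, mff = c(1.0, 1.2),
                            parameter_mode = "ci-implied"),
                       tmp, auto_unbox = TRUE)
  cfg <- read_scenario_config(tmp)
  expect_equal(cfg$qaly_method, "auc")
  expect_equal(cfg$horizon_months, 6L)
  expect_equal(cfg$n_sims, 123L)
  expect_equal(attr(cfg$mff, "mff_mean"), 1.1)
})
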