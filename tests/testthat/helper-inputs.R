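# Shared fixture objects, loaded once per test run.
trial_inputs <- load_trial_inputs()

# Build a psa_draws object by hand for decision-output unit tests.
manual_draws <- function(dc, dq, cost_control = 1000) {
  structure(data.frame(cost_control = cost_control,
                       cost_intervention = cost_control + dc,
                       qaly_control = 0.1,
                       qaly_intervention = 0.1 + dq),
            config = scenario_config(n_sims = length(dc)),
            class = c("psa_draws", "data.frame"))
}
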