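# Shared fixtures, built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# short line-attractor session + fit for module-level tests
short_line_session <- function() memo("short_line", {
  synthetic_session(ground_truth_scenario("line_attractor", duration = 300,
                                          seed = 11))
})

short_line_fit <- function() memo("short_line_fit", {
  ss <- short_line_session()
  fit_rslds(ss$recording, ss$inputs, K = 3, D = 8,
            config = list(max_iter = 25, seed = 1))
})

short_rot_session <- function() memo("short_rot", {
  synthetic_session(ground_truth_scenario("rotational", duration = 300,
                                          seed = 21))
})

# the 10-seed line-attractor fitting experiment shared by the acceptance
# criteria (600 s sessions, ground-truth slow tau 150 s, D = 8, K = 3)
acceptance_line_runs <- function(seeds = 1:10) memo("acc_line", {
  lapply(seeds, function(sd) {
    sc <- ground_truth_scenario("line_attractor", seed = sd)
    ss <- synthetic_session(sc)
    fit <- fit_rslds(ss$recording, ss$inputs, K = sc$K, D = sc$D,
                     config = list(max_iter = 30, seed = sd))
    enr <- select_analysis_state(fit$most_likely_states, ss$annotations, "attack")
    spec <- time_constants(fit$params$A[[enr$state]], fit$sampling_rate,
                           state = enr$state)
    list(session = ss, fit = fit, enriched = enr, spectrum = spec,
         score = line_attractor_score(spec))
  })
})

acceptance_rot_runs <- function(seeds = 1:10) memo("acc_rot", {
  lapply(seeds, function(sd) {
    sc <- ground_truth_scenario("rotational", seed = sd)
    ss <- synthetic_session(sc)
    fit <- fit_rslds(ss$recording, ss$inputs, K = sc$K, D = sc$D,
                     config = list(max_iter = 30, seed = sd))
    enr <- select_analysis_state(fit$most_likely_states, ss$annotations, "mount_usv")
    spec <- time_constants(fit$params$A[[enr$state]], fit$sampling_rate,
                           state = enr$state)
    list(session = ss, fit = fit, enriched = enr, spectrum = spec,
         score = line_attractor_score(spec))
  })
})
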