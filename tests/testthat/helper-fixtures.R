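# Shared fixtures built in code: tiny cohorts and parameter draws.

default_schedule <- c(-60, 30, 60, 180, 600, 1200, 1800)

# random positive parameter draws around the healthy priors (log-normal)
random_params <- function(n, sd = 0.5, seed = 1) {
  th <- prior_expectations()
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    rate_parameters(
      k_diff = th$k_diff * exp(rnorm(1, 0, sd)),
      k_ph = th$k_ph * exp(rnorm(1, 0, sd)),
      k_hp = th$k_hp * exp(rnorm(1, 0, sd)),
      k_hb = th$k_hb * exp(rnorm(1, 0, sd)),
      xi = th$xi * exp(rnorm(1, 0, sd / 2)))))
}

# a small single-stage virtual cohort
small_cohort <- function(n = 4, noise_sd = 0.18, seed = 11,
                         stage = "F0") {
  counts <- stats::setNames(rep(0L, 5), paste0("F", 0:4))
  counts[stage] <- n
  generate_cohort(cohort_spec(n_patients = n, stage_counts = counts,
                              noise_sd = noise_sd, seed = seed))
}

# one deterministic noise-free patient with known parameters
noise_free_patient <- function(params = prior_expectations(), id = "p1",
                               weight = 70, schedule = default_schedule) {
  spec <- cohort_spec(n_patients = 1,
                      stage_counts = c(F0 = 1, F1 = 0, F2 = 0, F3 = 0,
                                       F4 = 0),
                      noise_sd = 0, schedule_s = schedule, seed = 1)
  generate_patient(params, spec, patient_id = id, body_weight = weight,
                   stage = "F0")
}
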