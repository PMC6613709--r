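#' Default population model of the virtual-cohort generator
#'
#' Typical values are the healthy-cohort expectations
#' ([prior_expectations()]); inter-individual variability is set to a
#' typical pharmacokinetic ~30% CV: log-scale SD 0.3 for the four
#' lognormal rates and natural-scale SD 0.3 for the normal signal scale.
#'
#' @return [population_model()]
#' @export
generator_population <- function() {
  th <- prior_expectations()
  population_model(lapply(PARAM_NAMES, function(nm)
    parameter_distribution(nm,
                           family = if (nm == "xi") "normal" else "lognormal",
                           theta = th[[nm]],
                           omega = 0.3)))
}

#' Specification of a synthetic virtual cohort
#'
#' Defaults emulate the clinical study conditions: 91 patients with
#' fibrosis-stage counts 29/16/25/14/7 (F0-F4), the clinical sampling
#' schedule (pre-injection baseline, arterial ~30 s, portal-venous ~60 s,
#' then 3, 10, 20, 30 min), additive Gaussian delta-R1 noise with SD equal
#' to the 0.18 uncertainty floor, and ROI SEMs below the floor. Fibrosis
#' acts multiplicatively on the typical hepatocyte uptake rate
#' (decreasing with stage) and raises biliary excretion in cirrhosis.
#'
#' @param n_patients cohort size
#' @param stage_counts integer counts per stage F0-F4; must sum to
#'   `n_patients`
#' @param population [population_model()] the effects are drawn from
#' @param kph_stage_factors multiplicative factors on theta(k_ph) per stage
#' @param khb_f4_factor multiplicative factor on theta(k_hb) at F4
#' @param schedule_s sampling times (s relative to injection)
#' @param noise_sd additive Gaussian delta-R1 noise SD (s^-1)
#' @param sem_value constant per-timepoint ROI SEM written into records
#' @param weight_range body-weight range (kg), sampled uniformly
#' @param seed RNG seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_patients = 91,
                        stage_counts = c(F0 = 29, F1 = 16, F2 = 25,
                                         F3 = 14, F4 = 7),
                        population = generator_population(),
                        kph_stage_factors = c(F0 = 1.0, F1 = 0.9, F2 = 0.75,
                                              F3 = 0.5, F4 = 0.35),
                        khb_f4_factor = 1.5,
                        schedule_s = c(-60, 30, 60, 180, 600, 1200, 1800),
                        noise_sd = 0.18, sem_value = 0.05,
                        weight_range = c(50, 100), seed = 42L) {
  if (sum(stage_counts) != n_patients)
    stop("stage_counts must sum to n_patients", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.unsorted(schedule_s, strictly = TRUE))
    stop("schedule_s must be strictly increasing", call. = FALSE)
  structure(list(n_patients = n_patients, stage_counts = stage_counts,
                 population = population,
                 kph_stage_factors = kph_stage_factors,
                 khb_f4_factor = khb_f4_factor, schedule_s = schedule_s,
                 noise_sd = noise_sd, sem_value = sem_value,
                 weight_range = weight_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw per-patient parameters and fibrosis stages
#'
#' Stages are assigned by the spec counts; random effects eta are drawn
#' N(0, omega^2) per parameter; rates follow the lognormal map with the
#' stage-adjusted typical value, and the signal scale follows the normal
#' map truncated to be positive.
#'
#' @param spec [cohort_spec()]
#' @return data.frame: patient_id, fibrosis_stage, body_weight, the five
#'   parameters, and the five eta draws (columns `eta_*`)
#' @export
sample_parameters <- function(spec) {
  stages <- rep(names(spec$stage_counts), spec$stage_counts)
  n <- spec$n_patients
  om <- pop_omegas(spec$population)
  th <- pop_thetas(spec$population)
  eta <- vapply(PARAM_NAMES, function(nm) stats::rnorm(n, 0, om[[nm]]),
                numeric(n))
  if (!is.matrix(eta))
    eta <- matrix(eta, nrow = 1, dimnames = list(NULL, PARAM_NAMES))
  weights <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  rows <- lapply(seq_len(n), function(i) {
    st <- stages[i]
    th_i <- th
    th_i[["k_ph"]] <- th_i[["k_ph"]] * spec$kph_stage_factors[[st]]
    if (st == "F4") th_i[["k_hb"]] <- th_i[["k_hb"]] * spec$khb_f4_factor
    xi <- th_i[["xi"]] + eta[i, "xi"]
    while (xi <= 0) xi <- th_i[["xi"]] + stats::rnorm(1, 0, om[["xi"]])
    data.frame(patient_id = sprintf("vp%03d", i), fibrosis_stage = st,
               body_weight = weights[i],
               k_diff = th_i[["k_diff"]] * exp(eta[i, "k_diff"]),
               k_ph = th_i[["k_ph"]] * exp(eta[i, "k_ph"]),
               k_hp = th_i[["k_hp"]] * exp(eta[i, "k_hp"]),
               k_hb = th_i[["k_hb"]] * exp(eta[i, "k_hb"]),
               xi = xi,
               eta_k_diff = eta[i, "k_diff"], eta_k_ph = eta[i, "k_ph"],
               eta_k_hp = eta[i, "k_hp"], eta_k_hb = eta[i, "k_hb"],
               eta_xi = xi - th_i[["xi"]])
  })
  do.call(rbind, rows)
}

#' Generate one virtual patient's MRI record
#'
#' Simulates the forward model at the schedule times, maps to liver and
#' spleen delta-R1, adds independent Gaussian noise of SD `noise_sd` to
#' every post-injection point, and sets the pre-injection baseline to
#' exactly zero (delta-R1 is change from baseline by definition).
#'
#' @param params [rate_parameters()] for this patient
#' @param spec [cohort_spec()]
#' @param patient_id id string
#' @param body_weight kg
#' @param stage fibrosis stage label
#' @param constants [physiological_constants()]
#' @return [patient_record()]
#' @export
generate_patient <- function(params, spec, patient_id = "vp001",
                             body_weight = 70, stage = "unknown",
                             constants = physiological_constants()) {
  dose <- dose_protocol(body_weight = body_weight)
  times <- spec$schedule_s
  traj <- simulate_gadoxetate(params, constants, dose, times)
  sig <- predict_delta_r1(traj, params, constants)
  post <- times >= 0
  n_post <- sum(post)
  liver <- ifelse(post, sig$liver + stats::rnorm(length(times), 0,
                                                 spec$noise_sd), 0)
  spleen <- ifelse(post, sig$spleen + stats::rnorm(length(times), 0,
                                                   spec$noise_sd), 0)
  patient_record(patient_id, times,
                 liver_dr1 = liver,
                 liver_sem = rep(spec$sem_value, length(times)),
                 spleen_dr1 = spleen,
                 spleen_sem = rep(spec$sem_value, length(times)),
                 body_weight = body_weight, fibrosis_stage = stage)
}

#' Generate a virtual cohort with ground truth
#'
#' @param spec [cohort_spec()]
#' @param constants [physiological_constants()]
#' @return list: `cohort` (a [cohort()]) and `truth` (data.frame of
#'   generating parameters, random effects and stages per patient)
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            constants = physiological_constants()) {
  withr_seed(spec$seed, {
    truth <- sample_parameters(spec)
    pats <- lapply(seq_len(nrow(truth)), function(i) {
      r <- truth[i, ]
      params <- rate_parameters(r$k_diff, r$k_ph, r$k_hp, r$k_hb, r$xi)
      generate_patient(params, spec, patient_id = r$patient_id,
                       body_weight = r$body_weight,
                       stage = r$fibrosis_stage, constants = constants)
    })
    list(cohort = cohort(pats,
                         provenance = sprintf("synthetic cohort, seed %d",
                                              spec$seed)),
         truth = truth)
  })
}
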