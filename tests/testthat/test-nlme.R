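test_that("individual parameter maps follow the two distribution families", {
  ln <- parameter_distribution("k_ph", "lognormal", theta = 4.7e-3,
                               omega = 0.1)
  no <- parameter_distribution("xi", "normal", theta = 1.6, omega = 1)
  expect_equal(individual_parameter(ln, 0), 4.7e-3)
  expect_equal(individual_parameter(no, 0), 1.6)
  expect_equal(individual_parameter(ln, log(2)), 9.4e-3, tolerance = 1e-12)
  expect_equal(individual_parameter(no, -0.2), 1.4, tolerance = 1e-12)
  # strictly monotone in eta for both families
  etas <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(vapply(etas, individual_parameter,
                              numeric(1), dist = ln)) > 0))
  expect_true(all(diff(vapply(etas, individual_parameter,
                              numeric(1), dist = no)) > 0))
})

test_that("population model validates families and parameter set", {
  expect_s3_class(prior_population(), "population_model")
  expect_error(population_model(list(
    parameter_distribution("xi", "lognormal", 1.6, 1),
    parameter_distribution("k_diff", "lognormal", 1e-3, 0.1),
    parameter_distribution("k_ph", "lognormal", 1e-3, 0.1),
    parameter_distribution("k_hp", "lognormal", 1e-3, 0.1),
    parameter_distribution("k_hb", "lognormal", 1e-3, 0.1))),
    "xi must be normal")
  expect_error(population_model(list(
    parameter_distribution("xi", "normal", 1.6, 1))), "five")
})

test_that("joint objective matches hand arithmetic on a one-point fixture", {
  # single patient, single post-3-min observation pair
  pat <- patient_record("toy", 600, 2.0, 0.05, 0.8, 0.05)
  co <- cohort(list(pat))
  pop <- prior_population()
  k <- physiological_constants()
  d <- dose_protocol(body_weight = 70)
  eta <- stats::setNames(c(0.1, -0.2, 0, 0, 0.3),
                         c("k_diff", "k_ph", "k_hp", "k_hb", "xi"))
  # independent reconstruction through the public simulation surface
  params <- rate_parameters(1.7e-3 * exp(0.1), 4.7e-3 * exp(-0.2),
                            2.8e-5, 3.8e-5, 1.6 + 0.3)
  traj <- simulate_gadoxetate(params, k, d, 600)
  sig <- predict_delta_r1(traj, params, k)
  expected <- 0.5 * ((sig$liver - 2)^2 + (sig$spleen - 0.8)^2) / 0.18^2 +
    0.1^2 / (2 * 0.1^2) + 0.2^2 / (2 * 0.1^2) + 0.3^2 / (2 * 1^2) +
    log(0.1) + log(0.1) + log(0.01) + log(0.01) + log(1)
  expect_equal(neg_log_joint(list(eta), pop, co), expected,
               tolerance = 1e-12)
  # zero effects and perfect data leave only the log-omega constant
  pat0 <- noise_free_patient()
  co0 <- cohort(list(pat0))
  zero <- stats::setNames(numeric(5), c("k_diff", "k_ph", "k_hp", "k_hb",
                                        "xi"))
  const <- sum(log(c(0.1, 0.1, 0.01, 0.01, 1)))
  expect_equal(neg_log_joint(list(zero), pop, co0), const,
               tolerance = 1e-10)
  # any nonzero effect with perfect data strictly increases the objective
  up <- zero; up[["k_ph"]] <- 0.05
  expect_gt(neg_log_joint(list(up), pop, co0),
            neg_log_joint(list(zero), pop, co0))
  # omega = 0 with nonzero eta is an infinite penalty, not an exception
  pop0 <- prior_population(omega = c(k_ph = 0))
  expect_equal(neg_log_joint(list(up), pop0, co0), Inf)
})

test_that("MAP estimate shrinks to the prior as data become uninformative", {
  gen <- small_cohort(n = 1, seed = 53)
  pat <- gen$cohort$patients[[1]]
  pop <- prior_population()
  vague <- uncertainty_config(sigma_floor = 1e5)
  est <- fit_individual_map(pat, pop, config = vague)
  expect_equal(max(abs(est$eta)), 0, tolerance = 1e-4)
  expect_equal(est$params$k_ph, 4.7e-3, tolerance = 1e-3)
  expect_equal(est$params$xi, 1.6, tolerance = 1e-3)
})

test_that("MAP approaches the STS optimum as the priors widen", {
  gen <- small_cohort(n = 1, seed = 59)
  pat <- gen$cohort$patients[[1]]
  sts <- fit_sts(pat)
  wide <- prior_population(omega = c(k_diff = 25, k_ph = 25, k_hp = 25,
                                     k_hb = 25, xi = 2500))
  map <- fit_individual_map(pat, wide, eta0 = stats::setNames(
    log(unlist(sts$params)[c("k_diff", "k_ph", "k_hp", "k_hb")] /
          c(1.7e-3, 4.7e-3, 2.8e-5, 3.8e-5)) |>
      c(sts$params$xi - 1.6),
    c("k_diff", "k_ph", "k_hp", "k_hb", "xi")))
  expect_equal(map$gof$chi2, sts$gof$chi2, tolerance = 0.02)
  expect_equal(log(map$params$k_ph), log(sts$params$k_ph),
               tolerance = 0.05)
})

test_that("MAP random effects are smaller than the unpenalized ones", {
  gen <- small_cohort(n = 3, seed = 61)
  pop <- prior_population()
  th <- c(k_diff = 1.7e-3, k_ph = 4.7e-3, k_hp = 2.8e-5,
          k_hb = 3.8e-5, xi = 1.6)
  for (pat in gen$cohort$patients) {
    map <- fit_individual_map(pat, pop)
    sts <- fit_sts(pat)
    eta_sts <- c(log(sts$params$k_diff / th[["k_diff"]]),
                 log(sts$params$k_ph / th[["k_ph"]]),
                 log(sts$params$k_hp / th[["k_hp"]]),
                 log(sts$params$k_hb / th[["k_hb"]]),
                 sts$params$xi - th[["xi"]])
    expect_lt(sqrt(sum(map$eta^2)), sqrt(sum(eta_sts^2)) + 1e-8)
  }
})

test_that("population fit collapses correctly on identical noise-free data", {
  truth <- rate_parameters(2.2e-3, 3.9e-3, 2.8e-5, 3.8e-5, 1.5)
  pat <- noise_free_patient(truth)
  pats <- lapply(1:3, function(i) {
    p <- pat; p$patient_id <- paste0("c", i); p
  })
  co <- cohort(pats)
  fit <- suppressWarnings(fit_population(co, tol = 1e-6, obj_tol = 1e-9,
                                         max_iter = 300))
  om <- vapply(fit$population$distributions, `[[`, numeric(1), "omega")
  expect_true(all(om < 1e-6))
  th <- vapply(fit$population$distributions, `[[`, numeric(1), "theta")
  expect_equal(th[["k_ph"]], truth$k_ph, tolerance = 0.02)
  expect_equal(th[["k_diff"]], truth$k_diff, tolerance = 0.02)
  expect_equal(th[["xi"]], truth$xi, tolerance = 0.02)
  expect_true(all(diff(fit$objective) <= 1e-6))
})

test_that("population fitting improves the data fit on noisy cohorts", {
  gen <- small_cohort(n = 6, seed = 67)
  fit <- fit_population(gen$cohort, tol = 1e-4)
  expect_true(fit$converged)
  # the residual fit improves across the alternation; the joint objective
  # may rise only through the controlled omega re-estimation (ln omega)
  expect_lt(fit$chi2[length(fit$chi2)], fit$chi2[1])
  expect_true(all(diff(fit$objective) < 1))
  # estimated effects are centred and no wider than the generator's
  emat <- do.call(rbind, lapply(fit$estimates, `[[`, "eta"))
  expect_lt(abs(mean(emat[, "k_ph"])), 0.2)
  expect_lte(stats::sd(emat[, "k_ph"]), 0.45)
})

test_that("population moments are recovered from homogeneous cohorts", {
  # three 50-patient single-stage cohorts drawn from known (theta, omega);
  # the mean estimate must land within 10% (theta) and 30% (omega)
  res <- lapply(2718 + 0:2, function(seed) {
    spec <- cohort_spec(n_patients = 50,
                        stage_counts = c(F0 = 50, F1 = 0, F2 = 0, F3 = 0,
                                         F4 = 0),
                        seed = seed)
    gen <- generate_cohort(spec)
    fit <- fit_population(gen$cohort)
    c(theta = fit$population$distributions$k_ph$theta,
      omega = fit$population$distributions$k_ph$omega)
  })
  res <- do.call(rbind, res)
  expect_lt(abs(mean(res[, "theta"]) / 4.7e-3 - 1), 0.10)
  expect_lt(abs(mean(res[, "omega"]) / 0.3 - 1), 0.30)
})

test_that("leave-one-out with infinite cutoff reproduces the full fit", {
  gen <- small_cohort(n = 3, seed = 71)
  full <- fit_population(gen$cohort)
  loo <- leave_one_out_truncated_fit(gen$cohort, "vp002", cutoff_s = Inf)
  expect_equal(loo$eta, full$estimates[[2]]$eta, tolerance = 1e-12)
  expect_equal(unlist(loo$params), unlist(full$estimates[[2]]$params),
               tolerance = 1e-12)
})

test_that("leave-one-out enforces the data-sufficiency contract", {
  gen <- small_cohort(n = 3, seed = 73)
  short <- gen$cohort$patients[[1]]
  keep <- short$times <= 600
  short <- patient_record("short", short$times[keep],
                          short$liver_dr1[keep], short$liver_sem[keep],
                          short$spleen_dr1[keep], short$spleen_sem[keep])
  co <- cohort(c(gen$cohort$patients[2:3], list(short)))
  expect_error(leave_one_out_truncated_fit(co, "short", cutoff_s = 600),
               "insufficient")
  expect_error(leave_one_out_truncated_fit(co, "nobody"), "not in cohort")
})
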