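test_that("estimation/validation split follows the 10-minute protocol", {
  pat <- patient_record("p", c(180, 600, 1200, 1800),
                        c(1, 2, 2.5, 2.7), rep(0.1, 4),
                        c(0.8, 0.5, 0.4, 0.35), rep(0.1, 4))
  sp <- split_at_cutoff(pat)
  expect_equal(sp$estimation$times, c(180, 600))
  expect_equal(sp$validation$times, c(1200, 1800))
  expect_true(sp$sufficient)
  # union is the usable set, intersection empty
  expect_setequal(c(sp$estimation$times, sp$validation$times),
                  pat$times[pat$times >= 180])

  short <- patient_record("q", c(180, 600), c(1, 2), c(0.1, 0.1),
                          c(0.8, 0.5), c(0.1, 0.1))
  sp2 <- split_at_cutoff(short)
  expect_false(sp2$sufficient)
  expect_null(sp2$validation)

  late <- patient_record("r", c(1200, 1800), c(2.5, 2.7), c(0.1, 0.1),
                         c(0.4, 0.35), c(0.1, 0.1))
  expect_error(split_at_cutoff(late), "no estimation data")
})

test_that("Lin's concordance matches hand-computed toy values", {
  expect_equal(lins_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 4, 6)), 8 / 22, tolerance = 1e-12)
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_error(lins_ccc(1, 1), "length")
  expect_error(lins_ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("Lin's concordance never exceeds Pearson in absolute value", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20, sd = 0.7) + runif(1, -1, 1)
    expect_lte(abs(lins_ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
    expect_gte(lins_ccc(x, y), -1 - 1e-12)
    expect_lte(lins_ccc(x, y), 1 + 1e-12)
  }
})

test_that("predicted sample concentrations track the fitted model", {
  k <- physiological_constants()
  d <- dose_protocol(body_weight = 70)
  fit <- list(params = prior_expectations())
  out <- predict_sample_concentrations(fit, 1800, k, d)
  traj <- simulate_gadoxetate(fit$params, k, d, c(0, 1800))
  expect_equal(out[["blood_mM"]],
               blood_concentration(traj, 1800, 0.45), tolerance = 1e-12)
  expect_equal(out[["liver_mM"]],
               liver_tissue_concentration(traj, k, 1800), tolerance = 1e-12)
  expect_error(predict_sample_concentrations(fit, -5, k, d), "after")

  # uptake monotonicity: more OATP1 activity, more gadoxetate in tissue
  kphs <- c(1e-3, 2e-3, 4e-3, 8e-3)
  liver <- vapply(kphs, function(kph) {
    f <- list(params = rate_parameters(1.7e-3, kph, 2.8e-5, 3.8e-5, 1.6))
    predict_sample_concentrations(f, 1800, k, d)[["liver_mM"]]
  }, numeric(1))
  expect_true(all(diff(liver) > 0))
})

test_that("closed-loop concentration predictions agree with generation", {
  gen <- small_cohort(n = 10, noise_sd = 0.05, seed = 83)
  k <- physiological_constants()
  pred <- meas <- numeric(10)
  for (i in 1:10) {
    pat <- gen$cohort$patients[[i]]
    tr <- gen$truth[i, ]
    d <- dose_protocol(body_weight = pat$body_weight)
    true_params <- rate_parameters(tr$k_diff, tr$k_ph, tr$k_hp, tr$k_hb,
                                   tr$xi)
    traj <- simulate_gadoxetate(true_params, k, d, c(0, 1800))
    meas[i] <- liver_tissue_concentration(traj, k, 1800)
    fit <- fit_sts(pat)
    pred[i] <- predict_sample_concentrations(fit, 1800, k, d)[["liver_mM"]]
  }
  expect_gt(lins_ccc(pred, meas), 0.9)
})

test_that("fibrosis group analysis recovers a stage-dependent uptake trend", {
  spec <- cohort_spec(n_patients = 40,
                      stage_counts = c(F0 = 10, F1 = 8, F2 = 8, F3 = 8,
                                       F4 = 6),
                      seed = 89)
  gen <- generate_cohort(spec)
  est <- gen$truth  # generating parameters stand in for fitted ones here
  res <- fibrosis_group_analysis(est, parameters = "k_ph")
  gs <- res$k_ph$group_stats
  expect_equal(gs$stage, paste0("F", 0:4))
  expect_true(all(diff(gs$mean) < 0))  # monotone decline F0 -> F4
  expect_lt(res$k_ph$anova_p, 0.001)
  expect_true("F4-F0" %in% rownames(res$k_ph$tukey))
})

test_that("identical groups yield no significant contrasts", {
  est <- data.frame(fibrosis_stage = rep(c("F0", "F2", "F4"), each = 5),
                    k_ph = rep(4.7e-3, 15) * exp(rnorm(15, 0, 0.01)))
  set.seed(97)
  res <- fibrosis_group_analysis(est, parameters = "k_ph")
  expect_true(all(res$k_ph$tukey[, "p adj"] > 0.05))
  # widely separated groups are all significant
  est2 <- data.frame(fibrosis_stage = rep(c("F0", "F4"), each = 6),
                     k_ph = c(rnorm(6, 100, 1), rnorm(6, 0, 1)))
  res2 <- fibrosis_group_analysis(est2, parameters = "k_ph",
                                  log_scale = FALSE)
  expect_true(all(res2$k_ph$tukey[, "p adj"] < 0.001))
  mw <- mann_whitney_groups(est2$k_ph, est2$fibrosis_stage)
  expect_lt(mw$p.value, 0.01)
})

test_that("confusion matrix applies the uptake cutoff rule", {
  toy <- data.frame(k_ph = c(0.001, 0.003),
                    fibrosis_stage = c("F4", "F0"))
  cm <- advanced_fibrosis_confusion(toy)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(1, 1, 0, 0))

  high <- data.frame(k_ph = rep(0.004, 6),
                     fibrosis_stage = c("F0", "F1", "F2", "F3", "F4", "F0"))
  cm2 <- advanced_fibrosis_confusion(high)
  expect_equal(cm2$fp + cm2$tp, 0)
  expect_equal(cm2$tn + cm2$fp + cm2$fn + cm2$tp, 6)

  mixed <- data.frame(k_ph = c(0.001, 0.003, 0.002),
                      fibrosis_stage = c("F4", "F0", "unknown"))
  expect_warning(cm3 <- advanced_fibrosis_confusion(mixed), "unknown")
  expect_equal(cm3$n, 2)
})

test_that("paired method comparison uses a signed-rank test", {
  set.seed(101)
  x <- rnorm(20); y <- x + 0.5 + rnorm(20, sd = 0.1)
  res <- paired_method_test(x, y)
  expect_lt(res$p.value, 0.001)
  expect_match(res$method, "signed rank", ignore.case = TRUE)
})
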