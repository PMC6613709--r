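test_that("ode_rhs reproduces hand-computed fluxes", {
  k <- physiological_constants()
  d <- dose_protocol(body_weight = 70)
  p <- rate_parameters(k_diff = 1.7e-3, k_ph = 4.7e-3, k_hp = 28e-3,
                       k_hb = 38e-3, xi = 1.6)

  # zero state, zero input
  expect_equal(ode_rhs(c(0, 0, 0), -10, p, k, d), c(0, 0, 0))

  # 1 mM in plasma only, input off (t after the pulse): hand arithmetic
  rhs <- ode_rhs(c(0, 1, 0), 100, p, k, d)
  expect_equal(rhs[1], 4.7e-3 * 1 * 0.9, tolerance = 1e-12)        # uptake
  expect_equal(rhs[3], 1.7e-3 * (0.9 - 0), tolerance = 1e-12)      # to EES
  dCp <- ((-4.7e-3 * 0.9) * 1.43 * 0.68 - (118 / 1000 / 60) * 0.9 +
            1.7e-3 * (0 - 0.9) * 14.77) / 2.57
  expect_equal(rhs[2], dCp, tolerance = 1e-12)
  expect_equal(rhs[2], -1.108e-2, tolerance = 1e-3)

  expect_error(ode_rhs(c(0, NA, 0), 0, p, k, d), "finite")
})

test_that("rhs conserves mass when elimination pathways are closed", {
  k <- physiological_constants(CLr = 0)
  d <- dose_protocol(body_weight = 70)
  p <- rate_parameters(k_diff = 1.7e-3, k_ph = 4.7e-3, k_hp = 28e-3,
                       k_hb = 0, xi = 1.6)
  for (state in list(c(0.1, 0.5, 0.2), c(1, 0, 0), c(0.3, 0.3, 0.3))) {
    rhs <- ode_rhs(state, 1000, p, k, d)
    total_flux <- k$v_h * k$V_l * rhs[1] + k$V_p * rhs[2] + k$V_ees * rhs[3]
    expect_equal(total_flux, 0, tolerance = 1e-15)
  }
})

test_that("infusion pulse has the documented dose, duration and integral", {
  d <- dose_protocol(body_weight = 70)
  expect_equal(d$duration_s, 7)
  expect_equal(d$total_dose_mmol, 1.75)
  expect_equal(infusion_rate(-1, d), 0)
  expect_equal(infusion_rate(3, d), 0.25)
  expect_equal(infusion_rate(7, d), 0)  # pulse is [start, start + duration)
  tt <- seq(0, 60, by = 1e-3)
  integral <- sum(infusion_rate(tt[-length(tt)], d)) * 1e-3
  expect_equal(integral, d$total_dose_mmol, tolerance = 1e-9)
})

test_that("closed-form simulation matches the independent ODE integrator", {
  k <- physiological_constants()
  d <- dose_protocol(body_weight = 82)
  tt <- c(-30, 15, 45, 180, 600, 1800)
  for (p in random_params(10, seed = 21)) {
    exact <- simulate_gadoxetate(p, k, d, tt)
    ode <- simulate_gadoxetate(p, k, d, tt, method = "ode")
    expect_equal(as.matrix(exact[, -1]), as.matrix(ode[, -1]),
                 tolerance = 1e-6)
  }
})

test_that("zero dose-free periods and positivity invariants hold", {
  k <- physiological_constants()
  d <- dose_protocol(body_weight = 70)
  for (p in random_params(5, seed = 31)) {
    tr <- simulate_gadoxetate(p, k, d, c(-120, -1, 2, 30, 300, 1800))
    expect_true(all(tr[tr$time <= 0, -1] == 0))
    expect_true(all(as.matrix(tr[, -1]) >= -1e-12))
  }
})

test_that("injected dose is conserved without elimination pathways", {
  k <- physiological_constants(CLr = 0)
  d <- dose_protocol(body_weight = 64)
  for (p in random_params(5, seed = 41)) {
    p0 <- rate_parameters(p$k_diff, p$k_ph, p$k_hp, 0, p$xi)
    tr <- simulate_gadoxetate(p0, k, d, c(60, 1800))
    total <- k$v_h * k$V_l * tr$C_hep + k$V_p * tr$C_p + k$V_ees * tr$C_ees
    expect_equal(total[2], d$total_dose_mmol, tolerance = 1e-6)
  }
})

test_that("signal model reproduces hand-computed delta-R1 and is linear", {
  k <- physiological_constants()
  traj <- structure(
    data.frame(time = 0, C_hep = 1, C_p = 0.2, C_ees = 0.1),
    class = c("compartment_trajectory", "data.frame"))
  p1 <- rate_parameters(1e-3, 1e-3, 1e-3, 1e-3, xi = 1)
  sig <- predict_delta_r1(traj, p1, k)
  expect_equal(sig$liver, 1 * 0.68 * 10.7 + 0.2 * 0.12 * 7.3 +
                 0.1 * 0.20 * 6.9, tolerance = 1e-12)
  expect_equal(sig$liver, 7.5892, tolerance = 1e-12)
  p2 <- rate_parameters(1e-3, 1e-3, 1e-3, 1e-3, xi = 2)
  sig2 <- predict_delta_r1(traj, p2, k)
  expect_equal(sig2$spleen, 2 * (0.2 * 0.35 * 7.3 + 0.1 * 0.20 * 6.9),
               tolerance = 1e-12)
  expect_equal(sig2$spleen, 1.298, tolerance = 1e-12)
  # homogeneity in xi and additivity in concentrations
  expect_equal(sig2$liver, 2 * sig$liver, tolerance = 1e-12)
  traj2 <- traj; traj2[, -1] <- 2 * traj2[, -1]
  expect_equal(predict_delta_r1(traj2, p1, k)$liver, 2 * sig$liver,
               tolerance = 1e-12)
  # zero concentrations give zero signal
  traj0 <- traj; traj0[, -1] <- 0
  expect_equal(unlist(predict_delta_r1(traj0, p1, k)[, -1]),
               c(liver = 0, spleen = 0))
})

test_that("tissue and blood concentrations follow the volume fractions", {
  k <- physiological_constants()
  traj <- structure(
    data.frame(time = c(0, 100), C_hep = c(1, 2), C_p = c(0.2, 0.4),
               C_ees = c(0.1, 0.2)),
    class = c("compartment_trajectory", "data.frame"))
  expect_equal(liver_tissue_concentration(traj, k, 0),
               0.68 + 0.024 + 0.02, tolerance = 1e-12)
  expect_equal(liver_tissue_concentration(traj, k, 100),
               2 * 0.724, tolerance = 1e-12)  # linearity
  expect_error(liver_tissue_concentration(traj, k, 200), "outside")

  expect_equal(blood_concentration(traj, 0, hematocrit = 0), 0.2)
  traj$C_p <- c(0.5, 0.5)
  expect_equal(blood_concentration(traj, 0, hematocrit = 0.45), 0.275)
  hcts <- c(0, 0.2, 0.4, 0.6)
  vals <- vapply(hcts, function(h) blood_concentration(traj, 0, h),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(blood_concentration(traj, 0, hematocrit = 1), "hematocrit")
})

test_that("constants and dose validation rejects unphysical values", {
  expect_error(physiological_constants(V_p = -1), "positive")
  expect_error(physiological_constants(Alb = 1.2), "fraction")
  expect_error(rate_parameters(-1e-3, 1e-3, 1e-3, 1e-3, 1), ">= 0")
  expect_error(rate_parameters(1e-3, 1e-3, 1e-3, 1e-3, 0), "positive")
  expect_error(dose_protocol(body_weight = 0), "positive")
})

test_that("model config round-trips through a flat key-value file", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("V_l: 1.5", "CLr: 0.002", "body_weight: 55"), path)
  cfg <- read_model_config(path)
  expect_equal(cfg$constants$V_l, 1.5)
  expect_equal(cfg$constants$CLr, 0.002)
  expect_equal(cfg$constants$V_p, 2.57)  # untouched default
  expect_equal(cfg$dose$body_weight, 55)
  writeLines("bogus_key: 1", path)
  expect_error(read_model_config(path), "unknown config keys")
})
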