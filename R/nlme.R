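#' Healthy-cohort prior expectations for the five model parameters
#'
#' Healthy-volunteer literature values: xi = 1.6, k_diff = 1.7e-3 s^-1, k_ph = 4.7e-3 s^-1,
#' k_hp = 2.8e-5 s^-1, k_hb = 3.8e-5 s^-1. The hepatocyte efflux rates are
#' orders of magnitude below the uptake rate: gadoxetate accumulates in the
#' liver over the 30-minute examination (the hepatobiliary phase), which is
#' what makes the liver signal rise while the spleen signal, tracking
#' plasma, washes out.
#'
#' @return [rate_parameters()]
#' @export
prior_expectations <- function() {
  rate_parameters(k_diff = 1.7e-3, k_ph = 4.7e-3, k_hp = 2.8e-5,
                  k_hb = 3.8e-5, xi = 1.6)
}

#' Distribution of one population parameter
#'
#' @param name parameter name
#' @param family `"normal"` (individual = theta + eta) or `"lognormal"`
#'   (individual = theta * exp(eta))
#' @param theta typical value (parameter units; > 0 for lognormal)
#' @param omega random-effect SD: parameter units for normal, dimensionless
#'   log-SD for lognormal; >= 0
#' @return object of class `parameter_distribution`
#' @export
parameter_distribution <- function(name, family = c("lognormal", "normal"),
                                   theta, omega) {
  family <- match.arg(family)
  if (family == "lognormal" && theta <= 0)
    stop("lognormal theta must be positive for '", name, "'", call. = FALSE)
  if (!is.finite(omega) || omega < 0)
    stop("omega must be finite and >= 0 for '", name, "'", call. = FALSE)
  structure(list(name = name, family = family, theta = theta, omega = omega),
            class = "parameter_distribution")
}

PARAM_NAMES <- c("k_diff", "k_ph", "k_hp", "k_hb", "xi")

#' Population model: one distribution per subject parameter
#'
#' The signal scale xi follows a normal distribution; the four rate
#' constants are lognormal. `population_model()` validates that exactly
#' these five parameters are present with those families.
#'
#' @param distributions named list of [parameter_distribution()], one per
#'   parameter in `k_diff, k_ph, k_hp, k_hb, xi`
#' @return object of class `population_model`
#' @export
population_model <- function(distributions) {
  nms <- vapply(distributions, `[[`, character(1), "name")
  names(distributions) <- nms
  if (!setequal(nms, PARAM_NAMES))
    stop("need exactly the five parameters: ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  fams <- vapply(distributions, `[[`, character(1), "family")
  if (fams[["xi"]] != "normal")
    stop("xi must be normal", call. = FALSE)
  if (any(fams[setdiff(PARAM_NAMES, "xi")] != "lognormal"))
    stop("rate parameters must be lognormal", call. = FALSE)
  structure(list(distributions = distributions[PARAM_NAMES]),
            class = "population_model")
}

#' Default a-priori population model
#'
#' Typical values from [prior_expectations()]; the a-priori random-effect
#' SDs (chosen wide enough not to constrain optimization) are xi = 1,
#' k_diff = 0.1, k_ph = 0.1, k_hp = 0.01, k_hb = 0.01, read as log-scale
#' SDs for the lognormal rates and a natural-scale SD for xi.
#'
#' @param omega optional named numeric overriding any of the SDs
#' @return [population_model()]
#' @export
prior_population <- function(omega = NULL) {
  th <- prior_expectations()
  om <- c(k_diff = 0.1, k_ph = 0.1, k_hp = 0.01, k_hb = 0.01, xi = 1)
  if (!is.null(omega)) om[names(omega)] <- omega
  population_model(lapply(PARAM_NAMES, function(nm)
    parameter_distribution(nm,
                           family = if (nm == "xi") "normal" else "lognormal",
                           theta = th[[nm]], omega = om[[nm]])))
}

#' Read a population model from a priors JSON file
#'
#' Expected layout: an array of objects with fields `name`, `family`,
#' `theta`, `omega`.
#'
#' @param path JSON file path
#' @return [population_model()]
#' @export
read_population <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_model(lapply(seq_len(nrow(j)), function(i)
    parameter_distribution(j$name[i], j$family[i], j$theta[i], j$omega[i])))
}

#' Individual parameter value from typical value and random effect
#'
#' Normal family: theta + eta. Lognormal family: theta * exp(eta).
#'
#' @param dist [parameter_distribution()]
#' @param eta random-effect value
#' @return individual parameter value
#' @export
individual_parameter <- function(dist, eta) {
  switch(dist$family,
         normal = dist$theta + eta,
         lognormal = dist$theta * exp(eta))
}

# eta (named length-5) -> rate_parameters under a population model;
# xi is clamped to stay positive (normal family can cross zero).
eta_to_params <- function(pop, eta) {
  v <- vapply(PARAM_NAMES, function(nm)
    individual_parameter(pop$distributions[[nm]], eta[[nm]]), numeric(1))
  v[["xi"]] <- max(v[["xi"]], 1e-6)
  rate_parameters(k_diff = v[["k_diff"]], k_ph = v[["k_ph"]],
                  k_hp = v[["k_hp"]], k_hb = v[["k_hb"]], xi = v[["xi"]])
}

# Prior penalty sum_p eta_p^2 / (2 omega_p^2) + sum_p log(omega_p), with the
# convention that omega = 0 forces eta = 0 (finite, zero contribution) and
# yields +Inf for nonzero eta.
eta_penalty <- function(eta, omegas, include_log_omega = TRUE) {
  tot <- 0
  for (nm in PARAM_NAMES) {
    om <- omegas[[nm]]
    e <- eta[[nm]]
    if (om == 0) {
      if (e != 0) return(Inf)
    } else {
      tot <- tot + e^2 / (2 * om^2) + if (include_log_omega) log(om) else 0
    }
  }
  tot
}

pop_omegas <- function(pop) vapply(pop$distributions, `[[`, numeric(1),
                                   "omega")
pop_thetas <- function(pop) vapply(pop$distributions, `[[`, numeric(1),
                                   "theta")

#' Joint negative log-posterior of the mixed-effects model
#'
#' For each patient j: half the chi-square residual cost of the individual
#' parameters implied by eta_j, plus the Gaussian random-effect penalty
#' sum_p eta^2/(2 omega^2) + log(omega). Residual sigmas come from
#' [effective_sigma()]. A zero omega with a nonzero eta yields `+Inf`.
#'
#' @param eta_all list (one per patient) of named length-5 eta vectors
#' @param pop [population_model()]
#' @param cohort [cohort()]
#' @param constants [physiological_constants()]
#' @param doses optional list of [dose_protocol()] per patient; derived from
#'   body weights when `NULL`
#' @param config [uncertainty_config()]
#' @param t_min,t_max observation inclusion window (s)
#' @return scalar objective (up to an additive constant)
#' @export
neg_log_joint <- function(eta_all, pop, cohort,
                          constants = physiological_constants(),
                          doses = NULL, config = uncertainty_config(),
                          t_min = 180, t_max = Inf) {
  omegas <- pop_omegas(pop)
  tot <- 0
  for (i in seq_along(cohort$patients)) {
    pat <- cohort$patients[[i]]
    dose <- if (is.null(doses)) dose_protocol(body_weight = pat$body_weight)
    else doses[[i]]
    pen <- eta_penalty(eta_all[[i]], omegas)
    if (!is.finite(pen)) return(Inf)
    params <- eta_to_params(pop, eta_all[[i]])
    tot <- tot + 0.5 * chi2_cost(params, pat, constants, dose, config,
                                 t_min, t_max) + pen
  }
  tot
}

zero_eta <- function() stats::setNames(numeric(5), PARAM_NAMES)

#' MAP estimate of one patient's random effects
#'
#' Minimizes the single-patient term of [neg_log_joint()] over eta given a
#' population model: half chi-square plus the quadratic random-effect
#' penalty. Parameters whose omega is zero are held at eta = 0.
#'
#' @inheritParams chi2_cost
#' @param pop [population_model()]
#' @param eta0 warm-start eta (default all zero)
#' @param maxit Nelder-Mead iteration cap
#' @param alpha significance level for the goodness-of-fit test
#' @param polish run a BFGS refinement after the simplex search
#' @param posterior_var also return the diagonal Laplace posterior
#'   variances of the random effects (used by the population ω update)
#' @return object of class `individual_estimate`: `patient_id`, `eta`,
#'   `params`, `map_objective`, `gof`, `method = "NLME"`
#' @export
fit_individual_map <- function(patient, pop,
                               constants = physiological_constants(),
                               dose = dose_protocol(
                                 body_weight = patient$body_weight),
                               config = uncertainty_config(),
                               t_min = 180, t_max = Inf,
                               eta0 = NULL, maxit = 300, alpha = 0.05,
                               polish = TRUE, posterior_var = FALSE) {
  obs <- usable_observations(patient, config, t_min, t_max)
  if (obs$n == 0)
    stop("patient '", patient$patient_id, "': no usable observations",
         call. = FALSE)
  omegas <- pop_omegas(pop)
  free <- PARAM_NAMES[omegas > 0]
  if (is.null(eta0)) eta0 <- zero_eta()
  thetas <- pop_thetas(pop)
  fams <- vapply(pop$distributions, `[[`, character(1), "family")
  inv_var <- ifelse(omegas > 0, 1 / (2 * omegas^2), 0)
  fn <- function(v) {
    if (any(!is.finite(v)) || any(abs(v) > 50)) return(1e12)
    eta <- zero_eta()
    eta[free] <- v
    pv <- ifelse(fams == "normal", thetas + eta, thetas * exp(eta))
    if (any(pv[1:4] < 0)) return(1e12)
    pv[["xi"]] <- max(pv[["xi"]], 1e-6)
    params <- list(k_diff = pv[["k_diff"]], k_ph = pv[["k_ph"]],
                   k_hp = pv[["k_hp"]], k_hb = pv[["k_hb"]],
                   xi = pv[["xi"]])
    val <- tryCatch(
      0.5 * obs_cost(params, obs, constants, dose) + sum(inv_var * eta^2),
      error = function(e) 1e12)
    if (!is.finite(val)) 1e12 else val
  }
  if (length(free) == 0) {
    best <- list(par = numeric(0), value = fn(numeric(0)))
  } else {
    nm <- stats::optim(eta0[free], fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-7))
    best <- nm
    if (polish) {
      pol <- tryCatch(
        stats::optim(nm$par, fn, method = "BFGS",
                     control = list(maxit = 50, reltol = 1e-12)),
        error = function(e) nm)
      if (is.finite(pol$value) && pol$value < best$value) best <- pol
    }
  }
  eta <- zero_eta()
  eta[free] <- best$par
  params <- eta_to_params(pop, eta)
  chi2 <- chi2_cost(params, patient, constants, dose, config, t_min, t_max)
  pvar <- NULL
  if (posterior_var) {
    # Laplace posterior covariance of the free effects via Gauss-Newton:
    # V = (J' J + diag(1/omega^2))^-1 with J the sigma-weighted Jacobian
    # of the model predictions wrt eta. The full matrix matters: the
    # signal scale and the uptake rate are strongly coupled in the liver
    # signal, and a diagonal approximation misattributes their variance.
    h <- 1e-3
    wpred <- function(e) {
      pv <- ifelse(fams == "normal", thetas + e, thetas * exp(e))
      pv[["xi"]] <- max(pv[["xi"]], 1e-6)
      pr <- sim_dr1(list(k_diff = pv[["k_diff"]], k_ph = pv[["k_ph"]],
                         k_hp = pv[["k_hp"]], k_hb = pv[["k_hb"]],
                         xi = pv[["xi"]]), constants, dose, obs$times)
      c(pr[1, ] / obs$sigma_liver, pr[2, ] / obs$sigma_spleen)
    }
    J <- vapply(free, function(nm) {
      ep <- em <- eta
      ep[[nm]] <- eta[[nm]] + h
      em[[nm]] <- eta[[nm]] - h
      (wpred(ep) - wpred(em)) / (2 * h)
    }, numeric(2 * length(obs$times)))
    fisher <- crossprod(J)
    prior_prec <- diag(1 / omegas[free]^2, nrow = length(free))
    V <- tryCatch(solve(fisher + prior_prec), error = function(e) NULL)
    pvar <- zero_eta()
    pvar[free] <- if (is.null(V)) omegas[free]^2 else pmax(diag(V), 0)
  }
  structure(list(patient_id = patient$patient_id,
                 fibrosis_stage = patient$fibrosis_stage,
                 eta = eta, params = params,
                 map_objective = best$value,
                 gof = gof_test(chi2, obs$n, alpha),
                 posterior_var = pvar,
                 method = "NLME"),
            class = "individual_estimate")
}

#' Fit the population model to a cohort (alternating MAP/EM-style scheme)
#'
#' Alternates an E-like step — per-patient MAP random effects given the
#' current (theta, omega) — with an M-like step that recentres theta (mean
#' of individual values for the normal family, geometric mean for the
#' lognormal families) and re-estimates each omega^2 as the mean of the
#' squared centred effects plus their Laplace posterior variances, the
#' standard EM update for a Gaussian random effect (moments of the MAP
#' point estimates alone are biased towards zero and collapse the
#' population variance). When the between-patient variance of an effect is
#' numerically zero the effect is degenerate and omega is set to 0. The
#' E-step penalty uses `max(omega, omega_damp)` as an additional guard
#' against premature collapse. The joint objective is logged per iteration;
#' it decreases throughout except for the controlled omega re-estimation,
#' which targets the marginal rather than the joint criterion.
#'
#' @param cohort [cohort()]
#' @param init initial [population_model()] (defaults to the a-priori model)
#' @param constants,doses,config,t_min,t_max as in [neg_log_joint()]
#' @param tol convergence tolerance: max relative change in (theta, damped
#'   omega) between outer iterations
#' @param obj_tol secondary stop: the scheme also counts as converged when
#'   the objective decreases by less than this (absolute, chi-square scale)
#'   over an outer iteration — the weakly identified efflux
#'   rates can drift along near-flat directions long after the fit has
#'   stopped improving. Default `2e-4 * n_patients` (average per-patient
#'   improvement below 2e-4)
#' @param max_iter outer iteration cap
#' @param init_etas optional named list (by patient id) of length-5 eta
#'   vectors used to warm-start the first E-step
#' @param omega_damp lower bound on the omega used inside the E-step penalty
#' @param maxit_map per-patient Nelder-Mead cap
#' @param alpha goodness-of-fit significance level
#' @return list with `population`, `estimates` (per-patient
#'   `individual_estimate`), `objective` (per-iteration trace of the damped
#'   joint objective), `chi2` (per-iteration total chi-square of the MAP
#'   fits), `converged`, `iterations`
#' @export
fit_population <- function(cohort, init = prior_population(),
                           constants = physiological_constants(),
                           doses = NULL, config = uncertainty_config(),
                           t_min = 180, t_max = Inf,
                           tol = 1e-4, obj_tol = NULL, max_iter = 200,
                           omega_damp = 0.05, maxit_map = 300,
                           alpha = 0.05, init_etas = NULL) {
  if (length(cohort$patients) < 2)
    stop("population fitting needs at least 2 patients", call. = FALSE)
  pats <- cohort$patients
  n <- length(pats)
  if (is.null(obj_tol)) obj_tol <- 2e-4 * n
  if (is.null(doses))
    doses <- lapply(pats, function(p) dose_protocol(body_weight =
                                                      p$body_weight))
  thetas <- pop_thetas(init)
  omegas_raw <- pop_omegas(init)
  fams <- vapply(init$distributions, `[[`, character(1), "family")
  damp <- function(om) pmax(om, omega_damp)
  make_pop <- function(th, om) population_model(lapply(PARAM_NAMES,
    function(nm) parameter_distribution(nm, fams[[nm]], th[[nm]],
                                        om[[nm]])))
  etas <- replicate(n, zero_eta(), simplify = FALSE)
  if (!is.null(init_etas)) {
    hit <- match(names(pats), names(init_etas))
    for (i in seq_len(n))
      if (!is.na(hit[i])) etas[[i]] <- init_etas[[hit[i]]]
  }
  trace_obj <- numeric(0)
  trace_chi2 <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    pop_e <- make_pop(thetas, damp(omegas_raw))
    # E-like step: per-patient MAP effects (warm-started)
    ests <- lapply(seq_len(n), function(i)
      fit_individual_map(pats[[i]], pop_e, constants, doses[[i]], config,
                         t_min, t_max, eta0 = etas[[i]], maxit = maxit_map,
                         alpha = alpha, polish = FALSE,
                         posterior_var = TRUE))
    etas <- lapply(ests, `[[`, "eta")
    trace_chi2 <- c(trace_chi2,
                    sum(vapply(ests, function(e) e$gof$chi2, numeric(1))))
    emat <- do.call(rbind, etas)
    vmat <- do.call(rbind, lapply(ests, `[[`, "posterior_var"))
    # M-like step: recentre theta; omega from the MAP effects plus their
    # Laplace posterior variances (plain moments of the point estimates
    # systematically underestimate omega)
    shift <- colMeans(emat)
    new_thetas <- thetas
    for (nm in PARAM_NAMES) {
      if (fams[[nm]] == "normal") new_thetas[[nm]] <- thetas[[nm]] + shift[[nm]]
      else new_thetas[[nm]] <- thetas[[nm]] * exp(shift[[nm]])
    }
    emat <- sweep(emat, 2, shift)
    etas <- lapply(seq_len(n), function(i)
      stats::setNames(emat[i, ], PARAM_NAMES))
    v_between <- colMeans(emat^2)
    new_omegas <- ifelse(v_between < 1e-12, 0,
                         sqrt(v_between + colMeans(vmat)))
    obj <- neg_log_joint(etas, make_pop(new_thetas, damp(new_omegas)),
                         cohort, constants, doses, config, t_min, t_max)
    trace_obj <- c(trace_obj, obj)
    rel <- max(abs(new_thetas - thetas) / pmax(abs(thetas), 1e-12),
               abs(damp(new_omegas) - damp(omegas_raw)) /
                 pmax(damp(omegas_raw), 1e-12))
    n_tr <- length(trace_obj)
    obj_steps <- if (n_tr >= 2) abs(diff(trace_obj[(n_tr - 1):n_tr]))
    else Inf
    thetas <- new_thetas
    omegas_raw <- new_omegas
    if (rel < tol || all(obj_steps < obj_tol)) { converged <- TRUE; break }
  }
  pop_final <- make_pop(thetas, omegas_raw)
  pop_e <- make_pop(thetas, damp(omegas_raw))
  ests <- lapply(seq_len(n), function(i)
    fit_individual_map(pats[[i]], pop_e, constants, doses[[i]], config,
                       t_min, t_max, eta0 = etas[[i]], maxit = maxit_map,
                       alpha = alpha))
  if (!converged)
    warning("fit_population reached max_iter = ", max_iter,
            " before tolerance ", tol, call. = FALSE)
  list(population = pop_final, estimates = ests, objective = trace_obj,
       chi2 = trace_chi2, converged = converged, iterations = it)
}

#' Leave-one-out NLME estimate from truncated data
#'
#' Re-fits the population with the target patient's series truncated at
#' `cutoff_s` while all other patients contribute their full series, then
#' returns the target's MAP estimate obtained from its truncated
#' observations only. This mirrors the clinical situation where population
#' distributions are known from complete studies and a new patient is
#' examined with a short protocol.
#'
#' @inheritParams fit_population
#' @param target_patient_id id of the patient to truncate
#' @param cutoff_s truncation time (s), inclusive; default 600 (10 min)
#' @return the target's `individual_estimate`, with the fitted population
#'   model attached as attribute `"population"`
#' @export
leave_one_out_truncated_fit <- function(cohort, target_patient_id,
                                        cutoff_s = 600,
                                        init = prior_population(),
                                        constants = physiological_constants(),
                                        doses = NULL,
                                        config = uncertainty_config(),
                                        t_min = 180, tol = 1e-4,
                                        obj_tol = NULL, max_iter = 200,
                                        omega_damp = 0.05, maxit_map = 300,
                                        alpha = 0.05, init_etas = NULL) {
  idx <- match(target_patient_id, names(cohort$patients))
  if (is.na(idx))
    stop("patient '", target_patient_id, "' not in cohort", call. = FALSE)
  target <- cohort$patients[[idx]]
  n_est <- sum(target$times >= t_min & target$times <= cutoff_s)
  n_val <- sum(target$times > cutoff_s)
  if (n_est == 0)
    stop("patient '", target_patient_id, "': no estimation data in [",
         t_min, ", ", cutoff_s, "] s", call. = FALSE)
  if (is.finite(cutoff_s) && n_val == 0)
    stop("patient '", target_patient_id,
         "': insufficient data (no observations after ", cutoff_s, " s)",
         call. = FALSE)
  keep <- target$times <= cutoff_s
  truncated <- patient_record(target$patient_id, target$times[keep],
                              target$liver_dr1[keep], target$liver_sem[keep],
                              target$spleen_dr1[keep],
                              target$spleen_sem[keep],
                              body_weight = target$body_weight,
                              fibrosis_stage = target$fibrosis_stage)
  pats <- cohort$patients
  pats[[idx]] <- truncated
  mixed <- cohort(unname(pats), provenance = cohort$provenance)
  fit <- fit_population(mixed, init = init, constants = constants,
                        doses = doses, config = config, t_min = t_min,
                        tol = tol, obj_tol = obj_tol, max_iter = max_iter,
                        omega_damp = omega_damp, maxit_map = maxit_map,
                        alpha = alpha, init_etas = init_etas)
  est <- fit$estimates[[idx]]
  attr(est, "population") <- fit$population
  est
}
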