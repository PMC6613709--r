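#' Physiological constants of the whole-body gadoxetate model
#'
#' Fixed anatomical volumes, volume fractions, relaxivities and renal
#' clearance used by the compartment and signal models. Defaults are the
#' literature values for an average adult. Internal units are seconds,
#' litres, mmol, mM and s^-1 throughout; renal clearance is given in L/s
#' (118 mL/min = 1.9667e-3 L/s).
#'
#' @param V_l liver volume (L)
#' @param V_p blood plasma volume (L)
#' @param V_ees extracellular extravascular space volume (L)
#' @param Alb fraction of gadoxetate not bound to serum albumin
#' @param v_h hepatocyte volume fraction of the liver
#' @param CLr renal clearance (L/s)
#' @param v_p_l,v_ees_l plasma and EES volume fractions in the liver
#' @param v_p_s,v_ees_s plasma and EES volume fractions in the spleen
#' @param r1_hep,r1_p,r1_ees tissue-specific relaxivities (mM^-1 s^-1) in
#'   hepatocytes, plasma and EES
#'
#' @return An object of class `physiological_constants` (a validated list).
#' @export
physiological_constants <- function(V_l = 1.43, V_p = 2.57, V_ees = 14.77,
                                    Alb = 0.9, v_h = 0.68,
                                    CLr = 118 / 1000 / 60,
                                    v_p_l = 0.12, v_ees_l = 0.20,
                                    v_p_s = 0.35, v_ees_s = 0.20,
                                    r1_hep = 10.7, r1_p = 7.3, r1_ees = 6.9) {
  k <- list(V_l = V_l, V_p = V_p, V_ees = V_ees, Alb = Alb, v_h = v_h,
            CLr = CLr, v_p_l = v_p_l, v_ees_l = v_ees_l,
            v_p_s = v_p_s, v_ees_s = v_ees_s,
            r1_hep = r1_hep, r1_p = r1_p, r1_ees = r1_ees)
  for (nm in c("V_l", "V_p", "V_ees"))
    if (!is.finite(k[[nm]]) || k[[nm]] <= 0)
      stop("volume '", nm, "' must be positive", call. = FALSE)
  for (nm in c("Alb", "v_h", "v_p_l", "v_ees_l", "v_p_s", "v_ees_s"))
    if (!is.finite(k[[nm]]) || k[[nm]] <= 0 || k[[nm]] > 1)
      stop("fraction '", nm, "' must lie in (0, 1]", call. = FALSE)
  for (nm in c("r1_hep", "r1_p", "r1_ees"))
    if (!is.finite(k[[nm]]) || k[[nm]] <= 0)
      stop("relaxivity '", nm, "' must be positive", call. = FALSE)
  if (!is.finite(k$CLr) || k$CLr < 0)
    stop("renal clearance 'CLr' must be non-negative", call. = FALSE)
  structure(k, class = "physiological_constants")
}

#' Subject-level kinetic and signal parameters
#'
#' The five parameters estimated per patient: four first-order rate
#' constants and the arbitrary MRI signal scale.
#'
#' @param k_diff plasma <-> EES exchange rate (s^-1)
#' @param k_ph hepatocyte uptake rate, OATP1-mediated (s^-1)
#' @param k_hp hepatocyte -> plasma back-flux, MRP3-mediated (s^-1)
#' @param k_hb hepatocyte -> bile excretion, MRP2-mediated (s^-1)
#' @param xi dimensionless signal scaling
#'
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(k_diff, k_ph, k_hp, k_hb, xi) {
  p <- list(k_diff = k_diff, k_ph = k_ph, k_hp = k_hp, k_hb = k_hb, xi = xi)
  for (nm in c("k_diff", "k_ph", "k_hp", "k_hb"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("rate '", nm, "' must be finite and >= 0", call. = FALSE)
  if (!is.finite(xi) || xi <= 0)
    stop("signal scale 'xi' must be positive", call. = FALSE)
  structure(p, class = "rate_parameters")
}

#' Gadoxetate dosing protocol
#'
#' Weight-based bolus: `dose_volume_per_kg` mL/kg of a
#' `formulation_concentration` mmol/mL formulation, injected at
#' `injection_rate` mL/s by power injector. The input to the plasma
#' compartment is modelled as a rectangular pulse; the total dose (mmol)
#' and pulse duration (s) are derived fields.
#'
#' @param body_weight patient body weight (kg)
#' @param dose_volume_per_kg injected volume per kg (mL/kg)
#' @param formulation_concentration gadoxetate formulation strength (mmol/mL)
#' @param injection_rate injector speed (mL/s)
#' @param t_injection_start injection start time (s)
#'
#' @return An object of class `dose_protocol` with derived `total_dose_mmol`
#'   and `duration_s`.
#' @export
dose_protocol <- function(body_weight = 70, dose_volume_per_kg = 0.1,
                          formulation_concentration = 0.25,
                          injection_rate = 1.0, t_injection_start = 0) {
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be positive", call. = FALSE)
  if (dose_volume_per_kg <= 0 || formulation_concentration <= 0 ||
      injection_rate <= 0)
    stop("dose volume, concentration and rate must be positive", call. = FALSE)
  vol <- body_weight * dose_volume_per_kg
  structure(list(
    body_weight = body_weight,
    dose_volume_per_kg = dose_volume_per_kg,
    formulation_concentration = formulation_concentration,
    injection_rate = injection_rate,
    t_injection_start = t_injection_start,
    total_dose_mmol = vol * formulation_concentration,
    duration_s = vol / injection_rate
  ), class = "dose_protocol")
}

#' Load model constants and dose defaults from a flat key-value config file
#'
#' Reads a YAML (or `key: value` text) file whose keys match the field names
#' of [physiological_constants()] and [dose_protocol()]; unknown keys are an
#' error. Either section may be partially specified.
#'
#' @param path path to the config file
#' @return list with elements `constants` and `dose`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  const_names <- names(formals(physiological_constants))
  dose_names <- names(formals(dose_protocol))
  unknown <- setdiff(names(cfg), c(const_names, dose_names))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  list(
    constants = do.call(physiological_constants, cfg[names(cfg) %in% const_names]),
    dose = do.call(dose_protocol, cfg[names(cfg) %in% dose_names])
  )
}
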