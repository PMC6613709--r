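#' Uncertainty model configuration
#'
#' The measurement-noise model used in every chi-square computation: each
#' observation's standard deviation is its ROI standard error of the mean,
#' floored from below by a cohort-wide lower limit of uncertainty
#' (default 0.18, on the delta-R1 scale the residuals live on).
#'
#' @param sigma_floor lower limit of the per-observation standard deviation
#' @param use_sem_when_larger take the SEM when it exceeds the floor
#' @return object of class `uncertainty_config`
#' @export
uncertainty_config <- function(sigma_floor = 0.18, use_sem_when_larger = TRUE) {
  if (!is.finite(sigma_floor) || sigma_floor <= 0)
    stop("sigma_floor must be positive", call. = FALSE)
  structure(list(sigma_floor = sigma_floor,
                 use_sem_when_larger = isTRUE(use_sem_when_larger)),
            class = "uncertainty_config")
}

#' Propagated uncertainty of a baseline-normalized signal intensity
#'
#' For S = SI(t) / SI(0), standard first-order error propagation gives
#' sigma_S = |S| sqrt((sigma_SI(t)/SI(t))^2 + (sigma_SI(0)/SI(0))^2).
#'
#' @param si_t signal intensity at time t
#' @param si_0 baseline (pre-injection) signal intensity; must be non-zero
#' @param sigma_si_t,sigma_si_0 standard deviations of the two intensities
#' @return propagated standard deviation of the normalized signal
#' @export
normalized_si_uncertainty <- function(si_t, si_0, sigma_si_t, sigma_si_0) {
  if (any(si_0 == 0)) stop("baseline signal intensity is zero", call. = FALSE)
  if (any(si_t == 0))
    stop("signal intensity at t is zero; relative error undefined",
         call. = FALSE)
  abs(si_t / si_0) * sqrt((sigma_si_t / si_t)^2 + (sigma_si_0 / si_0)^2)
}

#' Cohort-wide lower limit of data uncertainty
#'
#' The cohort floor is the mean over patients of each patient's mean
#' normalized-signal uncertainty across liver and spleen ROIs (equivalently
#' the location of a normal distribution fitted to the per-patient means).
#'
#' @param per_patient_mean_sigmas numeric vector, one mean sigma per patient
#' @return scalar lower-limit estimate
#' @export
cohort_lower_limit <- function(per_patient_mean_sigmas) {
  x <- per_patient_mean_sigmas
  if (length(x) == 0) stop("no per-patient uncertainties given", call. = FALSE)
  if (any(!is.finite(x) | x < 0))
    stop("uncertainties must be finite and non-negative", call. = FALSE)
  mean(x)
}

#' Effective per-observation standard deviation
#'
#' Implements the floor rule: use the ROI SEM unless it falls below the
#' cohort lower limit, in which case the floor is used.
#'
#' @param sem per-timepoint standard error of the mean (vectorised)
#' @param config [uncertainty_config()]
#' @return effective sigma, same length as `sem`
#' @export
effective_sigma <- function(sem, config = uncertainty_config()) {
  if (any(!is.finite(sem) | sem < 0))
    stop("SEM values must be finite and non-negative", call. = FALSE)
  if (!config$use_sem_when_larger) return(rep(config$sigma_floor, length(sem)))
  pmax(sem, config$sigma_floor)
}
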