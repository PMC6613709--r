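#' Split a patient's usable observations into estimation and validation sets
#'
#' Estimation: observations with `t_min <= t <= cutoff_s` (the short
#' protocol); validation: `t > cutoff_s`. Pre-window observations (bolus
#' phases and baseline) belong to neither set. An empty validation set is
#' flagged as insufficient rather than an error — such patients are
#' excluded from the truncation experiment, mirroring how patients without
#' late observations cannot contribute.
#'
#' @param patient [patient_record()]
#' @param cutoff_s split time (s), inclusive on the estimation side
#' @param t_min first usable observation time (s)
#' @return list with `estimation` and `validation` patient records (the
#'   latter `NULL` when empty) and logical `sufficient`
#' @export
split_at_cutoff <- function(patient, cutoff_s = 600, t_min = 180) {
  sub_record <- function(keep) {
    if (!any(keep)) return(NULL)
    patient_record(patient$patient_id, patient$times[keep],
                   patient$liver_dr1[keep], patient$liver_sem[keep],
                   patient$spleen_dr1[keep], patient$spleen_sem[keep],
                   body_weight = patient$body_weight,
                   fibrosis_stage = patient$fibrosis_stage)
  }
  est_keep <- patient$times >= t_min & patient$times <= cutoff_s
  val_keep <- patient$times > cutoff_s
  if (!any(est_keep))
    stop("patient '", patient$patient_id, "': no estimation data in [",
         t_min, ", ", cutoff_s, "] s", call. = FALSE)
  list(estimation = sub_record(est_keep),
       validation = sub_record(val_keep),
       sufficient = any(val_keep))
}

#' Short-protocol truncation experiment
#'
#' For every patient with observations on both sides of the cutoff, fits
#' the model to the estimation window only — per-patient chi-square
#' minimization for `method = "STS"`, leave-one-out population MAP for
#' `method = "NLME"` — then simulates forward and tests goodness-of-fit
#' separately on the estimation and validation observations (degrees of
#' freedom equal to the observation count in each subset). Per-patient fit
#' failures are returned as flagged rows, never abort the cohort.
#'
#' @param cohort [cohort()]
#' @param method `"STS"` or `"NLME"`
#' @param cutoff_s estimation/validation split time (s)
#' @param constants,config,t_min,alpha as elsewhere
#' @param init initial population model for NLME
#' @param sts_settings [optimizer_settings()] for the STS fits
#' @param ... further arguments passed to [leave_one_out_truncated_fit()]
#'   (tolerances, iteration caps)
#' @return data.frame, one row per patient: id, stage, method, convergence
#'   flag, estimation and validation chi-square/df/pass, and the fitted
#'   parameters
#' @export
truncation_experiment <- function(cohort, method = c("NLME", "STS"),
                                  cutoff_s = 600,
                                  constants = physiological_constants(),
                                  config = uncertainty_config(),
                                  t_min = 180, alpha = 0.05,
                                  init = prior_population(),
                                  sts_settings = optimizer_settings(), ...) {
  method <- match.arg(method)
  rows <- lapply(cohort$patients, function(pat) {
    dose <- dose_protocol(body_weight = pat$body_weight)
    split <- tryCatch(split_at_cutoff(pat, cutoff_s, t_min),
                      error = function(e) NULL)
    base <- data.frame(patient_id = pat$patient_id,
                       fibrosis_stage = pat$fibrosis_stage, method = method,
                       sufficient = !is.null(split) && split$sufficient,
                       converged = NA, est_chi2 = NA_real_,
                       est_df = NA_integer_, est_pass = NA,
                       val_chi2 = NA_real_, val_df = NA_integer_,
                       val_pass = NA, k_diff = NA_real_, k_ph = NA_real_,
                       k_hp = NA_real_, k_hb = NA_real_, xi = NA_real_)
    if (is.null(split) || (!split$sufficient && is.finite(cutoff_s)))
      return(base)
    fit <- tryCatch({
      if (method == "STS")
        fit_sts(pat, constants, dose, config, settings = sts_settings,
                t_min = t_min, t_max = cutoff_s, alpha = alpha)
      else
        leave_one_out_truncated_fit(cohort, pat$patient_id, cutoff_s,
                                    init = init, constants = constants,
                                    config = config, t_min = t_min,
                                    alpha = alpha, ...)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      base$converged <- FALSE
      attr(base, "error") <- conditionMessage(fit)
      return(base)
    }
    params <- fit$params
    est_chi2 <- chi2_cost(params, pat, constants, dose, config,
                          t_min = t_min, t_max = cutoff_s)
    est_n <- 2L * sum(pat$times >= t_min & pat$times <= cutoff_s)
    val_n <- 2L * sum(pat$times > cutoff_s)
    est_gof <- gof_test(est_chi2, est_n, alpha)
    base$converged <- if (!is.null(fit$converged)) fit$converged else TRUE
    base$est_chi2 <- est_chi2; base$est_df <- est_gof$df
    base$est_pass <- est_gof$passed
    if (val_n > 0) {
      val_chi2 <- chi2_cost(params, pat, constants, dose, config,
                            t_min = cutoff_s * (1 + 1e-12), t_max = Inf)
      val_gof <- gof_test(val_chi2, val_n, alpha)
      base$val_chi2 <- val_chi2; base$val_df <- val_gof$df
      base$val_pass <- val_gof$passed
    }
    base$k_diff <- params$k_diff; base$k_ph <- params$k_ph
    base$k_hp <- params$k_hp; base$k_hb <- params$k_hb; base$xi <- params$xi
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lin's concordance correlation coefficient
#'
#' Agreement statistic penalizing both dispersion and location shift:
#' r_c = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2), with population
#' (n-denominator) moments. Equals 1 iff y = x elementwise.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return scalar in `[-1, 1]`
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("concordance undefined: zero variance and equal means",
         call. = FALSE)
  2 * sxy / denom
}

#' Predict blood and liver-biopsy gadoxetate concentrations from a fit
#'
#' Simulates the model with the fitted individual parameters and returns
#' the whole-blood concentration and the wet-tissue liver concentration at
#' the sampling time (default 1800 s, immediately after the 30-min
#' protocol).
#'
#' @param fit a `fit_result` or `individual_estimate`
#' @param t_sample venipuncture/biopsy time (s after injection)
#' @param constants [physiological_constants()]
#' @param dose [dose_protocol()]
#' @param hematocrit red-cell volume fraction for the blood value
#' @return named numeric: `blood_mM`, `liver_mM`
#' @export
predict_sample_concentrations <- function(fit, t_sample = 1800,
                                          constants =
                                            physiological_constants(),
                                          dose = dose_protocol(),
                                          hematocrit = 0.45) {
  if (t_sample <= dose$t_injection_start)
    stop("sample time must be after the injection", call. = FALSE)
  traj <- simulate_gadoxetate(fit$params, constants, dose,
                              times = c(0, t_sample))
  c(blood_mM = blood_concentration(traj, t_sample, hematocrit),
    liver_mM = liver_tissue_concentration(traj, constants, t_sample))
}

#' Fibrosis-stage group analysis of fitted parameters
#'
#' Per parameter: group means and SEMs by stage, one-way ANOVA with
#' Tukey's honest-significant-difference post-test across stages, and —
#' for two-group contrasts — an unpaired two-tailed Mann-Whitney U-test.
#' For paired comparisons of two fitting methods on the same patients use
#' [paired_method_test()].
#'
#' @param estimates data.frame with columns `fibrosis_stage` plus one
#'   column per parameter to analyse
#' @param parameters character vector of parameter column names
#' @param log_scale analyse log-transformed values (natural for the
#'   lognormal rates)
#' @return named list per parameter: `group_stats` (stage, n, mean, sem),
#'   `anova_F`, `anova_p`, `tukey` (pairwise adjusted p-values)
#' @export
fibrosis_group_analysis <- function(estimates,
                                    parameters = c("k_diff", "k_ph",
                                                   "k_hp", "k_hb"),
                                    log_scale = TRUE) {
  df <- estimates[estimates$fibrosis_stage %in% paste0("F", 0:4), ]
  df$fibrosis_stage <- factor(df$fibrosis_stage, levels = paste0("F", 0:4))
  df$fibrosis_stage <- droplevels(df$fibrosis_stage)
  counts <- table(df$fibrosis_stage)
  if (sum(counts >= 2) < 2)
    stop("need at least two stages with at least two patients each",
         call. = FALSE)
  out <- list()
  for (par in parameters) {
    v <- if (log_scale) log(df[[par]]) else df[[par]]
    keep <- is.finite(v)
    if (any(!keep))
      warning(sum(!keep), " non-finite values of ", par, " dropped",
              call. = FALSE)
    d <- data.frame(value = v[keep], stage = df$fibrosis_stage[keep])
    gs <- do.call(rbind, lapply(split(d$value, d$stage), function(x)
      data.frame(n = length(x), mean = mean(x),
                 sem = stats::sd(x) / sqrt(length(x)))))
    gs <- cbind(stage = rownames(gs), gs)
    rownames(gs) <- NULL
    fit <- stats::aov(value ~ stage, data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$stage
    out[[par]] <- list(group_stats = gs,
                       anova_F = an[["F value"]][1],
                       anova_p = an[["Pr(>F)"]][1],
                       tukey = tk)
  }
  out
}

#' Unpaired two-group comparison of a parameter between stage groups
#'
#' Two-tailed Mann-Whitney U-test (Wilcoxon rank-sum).
#'
#' @param values numeric vector
#' @param group logical or two-level factor defining the groups
#' @return htest object
#' @export
mann_whitney_groups <- function(values, group) {
  stats::wilcox.test(values ~ factor(group), exact = FALSE)
}

#' Paired comparison of two parametrization methods
#'
#' Two-tailed Wilcoxon signed-rank test on per-patient pairs (the
#' non-parametric paired analogue of the unpaired Mann-Whitney U-test).
#'
#' @param x,y paired per-patient values from the two methods
#' @return htest object
#' @export
paired_method_test <- function(x, y) {
  stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
}

#' Confusion matrix for detecting advanced fibrosis from hepatocyte uptake
#'
#' Predicted advanced fibrosis when the fitted uptake rate falls below the
#' cutoff (uptake decreases with fibrosis); truth is histological stage F3
#' or F4. Patients with unknown stage are excluded with a warning.
#'
#' @param estimates data.frame with columns `k_ph` and `fibrosis_stage`
#' @param cutoff uptake-rate threshold (s^-1)
#' @return object of class `confusion_matrix` with fields `tn`, `fp`,
#'   `fn`, `tp` and accessors via `print`
#' @export
advanced_fibrosis_confusion <- function(estimates, cutoff = 0.00198) {
  staged <- estimates$fibrosis_stage %in% paste0("F", 0:4)
  if (any(!staged))
    warning(sum(!staged), " patients with unknown stage excluded",
            call. = FALSE)
  df <- estimates[staged, ]
  truth <- df$fibrosis_stage %in% c("F3", "F4")
  pred <- df$k_ph < cutoff
  structure(list(tn = sum(!truth & !pred), fp = sum(!truth & pred),
                 fn = sum(truth & !pred), tp = sum(truth & pred),
                 cutoff = cutoff, n = nrow(df)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("true not advanced", "true advanced"),
                              c("pred not advanced", "pred advanced")))
  cat("advanced-fibrosis confusion matrix (k_ph cutoff ",
      format(x$cutoff), " s^-1, n = ", x$n, ")\n", sep = "")
  print(m)
  sens <- x$tp / (x$tp + x$fn)
  spec <- x$tn / (x$tn + x$fp)
  cat(sprintf("sensitivity %.3f, specificity %.3f\n", sens, spec))
  invisible(x)
}
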