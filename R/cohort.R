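FIBROSIS_STAGES <- c("F0", "F1", "F2", "F3", "F4", "unknown")

#' One patient's gadoxetate MRI time series
#'
#' Liver and spleen delta-R1 means (across 7 liver / 3 spleen ROIs) with
#' per-timepoint SEMs, on a common time axis in seconds relative to the
#' start of the contrast injection. A pre-injection baseline row, if
#' present, is encoded with a negative time and delta-R1 of exactly 0.
#'
#' @param patient_id unique identifier (character)
#' @param times observation times (s relative to injection), strictly
#'   increasing
#' @param liver_dr1,spleen_dr1 delta-R1 means (s^-1) per time
#' @param liver_sem,spleen_sem SEM across ROIs per time (>= 0)
#' @param body_weight kg (default 70)
#' @param fibrosis_stage one of `"F0"`..`"F4"` or `"unknown"`
#' @return object of class `patient_record`
#' @export
patient_record <- function(patient_id, times, liver_dr1, liver_sem,
                           spleen_dr1, spleen_sem, body_weight = 70,
                           fibrosis_stage = "unknown") {
  bad <- function(msg, field)
    stop("patient '", patient_id, "', field '", field, "': ", msg,
         call. = FALSE)
  if (!is.character(patient_id) || length(patient_id) != 1 ||
      !nzchar(patient_id))
    stop("patient_id must be a non-empty string", call. = FALSE)
  n <- length(times)
  if (n == 0) bad("empty time series", "times")
  for (f in c("liver_dr1", "liver_sem", "spleen_dr1", "spleen_sem")) {
    v <- get(f)
    if (length(v) != n) bad("length differs from times", f)
    if (any(!is.finite(v))) bad("non-finite values", f)
  }
  if (any(diff(times) <= 0)) bad("must be strictly increasing", "times")
  if (any(liver_sem < 0)) bad("negative SEM", "liver_sem")
  if (any(spleen_sem < 0)) bad("negative SEM", "spleen_sem")
  pre <- times < 0
  if (sum(pre) > 1) bad("more than one pre-injection time", "times")
  if (any(pre) && (any(liver_dr1[pre] != 0) || any(spleen_dr1[pre] != 0)))
    bad("pre-injection delta-R1 must be 0 (baseline definition)", "times")
  if (!fibrosis_stage %in% FIBROSIS_STAGES)
    bad(paste("must be one of", paste(FIBROSIS_STAGES, collapse = ", ")),
        "fibrosis_stage")
  if (!is.finite(body_weight) || body_weight <= 0)
    bad("must be positive", "body_weight")
  structure(list(patient_id = patient_id, fibrosis_stage = fibrosis_stage,
                 body_weight = body_weight, times = as.numeric(times),
                 liver_dr1 = as.numeric(liver_dr1),
                 liver_sem = as.numeric(liver_sem),
                 spleen_dr1 = as.numeric(spleen_dr1),
                 spleen_sem = as.numeric(spleen_sem)),
            class = "patient_record")
}

#' A cohort of patient records
#'
#' @param patients list of [patient_record()] objects
#' @param provenance free-text description of where the data came from
#' @return object of class `gadoxetate_cohort`
#' @export
cohort <- function(patients, provenance = "") {
  if (length(patients) == 0) stop("cohort must be non-empty", call. = FALSE)
  if (!all(vapply(patients, inherits, logical(1), "patient_record")))
    stop("all elements must be patient_record objects", call. = FALSE)
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(patients) <- ids
  structure(list(patients = patients, provenance = provenance),
            class = "gadoxetate_cohort")
}

#' @export
length.gadoxetate_cohort <- function(x) length(x$patients)

#' @export
print.gadoxetate_cohort <- function(x, ...) {
  stages <- table(factor(vapply(x$patients, `[[`, character(1),
                                "fibrosis_stage"), levels = FIBROSIS_STAGES))
  cat("gadoxetate cohort:", length(x$patients), "patients\n")
  cat("fibrosis stages:",
      paste(names(stages), stages, sep = "=", collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

patient_to_long <- function(p) {
  rbind(
    data.frame(patient_id = p$patient_id, fibrosis_stage = p$fibrosis_stage,
               body_weight = p$body_weight, time_s = p$times,
               tissue = "liver", dr1 = p$liver_dr1, sem = p$liver_sem),
    data.frame(patient_id = p$patient_id, fibrosis_stage = p$fibrosis_stage,
               body_weight = p$body_weight, time_s = p$times,
               tissue = "spleen", dr1 = p$spleen_dr1, sem = p$spleen_sem)
  )
}

long_to_patient <- function(df) {
  liv <- df[df$tissue == "liver", ]
  spl <- df[df$tissue == "spleen", ]
  liv <- liv[order(liv$time_s), ]
  spl <- spl[order(spl$time_s), ]
  if (nrow(liv) != nrow(spl) || any(liv$time_s != spl$time_s))
    stop("patient '", df$patient_id[1],
         "': liver and spleen time axes differ", call. = FALSE)
  patient_record(patient_id = as.character(df$patient_id[1]),
                 times = liv$time_s,
                 liver_dr1 = liv$dr1, liver_sem = liv$sem,
                 spleen_dr1 = spl$dr1, spleen_sem = spl$sem,
                 body_weight = df$body_weight[1],
                 fibrosis_stage = as.character(df$fibrosis_stage[1]))
}

#' Read a cohort from CSV (long format) or JSON (nested)
#'
#' CSV columns: `patient_id, fibrosis_stage, body_weight, time_s, tissue,
#' dr1, sem` with `tissue` in liver/spleen. JSON: list with `provenance`
#' and `patients`, each patient an object with the [patient_record()]
#' fields. All record invariants are validated on read; violations raise
#' errors naming the patient and field.
#'
#' @param path file path
#' @param format `"csv"` or `"json"`; guessed from the extension by default
#' @return a `gadoxetate_cohort`
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "fibrosis_stage", "body_weight", "time_s",
              "tissue", "dr1", "sem")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing required columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    pats <- lapply(split(df, df$patient_id), long_to_patient)
    pats <- pats[unique(df$patient_id)]  # preserve file order
    cohort(unname(pats), provenance = paste("read from", path))
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pats <- lapply(seq_len(nrow(j$patients)), function(i) {
      r <- j$patients[i, ]
      patient_record(patient_id = r$patient_id,
                     times = r$times[[1]],
                     liver_dr1 = r$liver_dr1[[1]], liver_sem = r$liver_sem[[1]],
                     spleen_dr1 = r$spleen_dr1[[1]],
                     spleen_sem = r$spleen_sem[[1]],
                     body_weight = r$body_weight,
                     fibrosis_stage = r$fibrosis_stage)
    })
    cohort(pats, provenance = j$provenance %||% paste("read from", path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV or JSON
#'
#' @param x a `gadoxetate_cohort`
#' @param path output file path
#' @param format `"csv"` or `"json"`; guessed from the extension by default
#' @return `path`, invisibly
#' @export
write_cohort <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- do.call(rbind, lapply(x$patients, patient_to_long))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(provenance = x$provenance,
           patients = lapply(unname(x$patients), unclass)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read per-patient time series from a MATLAB .mat container
#'
#' Converts the MAT container to JSON with a bundled Python helper (scipy.io
#' does the MAT parsing) and validates the result into a cohort. The reader
#' targets a canonical layout — a struct array `patients` with fields
#' `id`, `times`, `liver_dr1`, `liver_sem`, `spleen_dr1`, `spleen_sem`,
#' `weight` and `stage` (numeric 0-4, mapped to F0-F4) — and accepts a
#' field-name mapping for files using other names. Patients missing the
#' stage field load as `"unknown"` with a warning; unknown extra fields are
#' ignored with a warning.
#'
#' @param path path to the .mat file
#' @param field_map named character vector mapping canonical field names to
#'   the names used inside the file, e.g. `c(liver_dr1 = "liverR1")`
#' @param python python interpreter to invoke (needs scipy)
#' @return a `gadoxetate_cohort`
#' @export
read_s1_mat <- function(path, field_map = character(), python = "python") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  script <- system.file("python", "mat_to_json.py", package = "gadoflux")
  if (!nzchar(script)) stop("bundled mat_to_json.py not found", call. = FALSE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  args <- c(script, path, tmp)
  if (length(field_map))
    args <- c(args, "--map",
              paste(names(field_map), field_map, sep = "=", collapse = ","))
  status <- system2(python, shQuote(args), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0
  if (code != 0 || !file.exists(tmp))
    stop("could not parse MAT container '", path, "': ",
         paste(status, collapse = "\n"), call. = FALSE)
  j <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  for (w in unlist(j$warnings)) warning(w, call. = FALSE)
  pats <- lapply(j$patients, function(r) {
    stage <- if (is.null(r$stage)) "unknown"
    else FIBROSIS_STAGES[as.integer(r$stage) + 1]
    patient_record(patient_id = as.character(r$id),
                   times = unlist(r$times),
                   liver_dr1 = unlist(r$liver_dr1),
                   liver_sem = unlist(r$liver_sem),
                   spleen_dr1 = unlist(r$spleen_dr1),
                   spleen_sem = unlist(r$spleen_sem),
                   body_weight = r$weight %||% 70,
                   fibrosis_stage = stage)
  })
  cohort(pats, provenance = paste("MAT file", path))
}

#' Write per-patient fit results to CSV
#'
#' One row per fitted patient: id, fibrosis stage, the five parameter
#' estimates, chi-square, degrees of freedom, pass/reject verdict and
#' fitting method. Numbers are written with enough digits to round-trip.
#'
#' @param fits list of `fit_result` objects (see [fit_sts()]) or
#'   `individual_estimate` objects (see [fit_individual_map()])
#' @param path output CSV path
#' @param stages optional named character vector patient_id -> stage
#' @return the results data.frame, invisibly
#' @export
write_results <- function(fits, path, stages = NULL) {
  if (length(fits) == 0) stop("no fits to write", call. = FALSE)
  rows <- lapply(fits, function(f) {
    p <- f$params
    data.frame(patient_id = f$patient_id %||% NA_character_,
               fibrosis_stage =
                 if (!is.null(stages)) stages[[f$patient_id]] %||% "unknown"
                 else f$fibrosis_stage %||% "unknown",
               k_diff = p$k_diff, k_ph = p$k_ph, k_hp = p$k_hp,
               k_hb = p$k_hb, xi = p$xi,
               chi2 = f$gof$chi2, df = f$gof$df,
               verdict = if (f$gof$passed) "pass" else "reject",
               method = f$method)
  })
  df <- do.call(rbind, rows)
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 15,
                                                  scientific = TRUE,
                                                  trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
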