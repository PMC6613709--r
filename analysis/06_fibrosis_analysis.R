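#!/usr/bin/env Rscript
# Fibrosis-stage analysis: how do the fitted transporter rates vary with
# histological stage? One-way ANOVA with Tukey's post-test per parameter
# (log scale), plus the advanced-fibrosis (>= F3) classification by the
# hepatocyte uptake rate at the 0.00198 s^-1 cut-off.
suppressPackageStartupMessages(library(gadoflux))

est <- utils::read.csv("results/fits_nlme.csv")

res <- fibrosis_group_analysis(est)
for (par in names(res)) {
  r <- res[[par]]
  cat(sprintf("\n%s: ANOVA F = %.2f, p = %.2g\n", par, r$anova_F,
              r$anova_p))
  print(round(r$group_stats[, c("n", "mean", "sem")], 3))
  sig <- r$tukey[r$tukey[, "p adj"] < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant Tukey contrasts:\n")
    print(round(sig, 4))
  }
}

cm <- advanced_fibrosis_confusion(est)
cat("\n")
print(cm)
jsonlite::write_json(
  list(tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp,
       cutoff = cm$cutoff,
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp)),
  "results/confusion_matrix.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/confusion_matrix.json\n")
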