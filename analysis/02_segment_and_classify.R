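#!/usr/bin/env Rscript
# Segment the simulated imaging fields, measure envelope coverage,
# classify nuclei as normal / deformed / ruptured, and compare cohort
# fractions between control and depleted groups with a chi-square test.
# Reads results/data/, writes results/nuclei_*.csv and results/cohorts.csv.

library(nucmorph)

indir <- "results/data"
dir.create("results", showWarnings = FALSE)
pixel_size <- 0.2

records <- list()
for (g in c("control", "depleted")) {
  recs <- list()
  for (f in 1:3) {
    img <- read_multipage_tiff(file.path(indir,
                                         sprintf("field_%s_%d.tif", g, f)))
    seg <- segment_nuclei(img[, , 1], pixel_size)
    cov <- assess_envelope_coverage(seg$label, img[, , 2], pixel_size)
    rec <- classify_phenotype(merge(seg$records, cov, by = "nucleus_id"))
    rec$field <- f
    recs[[f]] <- rec
  }
  records[[g]] <- do.call(rbind, recs)
  write.csv(records[[g]], sprintf("results/nuclei_%s.csv", g),
            row.names = FALSE)
}

cohorts <- rbind(score_cohort(records$control, "control"),
                 score_cohort(records$depleted, "depleted"))
write.csv(cohorts, "results/cohorts.csv", row.names = FALSE)
print(cohorts)

tab <- rbind(
  control = table(factor(records$control$phenotype_class != "normal",
                         levels = c(TRUE, FALSE))),
  depleted = table(factor(records$depleted$phenotype_class != "normal",
                          levels = c(TRUE, FALSE))))
cmp <- compare_groups(unclass(tab), "chi_square")
message(sprintf(
  "abnormal nuclei: control %.0f%%, depleted %.0f%% (chi2 = %.1f, p = %.2g)",
  100 * mean(records$control$phenotype_class != "normal"),
  100 * mean(records$depleted$phenotype_class != "normal"),
  cmp$statistic, cmp$p_value))
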