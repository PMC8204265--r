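#!/usr/bin/env Rscript
# Region comparison from the tables written by 02_cohorts.R: group
# mean +/- SEM per metabolite and region, and Welch unpaired t-tests
# between regions for the water-referenced concentrations before and
# after tissue correction. With equal true concentrations in both
# regions, the uncorrected estimates should differ (tissue-driven) and
# the corrected ones should not.
#
# Output: results/region_comparison.csv

library(hermesneo)

for (f in c("results/acc/quant.csv", "results/thalamus/quant.csv")) {
  if (!file.exists(f)) stop("missing ", f, "; run analysis/02_cohorts.R first")
}
quant <- rbind(read.csv("results/acc/quant.csv"),
               read.csv("results/thalamus/quant.csv"))

rows <- list()
for (m in unique(quant$metabolite)) {
  for (mode in c("conc_uncorrected", "conc_corrected")) {
    va <- quant[[mode]][quant$metabolite == m & quant$region == "ACC"]
    vb <- quant[[mode]][quant$metabolite == m & quant$region == "thalamus"]
    ga <- group_stats(va); gb <- group_stats(vb)
    tt <- compare_regions(va, vb)
    rows[[paste(m, mode)]] <- data.frame(
      metabolite = m, mode = sub("conc_", "", mode),
      acc_mean = ga$mean, acc_sem = ga$sem,
      tha_mean = gb$mean, tha_sem = gb$sem,
      t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value)
    message(sprintf(
      "%5s %-12s ACC %7.2f+/-%5.2f  THA %7.2f+/-%5.2f  p = %.4f",
      m, sub("conc_", "", mode), ga$mean, ga$sem, gb$mean, gb$sem,
      tt$p_value))
  }
}
write.csv(do.call(rbind, rows), "results/region_comparison.csv",
          row.names = FALSE)
message("wrote results/region_comparison.csv")
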