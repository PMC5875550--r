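#!/usr/bin/env Rscript
# Step 3 — pooled correlation study.
#
# Per organ group, the Pearson correlation between each geometric metric and
# the dosimetric accuracy, with two-sided p-values and a p < 0.05
# significance flag, plus outside-interobserver-range counts and group
# summaries. Reads results/case_records.csv written by step 2.

suppressPackageStartupMessages(library(contourdose))

tab <- read.csv("results/case_records.csv")
metric_cols <- c("dsc", "ci", "centroid_sep_mm", "mean_dta_mm",
                 "max_dta_mm", "hd95_mm")

rows <- list()
for (grp in unique(tab$organ_group)) {
  sub <- tab[tab$organ_group == grp, ]
  for (m in metric_cols) {
    ct <- pearson(sub[[m]], sub$accuracy_pct)
    rows[[length(rows) + 1]] <- data.frame(organ_group = grp, metric = m,
                                           r = ct$r, p = ct$p, n = ct$n,
                                           significant = ct$p < 0.05)
  }
}
correlations <- do.call(rbind, rows)
write.csv(correlations, "results/correlation_table.csv", row.names = FALSE)

message("Correlation of each metric with dosimetric accuracy:")
for (i in seq_len(nrow(correlations))) {
  with(correlations[i, ],
       message(sprintf("  %-13s %-16s r = %+.2f  p = %.4f%s", organ_group,
                       metric, r, p, ifelse(significant, " *", ""))))
}

summary_json <- lapply(split(tab, tab$organ_group), function(sub) {
  list(n = nrow(sub),
       mean_accuracy_pct = mean(sub$accuracy_pct),
       sd_accuracy_pct = sd(sub$accuracy_pct),
       mean_dsc = mean(sub$dsc),
       outside_iov = sum(sub$outside_iov),
       strongest_metric = local({
         co <- correlations[correlations$organ_group == sub$organ_group[1], ]
         co$metric[which.max(abs(co$r))]
       }))
})
jsonlite::write_json(summary_json, "results/summary.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
message("Wrote results/correlation_table.csv and results/summary.json")
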