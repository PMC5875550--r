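#!/usr/bin/env Rscript
# Step 4 — figures.
#
# (a) Per-case box plots of the dosimetric interobserver variation with the
#     auto contour's accuracy overlaid as a point: whenever the point falls
#     outside the whiskers, the auto contour is dosimetrically worse than
#     observer disagreement can explain.
# (b) Scatter plots of dosimetric accuracy against centroid separation and
#     against DSC for the parotid-like group, with least-squares lines.
# Reads results/case_records.csv from step 2; writes PNGs to results/figures/.

suppressPackageStartupMessages({
  library(contourdose)
  library(ggplot2)
})

tab <- read.csv("results/case_records.csv")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (grp in unique(tab$organ_group)) {
  sub <- tab[tab$organ_group == grp, ]
  sub$case <- seq_len(nrow(sub))
  p <- ggplot(sub, aes(x = factor(case))) +
    geom_boxplot(aes(ymin = iov_min_pct, lower = iov_q1_pct,
                     middle = iov_median_pct, upper = iov_q3_pct,
                     ymax = iov_max_pct), stat = "identity",
                 fill = "grey85", width = 0.6) +
    geom_point(aes(y = accuracy_pct, colour = outside_iov), size = 2) +
    scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                        name = "outside IOV") +
    labs(x = "case", y = "mean-dose difference vs reference (%)",
         title = sprintf("Dosimetric interobserver variation (%s)", grp)) +
    theme_bw()
  out <- sprintf("results/figures/iov_%s.png", gsub("-like", "", grp))
  ggsave(out, p, width = 8, height = 4.5, dpi = 150)
  message("Wrote ", out)
}

par_tab <- tab[tab$organ_group == "parotid-like", ]
for (m in c("centroid_sep_mm", "dsc")) {
  r <- pearson(par_tab[[m]], par_tab$accuracy_pct)
  p <- ggplot(par_tab, aes(x = .data[[m]], y = accuracy_pct)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    labs(x = m, y = "dosimetric accuracy (%)",
         title = sprintf("Parotid-like: accuracy vs %s (r = %.2f)", m, r$r)) +
    theme_bw()
  out <- sprintf("results/figures/scatter_%s.png", m)
  ggsave(out, p, width = 5, height = 4.5, dpi = 150)
  message("Wrote ", out)
}
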