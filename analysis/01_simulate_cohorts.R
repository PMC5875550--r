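#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Two synthetic cohorts stand in for the clinical study population:
#   * 20 parotid-like structures sitting on a steep unidirectional dose
#     gradient, with auto-contour errors dominated by down-gradient shifts;
#   * 10 larynx-like structures in a central dose trough between opposing
#     gradients, with well-localized auto contours that systematically
#     undersegment.
# Each case carries a ground-truth organ, five simulated observer contours,
# an auto contour, and its dose field. Everything is a pure function of the
# seed; manifests go to results/.

suppressPackageStartupMessages(library(contourdose))

seed <- 1L
dir.create("results", showWarnings = FALSE)

message("Simulating 20 parotid-like cases ...")
parotid <- generate_cohort(20, "parotid-like", seed = seed)
write_manifest(parotid, "results/manifest_parotid.csv")

message("Simulating 10 larynx-like cases ...")
larynx <- generate_cohort(10, "larynx-like", seed = seed + 1L)
write_manifest(larynx, "results/manifest_larynx.csv")

for (co in list(parotid, larynx)) {
  vols <- sapply(co$cases, function(cs) volume_mm3(cs$truth)) / 1000
  doses <- sapply(co$cases, function(cs) mean_dose(cs$dose, cs$truth))
  message(sprintf("%s: %d cases, truth volume %.1f-%.1f cm^3, mean truth dose %.0f-%.0f cGy",
                  co$regime, length(co$cases), min(vols), max(vols),
                  min(doses), max(doses)))
}
message("Manifests written to results/manifest_{parotid,larynx}.csv")
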