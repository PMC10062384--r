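#!/usr/bin/env Rscript
# Influence of cerebrospinal fluid on three-layer CBFi recovery.
#
# Simulates photon transport through four-layer slabs (scalp 6 mm, skull
# 6 mm, CSF 1-4 mm, brain), synthesizes g2 for the 72-point flow grid, and
# fits the three-layer model under the two CSF-grouping conventions:
# CSF lumped into layer 2 (L2 = skull + CSF) or ignored (L2 = skull).
# Writes per-point errors and boxplot summaries to results/csf/.
#
# Usage: Rscript analysis/02_csf_study.R [n_photons] [seed]

library(dcslayers)

args <- commandArgs(trailingOnly = TRUE)
n_photons <- if (length(args) >= 1) as.numeric(args[1]) else 5e6
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

out_dir <- "results/csf"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

res <- run_study(list(suite = "csf", csf_thickness_mm = 1:4,
                      n_photons = n_photons, seed = seed))
write.csv(res$per_point, file.path(out_dir, "per_point.csv"),
          row.names = FALSE)
write.csv(res$summaries, file.path(out_dir, "summary.csv"),
          row.names = FALSE)
jsonlite::write_json(list(n_photons = n_photons, seed = seed,
                          conventions = c("csf_layer2", "csf_layer3")),
                     file.path(out_dir, "manifest.json"), auto_unbox = TRUE)

cat("\nCBFi percentage error by CSF thickness and grouping convention:\n")
s <- res$summaries[res$summaries$metric == "cbfi_error_pct", ]
print(s[order(s$convention, s$scenario),
        c("scenario", "convention", "median", "q25", "q75")],
      row.names = FALSE, digits = 3)
cat("\nrCBFi error (percentage points):\n")
s <- res$summaries[res$summaries$metric == "rcbfi_error_pp", ]
print(s[order(s$convention, s$scenario),
        c("scenario", "convention", "median", "whisker_lo", "whisker_hi")],
      row.names = FALSE, digits = 3)
cat("\nExpected pattern: grouping CSF into layer 2 overestimates CBFi",
    "(worse with thicker CSF); ignoring CSF underestimates it; relative",
    "changes are recovered far more accurately than absolute values.\n")
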