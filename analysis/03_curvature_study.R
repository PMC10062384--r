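#!/usr/bin/env Rscript
# Influence of head curvature on three-layer CBFi recovery.
#
# Simulates photon transport on three-layer spheres (outer radius 7-10 cm)
# and on the flat slab twin, fits the (planar) three-layer model using
# either the arc separation or the straight chord, and summarizes errors.
# Writes results/curvature/.
#
# Usage: Rscript analysis/03_curvature_study.R [n_photons] [seed]

library(dcslayers)

args <- commandArgs(trailingOnly = TRUE)
n_photons <- if (length(args) >= 1) as.numeric(args[1]) else 5e6
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

out_dir <- "results/curvature"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

res <- run_study(list(suite = "sphere", radii_cm = c(7, 8, 9, 10),
                      n_photons = n_photons, seed = seed))
write.csv(res$per_point, file.path(out_dir, "per_point.csv"),
          row.names = FALSE)
write.csv(res$summaries, file.path(out_dir, "summary.csv"),
          row.names = FALSE)

# flat (zero-curvature) reference with the same layers
lay <- detector_layout(c(1, 2.5), distance_convention = "line")
flat <- simulate_slab(make_flat_scenario(), lay, n_photons, seed)
sw <- sweep_three_layer(flat, make_flow_grid(), 0.6, 0.6,
                        standard_fit_props(), label = "flat")
sw <- cbind(scenario = "slab_flat", sw)
flat_tab <- grid_error_table(sw)
write.csv(flat_tab, file.path(out_dir, "per_point_flat.csv"),
          row.names = FALSE)

cat("\nMedian CBFi percentage error by radius and separation convention:\n")
s <- res$summaries[res$summaries$metric == "cbfi_error_pct", ]
print(s[order(s$scenario, s$convention),
        c("scenario", "convention", "median", "q25", "q75")],
      row.names = FALSE, digits = 3)
cat(sprintf("\nflat-slab control: median %.1f%%\n",
            median(flat_tab$cbfi_error_pct)))
cat("\nExpected pattern: curvature causes a systematic underestimation of",
    "CBFi at every radius, while the arc-vs-chord separation choice has",
    "minimal influence; rCBFi errors stay within a much tighter band.\n")
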