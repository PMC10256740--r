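#!/usr/bin/env Rscript
# Anchored versus freely diffusing RNP reporters: MSD-based diffusion
# estimation at the ensemble medians reported for MCP-Halo fusions, plus a
# confinement series reproducing the anchoring signature.
# Writes results/anchoring_dynamics.tsv and results/confinement_series.tsv.

suppressPackageStartupMessages(library(rnptrack))
dir.create("results", showWarnings = FALSE)

# Reported ensemble median diffusion coefficients (um^2/s) for the
# MCP-Halo constructs: full-length RIM fusion (most anchored), deletion
# mutants, and the free coat protein.
conditions <- data.frame(
  label = c("MCP-Halo-RIM", "MCP-Halo-dC-RIM", "MCP-Halo-d3dC-RIM",
            "MCP-Halo", "MCP-Halo-Cterm"),
  D = c(6.7e-3, 1.47e-2, 1.16e-2, 2.31e-2, 1.10e-2))

rows <- lapply(seq_len(nrow(conditions)), function(i) {
  acq <- acquisition_spec(nx = 600, ny = 600, n_frames = 600,
                          noise = "none", seed = 300L + i)
  ts <- simulate_tracks(motion_model("brownian", D = conditions$D[i]),
                        acq, 250, boundary = "none", start = "center")
  dyn <- summarize_dynamics(ts)
  data.frame(condition = conditions$label[i],
             generative_D = conditions$D[i],
             median_D_hat = dyn$ensemble$D_um2_per_s,
             median_log10_D = dyn$ensemble$log10_D,
             median_d_max_um = dyn$ensemble$d_max_um)
})
out <- do.call(rbind, rows)
write.table(out, "results/anchoring_dynamics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(out, digits = 3)

# Confinement series: fixed generative D, shrinking corral radius.
series <- lapply(c(Inf, 1, 0.5, 0.25, 0.15), function(r) {
  acq <- acquisition_spec(nx = 300, ny = 300, n_frames = 300,
                          noise = "none", seed = 350L)
  model <- if (is.finite(r))
    motion_model("confined", D = 0.02, corral_radius = r)
  else motion_model("brownian", D = 0.02)
  ts <- simulate_tracks(model, acq, 80, start = "center")
  dyn <- summarize_dynamics(ts)
  data.frame(corral_radius_um = r, median_D_hat = dyn$ensemble$D_um2_per_s,
             median_d_max_um = dyn$ensemble$d_max_um)
})
series <- do.call(rbind, series)
write.table(series, "results/confinement_series.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(series, digits = 3)

cat("\nApparent D falls monotonically with confinement: the anchoring",
    "signature.\nMann-Whitney on per-cell medians is the intended group",
    "comparison (see compare_groups).\n")
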