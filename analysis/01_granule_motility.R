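#!/usr/bin/env Rscript
# Directed transport of RNP granules in neurons: simulate per-isoform
# velocity/distance summaries and recover them with the track statistics.
# Writes results/motility_summary.tsv.

suppressPackageStartupMessages(library(rnptrack))
dir.create("results", showWarnings = FALSE)
seed <- 101L

isoforms <- data.frame(
  label = c("MBNL1-40kDa", "MBNL1-41kDa", "MBNL2-iso1"),
  mean_velocity = c(0.84, 1.10, 1.21),
  sem_velocity = c(0.08, 0.08, 0.09),
  n_tracks = c(36, 71, 50))

rows <- lapply(seq_len(nrow(isoforms)), function(i) {
  iso <- isoforms[i, ]
  acq <- acquisition_spec(nx = 256, ny = 256, n_frames = 100,
                          noise = "none", seed = seed + i)
  model <- motion_model("directed", v = iso$mean_velocity,
                        v_sd = iso$sem_velocity * sqrt(iso$n_tracks))
  ts <- simulate_tracks(model, acq, iso$n_tracks)
  v <- vapply(split(ts$tracks, ts$tracks$track_id), track_velocity,
              numeric(1), frame_interval = 0.1)
  d <- vapply(split(ts$tracks, ts$tracks$track_id), max_distance, numeric(1))
  data.frame(isoform = iso$label, n_tracks = iso$n_tracks,
             generative_velocity = iso$mean_velocity,
             recovered_mean_velocity = mean(v),
             recovered_sem_velocity = sd(v) / sqrt(length(v)),
             recovered_mean_distance = mean(d))
})
out <- do.call(rbind, rows)
write.table(out, "results/motility_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Directed-transport recovery (velocities in um/s):\n")
print(out, digits = 3)
cat("\nEach recovered mean velocity should sit within ~2 SEM of its",
    "generative value;\nspeeds are in the microtubule-transport regime",
    "(~1 um/s).\n")
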