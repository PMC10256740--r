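#!/usr/bin/env Rscript
# Centrosome recruitment assay: score synthetic cells constructed at the
# enrichment levels reported for each kinesin-tail / zinc-finger pairing,
# with per-group box statistics and pairwise Mann-Whitney tests.
# Writes results/recruitment_scores.tsv and results/recruitment_groups.tsv.

suppressPackageStartupMessages(library(rnptrack))
dir.create("results", showWarnings = FALSE)

# Reported log2 mean centrosome enrichments used as generative values:
# Kif1b-alpha 0.506, Kif1c 0.560, Kif1b-beta 0.149 (selectivity), and the
# mutant series with Kif1c: wild-type 0.497/0.556, delta-unstructured
# 0.724, chelation mutant 0.356.
groups <- list(
  "Kif1b-alpha" = 0.506, "Kif1c" = 0.560, "Kif1b-beta" = 0.149,
  "MBNL1-41-RIM" = 0.556, "MBNL1-41" = 0.497,
  "MBNL1-d3dC-RIM" = 0.724, "MBNL1-41-CM" = 0.356)

set.seed(50)
scores <- do.call(rbind, lapply(names(groups), function(g) {
  # per-cell scatter around the group mean, scored on noisy renderings
  cells <- vapply(1:30, function(i) {
    e <- rnorm(1, groups[[g]], 0.15)
    sc <- synthetic_cell(e, noise = "gaussian", noise_sd = 1,
                         seed = sample.int(2^30, 1))
    centrosome_enrichment(sc$image, sc$cell_mask, sc$centrosome_mask)
  }, numeric(1))
  data.frame(group = g, cell = seq_along(cells), score = cells)
}))
write.table(scores, "results/recruitment_scores.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

res <- enrichment_experiment(scores$score, scores$group)
write.table(res$summary, "results/recruitment_groups.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(res$summary, digits = 3)
sel <- res$pairwise[res$pairwise$group1 %in% c("Kif1b-alpha", "Kif1c") &
                    res$pairwise$group2 == "Kif1b-beta" |
                    res$pairwise$group2 %in% c("Kif1b-alpha", "Kif1c") &
                    res$pairwise$group1 == "Kif1b-beta", ]
print(sel, digits = 3)
cat("\nThe alpha/c tails recruit ~0.5 log2 units versus ~0.15 for the beta",
    "tail;\nnoise-free construction round-trips scores to machine",
    "precision (see tests).\n")

# Masked colocalization on a synthetic two-channel cell
sc <- synthetic_cell(0.5)
ch2 <- sc$image * 0.8 + matrix(rnorm(length(sc$image), 0, 2),
                               nrow(sc$image))
cat(sprintf("Pearson r within the cell mask (correlated channels): %.3f\n",
            pearson_in_mask(sc$image, ch2, sc$cell_mask)))
m <- manders_in_mask(sc$image, ch2, sc$cell_mask, t1 = 0, t2 = 0)
cat(sprintf("Manders M1 = %.3f, M2 = %.3f\n", m["M1"], m["M2"]))
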