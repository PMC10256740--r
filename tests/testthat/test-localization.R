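# Normalization, localization ratios, CLIP-density binning, overlaps,
# FISH distances, qPCR enrichment, isoform fractions.

test_that("cyclic loess leaves identical samples untouched and removes scale offsets", {
  set.seed(1)
  base <- rpois(400, 200)
  m <- cbind(s1 = base, s2 = base)
  n <- normalize_cyclic_loess(m)
  expect_equal(n[, 1], log2(base + 0.5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(n[, 1], n[, 2], ignore_attr = TRUE)
  m2 <- cbind(s1 = base, s2 = 2L * base)
  n2 <- normalize_cyclic_loess(m2)
  M <- n2[, 2] - n2[, 1]
  expect_lt(abs(median(M)), 0.05)
  # per-gene average expression is preserved by the symmetric adjustment
  A_pre <- rowMeans(log2(m2 + 0.5))
  expect_equal(rowMeans(n2), A_pre, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(normalize_cyclic_loess(m[, 1, drop = FALSE]), "2 samples")
})

test_that("localization ratios are exact for constructed counts", {
  genes <- paste0("g", 1:3)
  normed <- matrix(c(3, 3, 3,   3, 3, 3,    # ctrl soma / neurite equal
                     3, 3, 3,   5, 3, 3),   # pert: g1 neurite 4x soma
                   nrow = 3,
                   dimnames = list(genes, c("c_s", "c_n", "p_s", "p_n")))
  meta <- data.frame(sample = c("c_s", "c_n", "p_s", "p_n"),
                     compartment = c("soma", "neurite", "soma", "neurite"),
                     condition = c("ctrl", "ctrl", "pert", "pert"))
  lt <- localization_ratio(normed, meta, expression_filter = 0)
  expect_equal(lt$L_ctrl, c(0, 0, 0))
  expect_equal(lt$L_pert, c(2, 0, 0))
  expect_equal(lt$dL_pert, c(2, 0, 0))
  # control versus itself is identically zero
  lt2 <- localization_ratio(normed[, 1:2], meta[1:2, ], control = "ctrl",
                            expression_filter = 0)
  expect_equal(lt2$L_ctrl, c(0, 0, 0))
  expect_error(localization_ratio(normed, meta[-2, ]), "no neurite sample")
})

test_that("expression filter drops genes weak in any compartment", {
  normed <- matrix(c(5, 0.2, 5, 5, 5, 0.2, 5, 5), nrow = 2,
                   dimnames = list(c("hi", "lo"),
                                   c("c_s", "c_n", "p_s", "p_n")))
  meta <- data.frame(sample = colnames(normed),
                     compartment = c("soma", "neurite", "soma", "neurite"),
                     condition = c("c", "c", "p", "p"))
  lt <- localization_ratio(normed, meta)
  expect_true(lt$pass_filter[lt$gene == "hi"])
  expect_false(lt$pass_filter[lt$gene == "lo"])
})

test_that("a null fractionation simulation yields flat bins and a -0.5 shift is recovered", {
  null_spec <- count_table_spec(n_genes = 1500, seed = 8, effect_size = 0)
  sim <- simulate_fractionation_counts(null_spec)
  lt <- localization_ratio(normalize_cyclic_loess(sim$counts), sim$metadata)
  cs <- clip_density_shift(lt, sim$annotation, seed = 1)
  expect_true(all(abs(cs$median_dL) < 0.12))
  expect_true(all(cs$p_vs_zero[-1] > 0.005))
  eff <- count_table_spec(n_genes = 2000, seed = 8, effect_size = -0.5)
  sim2 <- simulate_fractionation_counts(eff)
  lt2 <- localization_ratio(normalize_cyclic_loess(sim2$counts), sim2$metadata)
  q <- quantile(sim2$annotation$tags_per_kb[sim2$annotation$tags_per_kb > 0],
                c(0.5, 0.75), type = 7)
  cs2 <- clip_density_shift(lt2, sim2$annotation, bin_edges = unname(q),
                            seed = 1)
  top <- cs2[nrow(cs2), ]
  expect_lt(top$median_dL, -0.3)
  expect_lt(top$p_vs_zero, 0.005)
  expect_equal(cs2$p_vs_zero[1], 1)  # reference bin against itself
})

test_that("mislocalized gene sets respect the threshold sign convention", {
  tab <- structure(data.frame(gene = c("a", "b", "c", "d"),
                              L_c = 0, L_p = c(-0.3, 0.3, -0.2, -0.5),
                              pass_filter = c(TRUE, TRUE, TRUE, FALSE),
                              dL_p = c(-0.3, 0.3, -0.2, -0.5)),
                   control = "c", conditions = c("c", "p"),
                   class = c("localization_table", "data.frame"))
  expect_equal(as.character(mislocalized_set(tab, 0.25)), "a")
  expect_setequal(as.character(mislocalized_set(tab, 0)),
                  c("a", "c"))  # threshold 0: all negative shifts
})

test_that("overlap enrichment reproduces closed-form folds and enumeration p-values", {
  A <- paste0("g", 1:100)
  B <- c(paste0("g", 1:26), paste0("x", 1:74))
  res <- overlap_enrichment(A, B, universe_size = 1000)
  expect_equal(res$fold, 2.6)
  res2 <- overlap_enrichment(paste0("g", 1:100),
                             c(paste0("g", 1:10), paste0("y", 1:90)), 1000)
  expect_equal(res2$fold, 1.0)
  # enumeration oracle on a 30-gene universe
  for (ov in c(2, 4, 6)) {
    a <- paste0("u", 1:8)
    b <- c(paste0("u", 1:ov), paste0("v", 1:(10 - ov)))
    got <- overlap_enrichment(a, b, 30)
    expect_equal(got$p, fisher_enum_p(ov, 8, 10, 30), tolerance = 1e-9)
  }
  expect_error(overlap_enrichment(character(0), A, 1000), "zero expected")
})

test_that("random independent sets have unit expected overlap fold", {
  set.seed(31)
  genes <- paste0("g", 1:400)
  folds <- replicate(300, {
    overlap_enrichment(sample(genes, 60), sample(genes, 60), 400)$fold
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("spot distances project onto neurites with exact endpoint behaviour", {
  geom <- neurite_geometry(c(0, 0), list(rbind(c(0, 0), c(100, 0))))
  spots <- data.frame(x_um = c(100, 0, 50, 30), y_um = c(0, 0, 1, -80))
  d <- spot_neurite_distance(spots, geom)
  expect_equal(d$fraction[1:3], c(1, 0, 0.5))
  expect_true(is.na(d$fraction[4]))  # unassignable spot flagged
  # monotone in arclength along a fixed neurite
  s2 <- data.frame(x_um = seq(5, 95, by = 10), y_um = 0.2)
  expect_true(all(diff(spot_neurite_distance(s2, geom)$fraction) > 0))
})

test_that("multi-neurite assignment picks the nearest polyline and bounds fractions", {
  geom <- neurite_geometry(c(0, 0), list(rbind(c(0, 0), c(50, 0)),
                                         rbind(c(0, 0), c(0, 120))))
  sp <- simulate_neurite_field(geom, 500, seed = 4, jitter_sd = 0.3)
  d <- spot_neurite_distance(sp, geom)
  ok <- !is.na(d$fraction)
  expect_gt(mean(ok), 0.95)
  expect_true(all(d$fraction[ok] >= 0 & d$fraction[ok] <= 1))
  expect_equal(d$neurite_id[ok], sp$neurite_id[ok])
  expect_equal(d$fraction[ok], sp$true_fraction[ok], tolerance = 0.05)
})

test_that("per-cell 95th percentiles follow order statistics and the spot filter", {
  same <- data.frame(cell_id = 1, fraction = rep(0.3, 200))
  expect_equal(cell_p95(same)$p95, 0.3)
  unif <- data.frame(cell_id = 1, fraction = runif(1e4))
  set.seed(6)
  expect_equal(cell_p95(unif)$p95, 0.95, tolerance = 0.011)
  mixed <- data.frame(cell_id = rep(c(1, 2), c(100, 200)),
                      fraction = runif(300))
  res <- cell_p95(mixed, min_spots = 150)
  expect_equal(res$cell_id, 2)  # 100-spot cell excluded
  expect_error(cell_p95(mixed, min_spots = 500), "min_spots")
})

test_that("depletion of distal spots lowers the per-cell 95th percentile", {
  geom <- neurite_geometry(c(0, 0), list(rbind(c(0, 0), c(100, 0))))
  p95s <- vapply(c(1, 2, 4), function(s2) {
    sp <- simulate_neurite_field(geom, 400,
                                 list(kind = "beta", shape1 = 1, shape2 = s2),
                                 seed = 20)
    d <- spot_neurite_distance(sp, geom)
    cell_p95(data.frame(cell_id = 1, fraction = d$fraction))$p95
  }, numeric(1))
  expect_true(all(diff(p95s) < 0))
})

test_that("centrosomal RNA fractions count spots inside nested masks", {
  cell <- disc_mask(60, 60, c(30, 30), 25)
  cent <- disc_mask(60, 60, c(40, 30), 4)
  inside <- data.frame(x_um = c(4.0, 4.1), y_um = c(3.0, 3.0))
  expect_equal(centrosomal_rna_fraction(inside, cent, cell, 0.1), 1)
  outside <- data.frame(x_um = c(2.0, 2.1), y_um = c(3.0, 3.0))
  expect_equal(centrosomal_rna_fraction(outside, cent, cell, 0.1), 0)
  mix <- data.frame(x_um = c(rep(4.0, 20), rep(2.0, 80)),
                    y_um = rep(3.0, 100))
  expect_equal(centrosomal_rna_fraction(mix, cent, cell, 0.1), 0.2)
  far <- data.frame(x_um = 0.1, y_um = 0.1)
  expect_error(centrosomal_rna_fraction(far, cent, cell, 0.1), "no spots")
})

test_that("qPCR round trip recovers a 1.6-fold membrane association within 10%", {
  exact <- qpcr_membrane_enrichment(simulate_qpcr(1.6, 0, 5))
  expect_equal(exact$fold, 1.6, tolerance = 1e-12)
  expect_equal(exact$percent_greater, 60, tolerance = 1e-9)
  noisy <- qpcr_membrane_enrichment(simulate_qpcr(1.6, 0.1, 5, seed = 2))
  expect_equal(noisy$fold, 1.6, tolerance = 0.1)
  bad <- simulate_qpcr(1.6, 0, 2)
  expect_error(qpcr_membrane_enrichment(bad[-1, ]), "exactly one Ct")
})

test_that("isoform fractions are exact and vectorized", {
  expect_equal(isoform_fraction(3, 1), 0.75)
  expect_equal(isoform_fraction(0, 5), 0)
  expect_equal(isoform_fraction(c(2, 1), c(2, 3)), c(0.5, 0.25))
  expect_error(isoform_fraction(0, 0), "> 0")
})
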