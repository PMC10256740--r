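# Synthetic two-compartment (soma/neurite) count tables with a
# CLIP-density-dependent localization shift, and synthetic qPCR Ct tables.

#' Specification for a synthetic fractionation count table
#'
#' Negative-binomial counts with a shared dispersion (the simplest model
#' consistent with RNA-seq overdispersion) for soma and neurite samples.
#' Each gene carries a baseline log2(neurite/soma) ratio drawn from
#' N(0, `baseline_ratio_sd`) and a CLIP tag density (tags per kb of UTR)
#' drawn from a zero-inflated gamma; in perturbed conditions, genes whose
#' density exceeds `effect_threshold` have their neurite abundance shifted
#' by `effect_size` log2 units, emulating the loss of RBP-dependent
#' transport for strongly bound transcripts.
#'
#' @param n_genes number of genes.
#' @param library_size expected total counts per sample.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param clip_density_distribution list: `p_zero` (fraction of genes with
#'   no tags), `shape`, `rate` of the gamma draw for the rest.
#' @param baseline_ratio_sd SD of the per-gene baseline log2(neurite/soma).
#' @param effect_size log2 shift of neurite abundance applied to
#'   high-density genes in perturbed conditions (negative = shift toward
#'   soma).
#' @param effect_threshold tags/kb above which the effect applies; `NULL`
#'   uses the upper quartile of the drawn densities.
#' @param seed RNG seed.
#' @return an object of class `count_table_spec`.
#' @export
count_table_spec <- function(n_genes = 2000, library_size = 5e5,
                             dispersion = 0.05,
                             clip_density_distribution =
                               list(p_zero = 0.4, shape = 1.2, rate = 0.4),
                             baseline_ratio_sd = 0.5, effect_size = -0.5,
                             effect_threshold = NULL, seed = NULL) {
  stop_arg(n_genes >= 1, "n_genes must be > 0")
  stop_arg(library_size > 0, "library_size must be > 0")
  stop_arg(dispersion > 0, "dispersion must be > 0")
  cd <- clip_density_distribution
  stop_arg(is.list(cd) && all(c("p_zero", "shape", "rate") %in% names(cd)),
           "clip_density_distribution needs p_zero, shape, rate")
  stop_arg(cd$p_zero >= 0 && cd$p_zero < 1, "p_zero must be in [0, 1)")
  stop_arg(baseline_ratio_sd >= 0, "baseline_ratio_sd must be >= 0")
  structure(list(n_genes = as.integer(n_genes), library_size = library_size,
                 dispersion = dispersion, clip_density_distribution = cd,
                 baseline_ratio_sd = baseline_ratio_sd,
                 effect_size = effect_size,
                 effect_threshold = effect_threshold, seed = seed),
            class = "count_table_spec")
}

#' Simulate a soma/neurite fractionation count table
#'
#' One soma and one neurite sample per condition (single biological
#' replicate, as in membrane-based neurite fractionation experiments); the
#' first condition is the control and receives no effect.
#'
#' @param spec a [count_table_spec()].
#' @param conditions character vector of condition names (>= 2; first is
#'   control).
#' @return list with `counts` (genes x samples), `metadata` (sample,
#'   compartment, condition), `annotation` (gene, tags_per_kb), and `truth`
#'   (per-gene baseline ratio, affected flag, true shift per condition).
#' @export
simulate_fractionation_counts <- function(spec,
                                          conditions = c("control", "perturbed")) {
  stopifnot(inherits(spec, "count_table_spec"))
  stop_arg(length(conditions) >= 2, "need >= 2 conditions (first is control)")
  with_seed(spec$seed, {
    ng <- spec$n_genes
    genes <- sprintf("gene%05d", seq_len(ng))
    cd <- spec$clip_density_distribution
    tags <- ifelse(stats::runif(ng) < cd$p_zero, 0,
                   stats::rgamma(ng, shape = cd$shape, rate = cd$rate))
    thr <- spec$effect_threshold
    if (is.null(thr)) thr <- quantile7(tags, 0.75)
    affected <- tags > thr
    # base expression profile (relative abundances)
    base <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
    L0 <- stats::rnorm(ng, 0, spec$baseline_ratio_sd)
    samples <- expand.grid(compartment = c("soma", "neurite"),
                           condition = conditions,
                           stringsAsFactors = FALSE)
    samples$sample <- paste(samples$condition, samples$compartment, sep = "_")
    counts <- matrix(0L, ng, nrow(samples),
                     dimnames = list(genes, samples$sample))
    # sequencing depth is set from the control composition per compartment,
    # so unaffected genes keep identical expected counts across conditions;
    # the perturbation then changes the perturbed sample's total slightly,
    # which is the normalization step's job to absorb.
    scale_soma <- spec$library_size / sum(base)
    scale_neur <- spec$library_size / sum(base * 2^L0)
    for (j in seq_len(nrow(samples))) {
      shift <- if (samples$condition[j] != conditions[1] &&
                   samples$compartment[j] == "neurite")
        ifelse(affected, spec$effect_size, 0) else 0
      mu <- if (samples$compartment[j] == "soma") base * scale_soma
            else base * 2^(L0 + shift) * scale_neur
      counts[, j] <- stats::rnbinom(ng, size = 1 / spec$dispersion, mu = mu)
    }
    truth <- data.frame(gene = genes, tags_per_kb = tags,
                        baseline_log2_ratio = L0, affected = affected,
                        effect_size = spec$effect_size,
                        effect_threshold = thr)
    list(counts = counts,
         metadata = samples[, c("sample", "compartment", "condition")],
         annotation = data.frame(gene = genes, tags_per_kb = tags),
         truth = truth)
  })
}

#' Simulate a qPCR Ct table for membrane/cytosol fractionation
#'
#' Generates threshold cycles for a target and a reference gene in membrane
#' and cytosol fractions such that the expected delta-delta-Ct equals
#' -log2(`true_ratio`), i.e. 2^-ddCt recovers `true_ratio` (the relative
#' membrane association of the target versus the reference).
#'
#' @param true_ratio generative membrane-association fold (> 0).
#' @param ct_noise_sd SD of Gaussian Ct noise, cycles.
#' @param n_replicates number of replicates (>= 1).
#' @param seed RNG seed.
#' @return data.frame `gene` (target/reference), `fraction`
#'   (membrane/cytosol), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(true_ratio, ct_noise_sd = 0, n_replicates = 3,
                          seed = NULL) {
  stop_arg(true_ratio > 0, "true_ratio must be > 0")
  stop_arg(n_replicates >= 1, "n_replicates must be >= 1")
  base_ct <- c(target_cytosol = 24, reference_cytosol = 18,
               reference_membrane = 19)
  target_membrane <- base_ct["target_cytosol"] +
    (base_ct["reference_membrane"] - base_ct["reference_cytosol"]) -
    log2(true_ratio)
  grid <- expand.grid(gene = c("target", "reference"),
                      fraction = c("membrane", "cytosol"),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$gene == "target" & grid$fraction == "membrane",
               target_membrane,
        ifelse(grid$gene == "target", base_ct["target_cytosol"],
        ifelse(grid$fraction == "membrane", base_ct["reference_membrane"],
               base_ct["reference_cytosol"])))
  with_seed(seed, {
    grid$ct <- mu + stats::rnorm(nrow(grid), 0, ct_noise_sd)
    grid
  })
}
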