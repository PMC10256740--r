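# Neurite/soma localization statistics: cyclic-loess normalization,
# log2(neurite/soma) ratios and their shifts between conditions,
# CLIP-density binning, gene-set overlap enrichment, FISH spot distances,
# centrosomal RNA fractions, qPCR membrane enrichment, isoform fractions.

#' Cyclic loess normalization of a count matrix
#'
#' log2(count + pseudocount) per sample followed by pairwise cyclic loess
#' (for each sample pair a loess curve of M versus A is fitted and half the
#' fitted M is subtracted/added symmetrically, cycled over all pairs),
#' delegated to \code{limma::normalizeCyclicLoess(method = "pairs")}.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param span loess span.
#' @param iterations number of cycles over all sample pairs.
#' @param pseudocount added before the log transform.
#' @return normalized log2 expression matrix, same dimnames as `counts`.
#' @export
normalize_cyclic_loess <- function(counts, span = 0.7, iterations = 3,
                                   pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stop_arg(ncol(counts) >= 2, "cyclic loess needs >= 2 samples")
  stop_arg(all(counts >= 0), "counts must be non-negative")
  lg <- log2(counts + pseudocount)
  out <- limma::normalizeCyclicLoess(lg, span = span, iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(counts)
  out
}

#' Per-gene localization ratios and shifts between conditions
#'
#' For each condition, L = (mean normalized log2 expression over neurite
#' samples) - (mean over soma samples); delta-L is the change of L in each
#' non-control condition relative to the control. An expression filter is
#' applied first: a gene passes if its mean normalized log2 expression
#' exceeds `expression_filter` in both compartments of every condition.
#'
#' @param normed normalized log2 expression matrix (genes x samples).
#' @param metadata data.frame with columns `sample`, `compartment`
#'   (soma/neurite), `condition`; every condition needs both compartments.
#' @param control control condition name (default: first in `metadata`).
#' @param expression_filter log2 expression threshold (default 1).
#' @return a `localization_table` data.frame: `gene`, `pass_filter`, one
#'   `L_<condition>` column per condition and one `dL_<condition>` per
#'   non-control condition; attributes `control` and `conditions`.
#' @export
localization_ratio <- function(normed, metadata, control = NULL,
                               expression_filter = 1) {
  normed <- as.matrix(normed)
  need <- c("sample", "compartment", "condition")
  miss <- setdiff(need, names(metadata))
  stop_arg(length(miss) == 0,
           paste("metadata missing column(s):", paste(miss, collapse = ", ")))
  stop_arg(all(metadata$sample %in% colnames(normed)),
           "metadata samples absent from the expression matrix")
  conds <- unique(metadata$condition)
  if (is.null(control)) control <- conds[1]
  stop_arg(control %in% conds, "control condition not present")
  mean_expr <- function(cond, comp) {
    s <- metadata$sample[metadata$condition == cond &
                         metadata$compartment == comp]
    if (length(s) == 0)
      stop(sprintf("condition '%s' has no %s sample", cond, comp),
           call. = FALSE)
    rowMeans(normed[, s, drop = FALSE])
  }
  out <- data.frame(gene = rownames(normed))
  pass <- rep(TRUE, nrow(normed))
  for (cond in conds) {
    ne <- mean_expr(cond, "neurite")
    so <- mean_expr(cond, "soma")
    out[[paste0("L_", cond)]] <- ne - so
    pass <- pass & ne > expression_filter & so > expression_filter
  }
  out$pass_filter <- pass
  for (cond in setdiff(conds, control))
    out[[paste0("dL_", cond)]] <- out[[paste0("L_", cond)]] -
      out[[paste0("L_", control)]]
  structure(out, control = control, conditions = conds,
            class = c("localization_table", "data.frame"))
}

#' Localization shift as a function of CLIP tag density
#'
#' Genes (passing the expression filter) are binned by CLIP tags per kb of
#' UTR; per bin the median delta-L, a bootstrap SEM of the median, and a
#' two-tailed Wilcoxon rank-sum p-value against the zero-density reference
#' bin are reported. Default bin edges place zero-density genes in the
#' reference bin and split the remaining genes at their median and upper
#' quartile.
#'
#' @param table a `localization_table` with a delta-L column.
#' @param annotation data.frame `gene`, `tags_per_kb`.
#' @param condition perturbed condition whose `dL_<condition>` column is
#'   analyzed; default: the first non-control condition.
#' @param bin_edges increasing numeric vector of internal edges for the
#'   positive-density bins; `NULL` for the default (q50, q75 of positive
#'   densities).
#' @param n_boot bootstrap replicates for the SEM of the median.
#' @param seed RNG seed for the bootstrap.
#' @param center_on_reference report bin medians relative to the
#'   zero-density bin's median (default). Global normalization cannot
#'   distinguish a broad localization shift from a depth difference, so it
#'   redistributes part of any real shift onto unbound genes; the
#'   zero-density bin, which carries no binding-dependent effect, is the
#'   natural internal reference. The uncentered median is kept in
#'   `median_dL_raw`.
#' @return data.frame per bin: `bin`, `n`, `median_dL`, `median_dL_raw`,
#'   `sem`, `p_vs_zero`.
#' @export
clip_density_shift <- function(table, annotation, condition = NULL,
                               bin_edges = NULL, n_boot = 200, seed = NULL,
                               center_on_reference = TRUE) {
  stopifnot(inherits(table, "localization_table"))
  control <- attr(table, "control")
  conds <- attr(table, "conditions")
  if (is.null(condition)) condition <- setdiff(conds, control)[1]
  col <- paste0("dL_", condition)
  stop_arg(col %in% names(table), sprintf("no column '%s' in table", col))
  df <- merge(as.data.frame(table)[table$pass_filter, c("gene", col)],
              annotation, by = "gene")
  stop_arg(any(df$tags_per_kb == 0),
           "no zero-density genes to form the reference bin")
  pos <- df$tags_per_kb[df$tags_per_kb > 0]
  if (is.null(bin_edges))
    bin_edges <- unique(c(quantile7(pos, 0.5), quantile7(pos, 0.75)))
  stop_arg(all(diff(bin_edges) > 0) && all(bin_edges > 0),
           "bin_edges must be positive and increasing")
  lo <- c(0, bin_edges)
  hi <- c(bin_edges, Inf)
  pos_lab <- ifelse(is.finite(hi),
                    sprintf("(%s, %s]", format(lo, digits = 3),
                            format(hi, digits = 3)),
                    sprintf("> %s", format(lo, digits = 3)))
  lab <- c("0", pos_lab)
  # left-open intervals: (0, e1], (e1, e2], ..., (ek, Inf)
  pos_idx <- findInterval(df$tags_per_kb, bin_edges, left.open = TRUE) + 1L
  df$bin <- ifelse(df$tags_per_kb == 0, "0", pos_lab[pos_idx])
  ref <- df[[col]][df$bin == "0"]
  with_seed(seed, {
    out <- lapply(lab, function(b) {
      x <- df[[col]][df$bin == b]
      if (length(x) == 0) {
        warning(sprintf("empty CLIP-density bin '%s' excluded", b))
        return(NULL)
      }
      boot_med <- replicate(n_boot,
        stats::median(x[sample.int(length(x), replace = TRUE)]))
      p <- if (b == "0") 1
           else stats::wilcox.test(x, ref, exact = FALSE)$p.value
      data.frame(bin = b, n = length(x), median_dL_raw = stats::median(x),
                 sem = stats::sd(boot_med), p_vs_zero = p)
    })
    out <- do.call(rbind, out)
    ref_med <- out$median_dL_raw[out$bin == "0"]
    out$median_dL <- if (center_on_reference) out$median_dL_raw - ref_med
                     else out$median_dL_raw
    out[, c("bin", "n", "median_dL", "median_dL_raw", "sem", "p_vs_zero")]
  })
}

#' Genes mis-localized away from neurites
#'
#' Genes (passing the expression filter) whose localization shift delta-L
#' is at most `-delta_threshold`, i.e. shifted toward the soma in the
#' perturbed condition. The threshold is a reporting parameter: results
#' carry it as an attribute.
#'
#' @inheritParams clip_density_shift
#' @param delta_threshold minimum magnitude of the negative shift, log2
#'   units (default 0.25).
#' @return character vector of gene identifiers (attribute
#'   `delta_threshold`).
#' @export
mislocalized_set <- function(table, delta_threshold = 0.25, condition = NULL) {
  stopifnot(inherits(table, "localization_table"))
  control <- attr(table, "control")
  conds <- attr(table, "conditions")
  if (is.null(condition)) condition <- setdiff(conds, control)[1]
  col <- paste0("dL_", condition)
  stop_arg(col %in% names(table), sprintf("no column '%s' in table", col))
  sel <- table$pass_filter & table[[col]] <= -delta_threshold
  structure(table$gene[sel], delta_threshold = delta_threshold)
}

#' Enrichment of overlap between two gene sets
#'
#' Fold enrichment = observed overlap / expected overlap under independence
#' (|A||B|/N); the p-value is a two-tailed Fisher's exact test on the 2x2
#' membership table.
#'
#' @param setA,setB character vectors of gene identifiers.
#' @param universe_size number of genes in the universe (>= |A|, |B|).
#' @return list with `overlap`, `expected`, `fold`, `p`.
#' @export
overlap_enrichment <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  nA <- length(setA); nB <- length(setB)
  stop_arg(universe_size >= max(nA, nB), "universe smaller than a set")
  expected <- nA * nB / universe_size
  stop_arg(expected > 0, "zero expected overlap")
  ov <- length(intersect(setA, setB))
  tab <- matrix(c(ov, nA - ov, nB - ov, universe_size - nA - nB + ov), 2, 2)
  stop_arg(all(tab >= 0), "sets exceed the stated universe")
  list(overlap = ov, expected = expected, fold = ov / expected,
       p = stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Normalized spot distance along a neurite
#'
#' Each spot is projected onto the nearest point of its nearest neurite
#' polyline; the normalized distance is the arclength from the soma end of
#' that neurite to the projection, divided by that neurite's total length
#' (so values are bounded by 1 per neurite). Spots farther than
#' `max_assign_dist` from every neurite are flagged unassigned (NA
#' fraction) and should be excluded downstream.
#'
#' @param spots data.frame with `x_um`, `y_um` (other columns preserved).
#' @param geometry a [neurite_geometry()].
#' @param max_assign_dist maximum projection distance for assignment, um.
#' @return `spots` with added columns `neurite_id`, `fraction`,
#'   `assign_dist_um`.
#' @export
spot_neurite_distance <- function(spots, geometry, max_assign_dist = 2) {
  stopifnot(inherits(geometry, "neurite_geometry"))
  stop_arg(all(c("x_um", "y_um") %in% names(spots)),
           "spots need x_um and y_um columns")
  n <- nrow(spots)
  res <- t(vapply(seq_len(n), function(i) {
    best <- c(dist = Inf, neurite = NA_real_, arc = NA_real_)
    for (k in seq_along(geometry$neurites)) {
      pr <- project_to_polyline(c(spots$x_um[i], spots$y_um[i]),
                                geometry$neurites[[k]])
      if (pr["dist"] < best["dist"])
        best <- c(dist = pr[["dist"]], neurite = k, arc = pr[["arc"]])
    }
    best
  }, c(dist = 0, neurite = 0, arc = 0)))
  assigned <- res[, "dist"] <= max_assign_dist
  spots$neurite_id <- ifelse(assigned, res[, "neurite"], NA_integer_)
  spots$fraction <- ifelse(assigned,
                           res[, "arc"] / geometry$lengths[res[, "neurite"]],
                           NA_real_)
  spots$assign_dist_um <- res[, "dist"]
  spots
}

# Nearest point on a polyline: returns distance and arclength of projection.
project_to_polyline <- function(p, vertices) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  best_d <- Inf; best_arc <- 0
  for (i in seq_len(nrow(seg))) {
    a <- vertices[i, ]
    t <- sum((p - a) * seg[i, ]) / seg_len[i]^2
    t <- min(max(t, 0), 1)
    q <- a + t * seg[i, ]
    d <- sqrt(sum((p - q)^2))
    if (d < best_d) {
      best_d <- d
      best_arc <- cum[i] + t * seg_len[i]
    }
  }
  c(dist = best_d, arc = best_arc)
}

#' Per-cell 95th percentile of normalized spot distances
#'
#' Cells with fewer than `min_spots` assigned spots are excluded (the
#' spot-count filter used for distal-distance statistics); for the rest the
#' 95th percentile (linear interpolation) of the normalized distance is
#' returned. Group comparisons of the per-cell values use
#' [compare_groups()].
#'
#' @param distances data.frame with `cell_id` and `fraction` (NA = spot
#'   unassigned).
#' @param min_spots minimum assigned spots per cell (default 150).
#' @param probs percentile (default 0.95).
#' @return data.frame `cell_id`, `n_spots`, `p95`.
#' @export
cell_p95 <- function(distances, min_spots = 150, probs = 0.95) {
  stop_arg(all(c("cell_id", "fraction") %in% names(distances)),
           "distances need cell_id and fraction columns")
  d <- distances[!is.na(distances$fraction), , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, d$cell_id), function(g) {
    data.frame(cell_id = g$cell_id[1], n_spots = nrow(g),
               p95 = quantile7(g$fraction, probs))
  }))
  out <- out[out$n_spots >= min_spots, , drop = FALSE]
  if (nrow(out) == 0)
    stop(sprintf("no cell passes the min_spots filter (>= %d)", min_spots),
         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of RNA spots at the centrosome
#'
#' Count of spots falling inside the centrosome mask divided by the count
#' inside the whole-cell mask. Spot coordinates are mapped to the nearest
#' pixel.
#'
#' @param spots data.frame with `x_um`, `y_um`.
#' @param centrosome_mask,cell_mask binary masks (centrosome inside cell).
#' @param pixel_size um per pixel.
#' @return fraction in [0, 1].
#' @export
centrosomal_rna_fraction <- function(spots, centrosome_mask, cell_mask,
                                     pixel_size = 0.1) {
  m <- check_masks(cell_mask, centrosome_mask)
  col <- round(spots$x_um / pixel_size) + 1L
  row <- round(spots$y_um / pixel_size) + 1L
  inside <- col >= 1 & col <= ncol(cell_mask) & row >= 1 & row <= nrow(cell_mask)
  idx <- cbind(row[inside], col[inside])
  in_cell <- m$cell[idx]
  stop_arg(sum(in_cell) > 0, "no spots inside the cell mask")
  sum(m$centrosome[idx][in_cell]) / sum(in_cell)
}

#' Relative membrane association from a qPCR Ct table
#'
#' Standard 2^-ddCt quantification: per replicate,
#' ddCt = (Ct_target,membrane - Ct_reference,membrane) -
#' (Ct_target,cytosol - Ct_reference,cytosol); the fold membrane
#' association of the target relative to the (cytosolic) reference gene is
#' 2^-ddCt, averaged over replicates, also reported as percent difference
#' from parity.
#'
#' @param qpcr data.frame `gene` (target/reference), `fraction`
#'   (membrane/cytosol), `replicate`, `ct`; all four gene-by-fraction
#'   combinations must be present in every replicate.
#' @return list with `fold`, `percent_greater` (100 * (fold - 1)),
#'   `per_replicate`.
#' @export
qpcr_membrane_enrichment <- function(qpcr) {
  need <- c("gene", "fraction", "replicate", "ct")
  miss <- setdiff(need, names(qpcr))
  stop_arg(length(miss) == 0,
           paste("qPCR table missing column(s):", paste(miss, collapse = ", ")))
  per <- lapply(split(qpcr, qpcr$replicate), function(g) {
    ct <- function(gene, fraction) {
      v <- g$ct[g$gene == gene & g$fraction == fraction]
      if (length(v) != 1)
        stop(sprintf("replicate %s: need exactly one Ct for %s/%s",
                     g$replicate[1], gene, fraction), call. = FALSE)
      v
    }
    ddct <- (ct("target", "membrane") - ct("reference", "membrane")) -
            (ct("target", "cytosol") - ct("reference", "cytosol"))
    data.frame(replicate = g$replicate[1], ddct = ddct, fold = 2^-ddct)
  })
  per <- do.call(rbind, per)
  fold <- mean(per$fold)
  list(fold = fold, percent_greater = 100 * (fold - 1), per_replicate = per)
}

#' Isoform fraction
#'
#' Fraction of the alpha isoform among the summed expression of the alpha
#' and beta isoforms (e.g. TPMs). Vectorized.
#'
#' @param tpm_alpha,tpm_beta non-negative expression values.
#' @return `tpm_alpha / (tpm_alpha + tpm_beta)`.
#' @export
isoform_fraction <- function(tpm_alpha, tpm_beta) {
  stop_arg(all(tpm_alpha >= 0) && all(tpm_beta >= 0),
           "expression values must be non-negative")
  total <- tpm_alpha + tpm_beta
  stop_arg(all(total > 0), "total isoform expression must be > 0")
  tpm_alpha / total
}
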