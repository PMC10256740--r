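# Centrosome-recruitment scoring and masked colocalization coefficients.

check_masks <- function(cell_mask, centrosome_mask = NULL) {
  stop_arg(is.matrix(cell_mask) || length(dim(cell_mask)) == 3,
           "cell mask must be a matrix or 3-D array")
  cm <- cell_mask != 0
  stop_arg(any(cm), "cell mask is empty")
  if (!is.null(centrosome_mask)) {
    stop_arg(all(dim(centrosome_mask) == dim(cell_mask)),
             "masks must have identical dimensions")
    sm <- centrosome_mask != 0
    stop_arg(any(sm), "centrosome mask is empty")
    stop_arg(all(cm[sm]),
             "centrosome mask contains pixels outside the cell mask")
    return(list(cell = cm, centrosome = sm))
  }
  list(cell = cm)
}

#' Centrosome enrichment score
#'
#' E = log2(mean intensity inside the centrosome mask / mean intensity over
#' the whole-cell mask). The whole-cell mask includes the centrosome pixels.
#' The score is invariant to multiplicative intensity scaling (exposure or
#' gain) but not to additive offsets; compute it on raw or
#' background-subtracted intensities consistently across groups.
#'
#' @param image intensity matrix (or 3-D array) of the reporter channel.
#' @param cell_mask binary mask of the whole cell (non-zero = inside).
#' @param centrosome_mask binary mask of the centrosome, a subset of the
#'   cell mask.
#' @return E, the log2 enrichment (unitless).
#' @export
centrosome_enrichment <- function(image, cell_mask, centrosome_mask) {
  stop_arg(all(dim(image) == dim(cell_mask)),
           "image and masks must have identical dimensions")
  m <- check_masks(cell_mask, centrosome_mask)
  mean_cell <- mean(image[m$cell])
  stop_arg(mean_cell > 0, "mean intensity over the cell mask must be > 0")
  log2(mean(image[m$centrosome]) / mean_cell)
}

#' Summarize an enrichment experiment across groups
#'
#' Per group: median, lower/upper quartiles and 10th/90th percentiles of the
#' enrichment scores (the box-and-whisker convention used for recruitment
#' assays; the natural reference line is E = 0, no enrichment), plus
#' pairwise two-tailed Mann-Whitney tests between all groups.
#'
#' @param scores numeric vector of per-cell enrichment scores.
#' @param group group label per score (>= 2 groups).
#' @return list with `summary` (per-group percentiles) and `pairwise`
#'   (group pair, U, p).
#' @export
enrichment_experiment <- function(scores, group) {
  stop_arg(length(scores) == length(group), "scores and group lengths differ")
  group <- as.character(group)
  gs <- split(scores, group)
  stop_arg(length(gs) >= 2, "need at least 2 groups")
  stop_arg(all(vapply(gs, length, 1L) > 0), "empty group")
  summary <- do.call(rbind, lapply(names(gs), function(g) {
    x <- gs[[g]]
    data.frame(group = g, n = length(x), median = stats::median(x),
               q25 = quantile7(x, 0.25), q75 = quantile7(x, 0.75),
               p10 = quantile7(x, 0.10), p90 = quantile7(x, 0.90))
  }))
  pairs <- utils::combn(names(gs), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    cmp <- compare_groups(gs[[pairs[1, k]]], gs[[pairs[2, k]]])
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               U = cmp$U, p = cmp$p, method = cmp$method)
  }))
  list(summary = summary, pairwise = pairwise, reference = 0)
}

#' Pearson correlation within a mask
#'
#' Pearson correlation of two channels over the masked pixels only, for 2-D
#' or 3-D arrays (e.g. a neurite mask restricting colocalization analysis
#' to the process).
#'
#' @param ch1,ch2 intensity arrays of identical dimension.
#' @param mask binary mask of the same dimension.
#' @return Pearson r.
#' @export
pearson_in_mask <- function(ch1, ch2, mask) {
  stop_arg(all(dim(ch1) == dim(ch2)) && all(dim(ch1) == dim(mask)),
           "channels and mask must have identical dimensions")
  sel <- mask != 0
  stop_arg(sum(sel) >= 2, "mask must contain at least 2 pixels")
  x <- ch1[sel]; y <- ch2[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined: zero variance within mask",
         call. = FALSE)
  stats::cor(x, y)
}

#' Manders overlap coefficients within a mask
#'
#' M1 is the fraction of channel-1 intensity (within the mask) lying over
#' pixels where channel 2 exceeds `t2`; M2 is the symmetric quantity for
#' channel 2 over channel-1-positive pixels. Thresholds default to 0.
#' Unlike Pearson's r, Manders coefficients are not symmetric in the
#' channels.
#'
#' @inheritParams pearson_in_mask
#' @param t1,t2 intensity thresholds (>= 0) defining "positive" pixels in
#'   channels 1 and 2.
#' @return named numeric: `M1`, `M2`, each in [0, 1].
#' @export
manders_in_mask <- function(ch1, ch2, mask, t1 = 0, t2 = 0) {
  stop_arg(all(dim(ch1) == dim(ch2)) && all(dim(ch1) == dim(mask)),
           "channels and mask must have identical dimensions")
  stop_arg(t1 >= 0 && t2 >= 0, "thresholds must be >= 0")
  sel <- mask != 0
  stop_arg(any(sel), "mask is empty")
  s1 <- sum(ch1[sel]); s2 <- sum(ch2[sel])
  stop_arg(s1 > 0 && s2 > 0,
           "zero total intensity within mask; Manders undefined")
  c(M1 = sum(ch1[sel & ch2 > t2]) / s1,
    M2 = sum(ch2[sel & ch1 > t1]) / s2)
}
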