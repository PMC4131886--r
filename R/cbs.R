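#' Maximal circular t-statistic split of an ordered signal
#'
#' Scans every circular split (i, j\] of the vector (the arc
#' \code{values[(i+1):j]} against its wrapped complement) and returns the
#' pair maximizing the two-sample t-like statistic with pooled variance.
#' A constant vector has no change point and returns T = 0.
#'
#' @param values ordered numeric vector (length >= 4).
#' @param min_width minimum number of values on each side of the split.
#' @return list with \code{i}, \code{j} (0-based split coordinates: the arc
#'   is \code{values[(i+1):j]}) and \code{T}.
#' @export
max_t_statistic <- function(values, min_width = 2L) {
  if (length(values) < 4) stop("need at least 4 values")
  cpp_max_t(as.numeric(values), as.integer(min_width))
}

#' Circular binary segmentation of an LRR vector
#'
#' Recursively finds the maximal circular split, assesses it by permuting
#' the values within the tested stretch (empirical p = (b+1)/(n_perm+1)),
#' accepts splits with p <= alpha and recurses into the resulting pieces.
#'
#' @param lrr ordered numeric vector (one chromosome).
#' @param alpha significance level for accepting a split.
#' @param n_perm number of within-stretch permutations.
#' @param min_width minimum probes on each side of a tested split.
#' @param seed optional RNG seed (set before permuting).
#' @param early_stop halt a permutation loop as soon as the exceedance
#'   count already forces p > alpha. The accept/reject decision is
#'   identical to the full loop; only downstream RNG state differs. Set
#'   FALSE for exactly reproducible permutation counts.
#' @return sorted integer vector of breakpoints: a value k means a change
#'   after the k-th probe (1-based).
#' @export
cbs_segment <- function(lrr, alpha = 0.01, n_perm = 1000L, min_width = 2L,
                        seed = NULL, early_stop = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (length(lrr) < 4) return(integer(0))
  cpp_cbs_segment(as.numeric(lrr), alpha, as.integer(n_perm),
                  as.integer(min_width), early_stop)
}

#' Segment classification thresholds
#'
#' Surrogates for the likelihood rule of segment-classification: a segment
#' is HOMDEL when its mean LRR is deeply negative, HETDEL when moderately
#' negative with the 0.5-centred BAF band empty, DUP when positive with the
#' 0.5 band empty (duplication heterozygote clusters sit at 1/3 and 2/3,
#' outside the (0.4, 0.6) mid-band). All configurable.
#'
#' @param homdel_lrr,hetdel_lrr,dup_lrr mean-LRR cutoffs.
#' @param hetdel_het_max,dup_het_max maximum fraction of segment BAF in the
#'   (0.4, 0.6) mid-band for the deletion / duplication rules. The defaults
#'   tolerate one or two stray heterozygous probes from breakpoint slop at
#'   typical segment sizes (10-40 probes) while remaining far below the
#'   ~0.36 mid-band fraction of a diploid segment.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(homdel_lrr = -2.0, hetdel_lrr = -0.3,
                                dup_lrr = 0.2, hetdel_het_max = 0.10,
                                dup_het_max = 0.15) {
  list(homdel_lrr = homdel_lrr, hetdel_lrr = hetdel_lrr, dup_lrr = dup_lrr,
       hetdel_het_max = hetdel_het_max, dup_het_max = dup_het_max)
}

#' Classify one segment from mean LRR and BAF distribution
#'
#' @param seg list or one-row data.frame with \code{mean_lrr} and
#'   \code{baf_mid_fraction} (fraction of segment BAF in (0.4, 0.6)).
#' @param thresholds [classify_thresholds()].
#' @return one of "HOMDEL", "HETDEL", "DUP", "NORMAL".
#' @export
classify_segment <- function(seg, thresholds = classify_thresholds()) {
  m <- seg$mean_lrr
  h <- seg$baf_mid_fraction
  if (m < thresholds$homdel_lrr) return("HOMDEL")
  if (m < thresholds$hetdel_lrr && h < thresholds$hetdel_het_max) return("HETDEL")
  if (m > thresholds$dup_lrr && h < thresholds$dup_het_max) return("DUP")
  "NORMAL"
}

# Internal: build the per-chromosome segment table from breakpoints.
segment_table <- function(pos, lrr, baf, breaks, chrom) {
  bounds <- c(0L, breaks, length(lrr))
  out <- lapply(seq_len(length(bounds) - 1L), function(k) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    data.frame(chrom = chrom, probe_from = idx[1], probe_to = idx[length(idx)],
               start = pos[idx[1]], end = pos[idx[length(idx)]],
               mean_lrr = mean(lrr[idx]), n_probes = length(idx),
               baf_het_fraction = mean(baf[idx] > 0.25 & baf[idx] < 0.75),
               baf_mid_fraction = mean(baf[idx] > 0.4 & baf[idx] < 0.6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' CBS-based CNV calling for one sample
#'
#' Per chromosome: segment the LRR vector, classify each segment from its
#' mean LRR and BAF distribution, merge adjacent segments of identical
#' class, and emit non-NORMAL segments as CNV calls. The call score is the
#' absolute mean LRR of the segment.
#'
#' @param signal one sample's signal data.frame.
#' @param map probe map (only used for probe order consistency checks).
#' @param alpha,n_perm,min_width,seed,early_stop passed to [cbs_segment()].
#' @param thresholds [classify_thresholds()].
#' @param sample_id id recorded in the output calls.
#' @return calls data.frame with \code{source = "CBS"}.
#' @export
cbs_call <- function(signal, map = NULL, alpha = 0.01, n_perm = 1000L,
                     min_width = 2L, thresholds = classify_thresholds(),
                     seed = NULL, early_stop = TRUE, sample_id = "sample") {
  if (!is.null(seed)) set.seed(seed)
  calls <- list()
  for (ch in unique(signal$chrom)) {
    idx <- which(signal$chrom == ch)
    if (length(idx) < 4) next
    idx <- idx[order(signal$pos[idx])]
    lrr <- signal$lrr[idx]
    breaks <- cbs_segment(lrr, alpha, n_perm, min_width,
                          early_stop = early_stop)
    segs <- segment_table(signal$pos[idx], lrr, signal$baf[idx], breaks, ch)
    segs$class <- vapply(seq_len(nrow(segs)), function(k)
      classify_segment(segs[k, ], thresholds), character(1))
    # merge adjacent same-class segments
    r <- rle(segs$class)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    for (g in which(r$values != "NORMAL")) {
      rows <- segs[lo[g]:hi[g], , drop = FALSE]
      np <- sum(rows$n_probes)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start = rows$start[1], end = rows$end[nrow(rows)],
        cn = CN_CLASSES[[r$values[g]]], n_probes = np,
        score = abs(sum(rows$mean_lrr * rows$n_probes) / np),
        source = "CBS", stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_calls())
  do.call(rbind, calls)
}
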