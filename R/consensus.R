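#' Quality-control configuration for consensus CNV filtering
#'
#' Thresholds of the CNV-level and sample-level quality-control ledger:
#' reciprocal-overlap fraction for caller agreement, minimum probe density,
#' minimum probe count and size for deletions and duplications,
#' maximum tolerated overlap with centromeric/telomeric regions, and the
#' per-sample call cap beyond which a sample is treated as an array failure.
#'
#' @param overlap_min minimum reciprocal-overlap fraction (of both calls).
#' @param density_min_bp maximum bp per probe inside a call (density rule
#'   \code{n_probes / length >= 1 / density_min_bp}).
#' @param del_min_probes,del_min_bp minimum probes / strict minimum length
#'   for deletion calls.
#' @param dup_min_probes,dup_min_bp same for duplication calls.
#' @param region_overlap_max maximum fraction of a call inside excluded
#'   (centromere/telomere) regions.
#' @param per_sample_max maximum surviving calls per sample.
#' @param common_freq CNVR frequency at or above which a region is flagged
#'   common.
#' @param n_perm permutations for the association test.
#' @param sig_threshold empirical p-value significance cutoff.
#' @return named list (class \code{filter_config}).
#' @export
filter_config <- function(overlap_min = 0.60, density_min_bp = 30000,
                          del_min_probes = 5L, del_min_bp = 5000,
                          dup_min_probes = 10L, dup_min_bp = 10000,
                          region_overlap_max = 0.50, per_sample_max = 100L,
                          common_freq = 0.05, n_perm = 5000L,
                          sig_threshold = 2e-4) {
  stopifnot(overlap_min > 0, overlap_min <= 1, density_min_bp > 0,
            del_min_probes > 0, dup_min_probes > 0, per_sample_max > 0)
  structure(list(overlap_min = overlap_min, density_min_bp = density_min_bp,
                 del_min_probes = del_min_probes, del_min_bp = del_min_bp,
                 dup_min_probes = dup_min_probes, dup_min_bp = dup_min_bp,
                 region_overlap_max = region_overlap_max,
                 per_sample_max = per_sample_max, common_freq = common_freq,
                 n_perm = n_perm, sig_threshold = sig_threshold),
            class = "filter_config")
}

#' Reciprocal overlap of two closed genomic intervals
#'
#' Overlap length is \code{max(0, min(ends) - max(starts) + 1)}; the two
#' fractions divide it by each interval's own length. Vectorized.
#'
#' @param a_chrom,a_start,a_end first interval(s).
#' @param b_chrom,b_start,b_end second interval(s).
#' @return data.frame \code{frac_a, frac_b, inter_start, inter_end}
#'   (intersection columns NA when the intervals do not overlap or lie on
#'   different chromosomes).
#' @export
reciprocal_overlap <- function(a_chrom, a_start, a_end,
                               b_chrom, b_start, b_end) {
  same <- a_chrom == b_chrom
  is <- pmax(a_start, b_start)
  ie <- pmin(a_end, b_end)
  ov <- ifelse(same, pmax(0, ie - is + 1), 0)
  data.frame(frac_a = ov / (a_end - a_start + 1),
             frac_b = ov / (b_end - b_start + 1),
             inter_start = ifelse(ov > 0, is, NA_integer_),
             inter_end = ifelse(ov > 0, ie, NA_integer_))
}

# Internal: count probes of map inside [start, end] on chrom (vectorized
# over calls).
count_probes <- function(map, chrom, start, end) {
  vapply(seq_along(chrom), function(i)
    sum(map$chrom == chrom[i] & map$pos >= start[i] & map$pos <= end[i]),
    integer(1))
}

#' Per-sample consensus of HMM and CBS call sets
#'
#' Two calls match when they come from the same sample and chromosome, have
#' the same direction (DEL vs DUP) and each is covered by their intersection
#' for at least \code{overlap_min} of its length. Matching is greedy
#' one-to-one by descending intersection length (ties by leftmost start).
#' The emitted consensus call is the intersection interval; its
#' copy-number class is taken from the HMM call and its probe count is
#' recounted within the intersection.
#'
#' @param hmm_calls,cbs_calls calls data.frames for the same sample set.
#' @param map probe map used to recount probes.
#' @param config [filter_config()].
#' @return list with \code{calls} (source = "CONSENSUS", plus
#'   \code{hmm_idx, cbs_idx} row indices of the paired calls) — the indices
#'   let [concordance_fraction()] report replication counts.
#' @export
consensus_calls <- function(hmm_calls, cbs_calls, map, config = filter_config()) {
  check_calls(hmm_calls); check_calls(cbs_calls)
  out <- list()
  if (nrow(hmm_calls) && nrow(cbs_calls)) {
    hmm_calls$dir <- cn_direction(hmm_calls$cn)
    cbs_calls$dir <- cn_direction(cbs_calls$cn)
    pairs <- list()
    for (i in seq_len(nrow(hmm_calls))) {
      h <- hmm_calls[i, ]
      cand <- which(cbs_calls$sample_id == h$sample_id &
                      cbs_calls$chrom == h$chrom & cbs_calls$dir == h$dir)
      if (!length(cand)) next
      ro <- reciprocal_overlap(h$chrom, h$start, h$end,
                               cbs_calls$chrom[cand], cbs_calls$start[cand],
                               cbs_calls$end[cand])
      ok <- ro$frac_a >= config$overlap_min & ro$frac_b >= config$overlap_min
      if (any(ok)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          hmm_idx = i, cbs_idx = cand[ok],
          inter_start = ro$inter_start[ok], inter_end = ro$inter_end[ok],
          ov = ro$inter_end[ok] - ro$inter_start[ok] + 1)
      }
    }
    if (length(pairs)) {
      pairs <- do.call(rbind, pairs)
      pairs <- pairs[order(-pairs$ov, pairs$inter_start), , drop = FALSE]
      used_h <- used_c <- logical(0)
      keep <- logical(nrow(pairs))
      taken_h <- rep(FALSE, nrow(hmm_calls))
      taken_c <- rep(FALSE, nrow(cbs_calls))
      for (k in seq_len(nrow(pairs))) {
        if (!taken_h[pairs$hmm_idx[k]] && !taken_c[pairs$cbs_idx[k]]) {
          keep[k] <- TRUE
          taken_h[pairs$hmm_idx[k]] <- TRUE
          taken_c[pairs$cbs_idx[k]] <- TRUE
        }
      }
      pairs <- pairs[keep, , drop = FALSE]
      if (nrow(pairs)) {
        h <- hmm_calls[pairs$hmm_idx, ]
        out <- data.frame(
          sample_id = h$sample_id, chrom = h$chrom,
          start = pairs$inter_start, end = pairs$inter_end, cn = h$cn,
          n_probes = count_probes(map, h$chrom, pairs$inter_start,
                                  pairs$inter_end),
          score = h$score, source = "CONSENSUS",
          hmm_idx = pairs$hmm_idx, cbs_idx = pairs$cbs_idx,
          stringsAsFactors = FALSE)
        out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
        rownames(out) <- NULL
        return(list(calls = out))
      }
    }
  }
  calls <- cbind(empty_calls(), hmm_idx = integer(0), cbs_idx = integer(0))
  list(calls = calls)
}

#' Fraction of CBS calls replicated by the HMM caller
#'
#' @param hmm_calls,cbs_calls the two call sets.
#' @param map probe map.
#' @param config [filter_config()].
#' @return list \code{fraction, n_replicated, n_total} (fraction NA when
#'   there are no CBS calls).
#' @export
concordance_fraction <- function(hmm_calls, cbs_calls, map,
                                 config = filter_config()) {
  cons <- consensus_calls(hmm_calls, cbs_calls, map, config)
  n_rep <- length(unique(cons$calls$cbs_idx))
  n_tot <- nrow(cbs_calls)
  list(fraction = if (n_tot) n_rep / n_tot else NA_real_,
       n_replicated = n_rep, n_total = n_tot)
}

# Internal: fraction of each call covered by a set of intervals (same
# chromosome, non-overlapping intervals assumed after merging).
region_cover_fraction <- function(calls, regions) {
  if (is.null(regions) || !nrow(regions)) return(rep(0, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    r <- regions[regions$chrom == calls$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(0)
    ov <- pmax(0, pmin(r$end, calls$end[i]) - pmax(r$start, calls$start[i]) + 1)
    sum(ov) / (calls$end[i] - calls$start[i] + 1)
  }, numeric(1))
}

#' Apply the CNV-level and sample-level quality filters
#'
#' Rejection rules, applied in order and each tagged in the ledger:
#' \code{sex_chrom} (call not on an autosome), \code{density} (fewer than
#' one probe per \code{density_min_bp}), \code{del_min} / \code{dup_min}
#' (probe count below the class minimum or length not strictly above the
#' class minimum), \code{region} (more than \code{region_overlap_max} of the
#' call inside excluded regions), and finally \code{per_sample_max}
#' (every call of a sample with more surviving calls than the cap).
#'
#' @param calls consensus calls.
#' @param map probe map.
#' @param excluded_regions data.frame \code{chrom, start, end} of
#'   centromere/telomere intervals (1-based closed; see [read_bed()]), or
#'   NULL for none.
#' @param config [filter_config()].
#' @return list \code{kept} (calls) and \code{rejected} (calls plus
#'   \code{reason}).
#' @export
apply_filters <- function(calls, map, excluded_regions = NULL,
                          config = filter_config()) {
  check_calls(calls)
  if (!nrow(calls))
    return(list(kept = calls, rejected = cbind(calls, reason = character(0))))
  len <- calls$end - calls$start + 1
  dir <- cn_direction(calls$cn)
  reason <- rep(NA_character_, nrow(calls))
  mark <- function(cond, tag) reason <<- ifelse(is.na(reason) & cond, tag, reason)
  mark(!is_autosome(calls$chrom), "sex_chrom")
  mark(calls$n_probes / len < 1 / config$density_min_bp, "density")
  mark(dir == "DEL" & (calls$n_probes < config$del_min_probes |
                         len <= config$del_min_bp), "del_min")
  mark(dir == "DUP" & (calls$n_probes < config$dup_min_probes |
                         len <= config$dup_min_bp), "dup_min")
  mark(region_cover_fraction(calls, excluded_regions) >
         config$region_overlap_max, "region")
  kept <- calls[is.na(reason), , drop = FALSE]
  rejected <- cbind(calls[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  per_sample <- table(kept$sample_id)
  bad <- names(per_sample)[per_sample > config$per_sample_max]
  if (length(bad)) {
    extra <- kept[kept$sample_id %in% bad, , drop = FALSE]
    rejected <- rbind(rejected, cbind(extra, reason = "per_sample_max"))
    kept <- kept[!(kept$sample_id %in% bad), , drop = FALSE]
  }
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
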