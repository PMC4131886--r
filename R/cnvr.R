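#' Merge CNV calls across samples into discrete CNVRs
#'
#' Any calls sharing at least one base (closed intervals; sharing a single
#' boundary base counts) are merged transitively into one copy number
#' variable region. A region's type is DEL or DUP when all member calls
#' agree in direction, COMPLEX otherwise.
#'
#' @param calls calls data.frame (across all samples).
#' @return data.frame \code{cnvr_id, chrom, start, end, n_calls, type} plus
#'   attribute \code{members}: named list mapping cnvr_id to member call row
#'   indices (into \code{calls}).
#' @export
merge_cnvrs <- function(calls) {
  check_calls(calls)
  if (!nrow(calls)) {
    out <- data.frame(cnvr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_calls = integer(), type = character(),
                      stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  dir <- cn_direction(calls$cn)
  rows <- list()
  members <- list()
  chroms <- unique(calls$chrom)
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)), chroms)]
  for (ch in chroms) {
    idx <- which(calls$chrom == ch)
    ir <- IRanges::IRanges(start = calls$start[idx], end = calls$end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    for (k in seq_along(red)) {
      mem <- idx[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == k]]
      dirs <- unique(dir[mem])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(red)[k], end = IRanges::end(red)[k],
        n_calls = length(mem),
        type = if (length(dirs) > 1) "COMPLEX" else dirs,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- mem
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(cnvr_id = sprintf("CNVR_%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  names(members) <- out$cnvr_id
  attr(out, "members") <- members
  out
}

#' Per-population CNVR carrier counts and frequencies
#'
#' An individual counts once per CNVR however many of their calls fall in
#' it; the frequency divides carriers by the population's total sample
#' count from the manifest.
#'
#' @param cnvrs output of [merge_cnvrs()].
#' @param calls the calls the CNVRs were built from (or any call set to
#'   tally; overlap with the CNVR interval is what counts).
#' @param manifest sample manifest (defines population sizes).
#' @param common_freq frequency at or above which \code{common} is TRUE
#'   (evaluated on the maximum per-population frequency).
#' @return cnvrs with added columns \code{n_carriers},
#'   \code{count_<pop>}, \code{freq_<pop>} per population, and
#'   \code{common}.
#' @export
cnvr_frequency <- function(cnvrs, calls, manifest, common_freq = 0.05) {
  check_calls(calls)
  if (nrow(calls) && !all(calls$sample_id %in% manifest$sample_id))
    stop("calls contain sample(s) not in the manifest")
  pops <- unique(manifest$population)
  pop_of <- manifest$population[match(calls$sample_id, manifest$sample_id)]
  n_pop <- table(manifest$population)
  carriers <- lapply(seq_len(nrow(cnvrs)), function(k) {
    ov <- calls$chrom == cnvrs$chrom[k] &
      calls$start <= cnvrs$end[k] & calls$end >= cnvrs$start[k]
    unique(data.frame(sample_id = calls$sample_id[ov],
                      population = pop_of[ov], stringsAsFactors = FALSE))
  })
  cnvrs$n_carriers <- vapply(carriers, nrow, integer(1))
  for (p in pops) {
    cnt <- vapply(carriers, function(cc) sum(cc$population == p), integer(1))
    cnvrs[[paste0("count_", p)]] <- cnt
    cnvrs[[paste0("freq_", p)]] <- cnt / as.integer(n_pop[[p]])
  }
  fcols <- paste0("freq_", pops)
  cnvrs$common <- apply(cnvrs[, fcols, drop = FALSE], 1, max) >= common_freq
  cnvrs
}

#' Drop CNVRs carried by a single individual
#'
#' @param cnvrs CNVR table with an \code{n_carriers} column (from
#'   [cnvr_frequency()]).
#' @return the multi-carrier subset (carrier count >= 2).
#' @export
singleton_filter <- function(cnvrs) {
  stopifnot("n_carriers" %in% names(cnvrs))
  cnvrs[cnvrs$n_carriers > 1, , drop = FALSE]
}

#' Genome-wide catalog summary
#'
#' Totals, deletion/duplication splits, per-genome call count statistics,
#' median sizes and genome coverage (union of CNVR bases over the summed
#' autosome lengths).
#'
#' @param calls filtered calls.
#' @param cnvrs CNVR table.
#' @param autosome_lengths named vector of autosome lengths in bp (the
#'   coverage denominator).
#' @param manifest sample manifest; samples with no calls count as zero in
#'   the per-genome statistics.
#' @return named list of summary statistics.
#' @export
summarize_catalog <- function(calls, cnvrs, autosome_lengths, manifest) {
  len <- if (nrow(calls)) calls$end - calls$start + 1 else numeric(0)
  dir <- cn_direction(calls$cn)
  per_genome <- table(factor(calls$sample_id, levels = manifest$sample_id))
  rlen <- if (nrow(cnvrs)) cnvrs$end - cnvrs$start + 1 else numeric(0)
  cov_bp <- sum(rlen[is_autosome(cnvrs$chrom)])
  denom <- sum(as.numeric(autosome_lengths))
  list(
    n_calls = nrow(calls),
    n_del = sum(dir == "DEL"), n_dup = sum(dir == "DUP"),
    n_cnvr = nrow(cnvrs),
    n_cnvr_del = sum(cnvrs$type == "DEL"),
    n_cnvr_dup = sum(cnvrs$type == "DUP"),
    n_cnvr_complex = sum(cnvrs$type == "COMPLEX"),
    calls_per_genome_median = as.numeric(median(per_genome)),
    calls_per_genome_mean = as.numeric(mean(per_genome)),
    call_size_median = if (length(len)) median(len) else 0,
    call_size_median_del = if (any(dir == "DEL")) median(len[dir == "DEL"]) else 0,
    call_size_median_dup = if (any(dir == "DUP")) median(len[dir == "DUP"]) else 0,
    cnvr_size_median = if (length(rlen)) median(rlen) else 0,
    genome_coverage_bp = cov_bp,
    genome_coverage_pct = 100 * cov_bp / denom
  )
}

#' Calls overlapping known syndrome regions of matched direction
#'
#' A call counts when it overlaps a syndrome region by at least one base
#' and the syndrome's documented direction (loss/gain) matches the call's.
#'
#' @param calls calls data.frame.
#' @param syndromes data.frame \code{chrom, start, end, direction} with
#'   direction in \{"DEL", "DUP"\}.
#' @return list \code{count, total, percent} (percent to 2 decimals).
#' @export
syndrome_overlap <- function(calls, syndromes) {
  check_calls(calls)
  n <- nrow(calls)
  if (!n || is.null(syndromes) || !nrow(syndromes))
    return(list(count = 0L, total = n,
                percent = if (n) 0 else NA_real_))
  dir <- cn_direction(calls$cn)
  hit <- vapply(seq_len(n), function(i) {
    s <- syndromes[syndromes$chrom == calls$chrom[i] &
                     syndromes$direction == dir[i], , drop = FALSE]
    any(s$start <= calls$end[i] & s$end >= calls$start[i])
  }, logical(1))
  list(count = sum(hit), total = n, percent = round(100 * sum(hit) / n, 2))
}

#' Genes overlapped by each CNVR
#'
#' @param cnvrs CNVR table.
#' @param genes data.frame \code{symbol, chrom, start, end}; malformed rows
#'   (missing fields or start > end) are skipped with a warning.
#' @return named list: cnvr_id -> character vector of gene symbols in
#'   positional order.
#' @export
gene_overlap <- function(cnvrs, genes) {
  bad <- is.na(genes$symbol) | is.na(genes$start) | is.na(genes$end) |
    genes$start > genes$end
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed gene row(s)")
    genes <- genes[!bad, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(cnvrs)), function(k) {
    g <- genes[genes$chrom == cnvrs$chrom[k] &
                 genes$start <= cnvrs$end[k] & genes$end >= cnvrs$start[k], ,
               drop = FALSE]
    g$symbol[order(g$start)]
  })
  names(out) <- cnvrs$cnvr_id
  out
}

#' Degree of match between two CNVR catalogs by frequency bin
#'
#' For each frequency bin of catalog A, the fraction of A's CNVRs that
#' overlap (>= 1 bp) any CNVR of catalog B.
#'
#' @param cnvrs_a CNVR table with a \code{freq} column (the focal
#'   population's frequency).
#' @param cnvrs_b CNVR table to match against.
#' @param bins increasing bin edges on the frequency axis; CNVRs at or
#'   below the first edge are excluded.
#' @return data.frame \code{bin, n, matched, fraction}.
#' @export
degree_of_match <- function(cnvrs_a, cnvrs_b,
                            bins = c(0.01, 0.05, 0.10, 0.20, 1.0)) {
  stopifnot("freq" %in% names(cnvrs_a))
  matched <- vapply(seq_len(nrow(cnvrs_a)), function(k) {
    b <- cnvrs_b[cnvrs_b$chrom == cnvrs_a$chrom[k], , drop = FALSE]
    any(b$start <= cnvrs_a$end[k] & b$end >= cnvrs_a$start[k])
  }, logical(1))
  bin <- cut(cnvrs_a$freq, breaks = bins)
  keep <- !is.na(bin)
  tab <- table(bin[keep])
  hit <- tapply(matched[keep], bin[keep], sum, default = 0L)
  data.frame(bin = names(tab), n = as.integer(tab),
             matched = as.integer(hit),
             fraction = ifelse(tab > 0, as.integer(hit) / as.integer(tab),
                               NA_real_),
             stringsAsFactors = FALSE)
}
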