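#' Infer genotypic sex from chromosome X BAF
#'
#' Females show a heterozygote BAF band near 0.5 on X; hemizygous males do
#' not. With fewer than 50 X probes the call is "unknown".
#'
#' @param x_baf numeric vector of BAF values at X probes.
#' @return one of "male", "female", "unknown".
#' @export
infer_sex <- function(x_baf) {
  x_baf <- x_baf[!is.na(x_baf)]
  if (length(x_baf) < 50) return("unknown")
  het <- mean(x_baf > 0.25 & x_baf < 0.75)
  if (het >= 0.10) "female" else if (het < 0.02) "male" else "unknown"
}

#' Sample-level quality control
#'
#' A sample fails if its autosomal LRR standard deviation exceeds
#' \code{lrr_sd_max} (strictly), its genotype call rate falls below
#' \code{call_rate_min} (strictly), or its X-inferred sex contradicts the
#' reported sex (when inferable). Failure reasons are recorded.
#'
#' @param signals named list of per-sample signal data.frames
#'   (\code{probe_id, chrom, pos, genotype, lrr, baf}).
#' @param manifest data.frame with \code{sample_id, population, reported_sex}.
#' @param lrr_sd_max maximum tolerated autosomal LRR SD (default 0.3).
#' @param call_rate_min minimum genotype call rate (default 0.98).
#' @return data.frame with one row per sample: \code{sample_id, lrr_sd,
#'   call_rate, inferred_sex, pass, reasons} (semicolon-joined).
#' @export
sample_qc <- function(signals, manifest, lrr_sd_max = 0.3, call_rate_min = 0.98) {
  miss <- setdiff(names(signals), manifest$sample_id)
  if (length(miss))
    stop("sample(s) missing from manifest: ", paste(miss, collapse = ", "))
  out <- lapply(names(signals), function(sid) {
    s <- signals[[sid]]
    auto <- is_autosome(s$chrom)
    if (sum(auto) < 2) stop("sample ", sid, " has fewer than 2 autosomal probes")
    lrr_sd <- sd(s$lrr[auto])
    call_rate <- mean(s$genotype != "NC" & !is.na(s$genotype))
    isex <- infer_sex(s$baf[s$chrom == "X"])
    rsex <- manifest$reported_sex[manifest$sample_id == sid]
    reasons <- character(0)
    if (lrr_sd > lrr_sd_max) reasons <- c(reasons, "lrr_sd")
    if (call_rate < call_rate_min) reasons <- c(reasons, "call_rate")
    if (isex != "unknown" && isex != rsex) reasons <- c(reasons, "sex_mismatch")
    data.frame(sample_id = sid, lrr_sd = lrr_sd, call_rate = call_rate,
               inferred_sex = isex, pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against the proportions p^2, 2pq, q^2 implied by the observed
#' allele frequency. Monomorphic probes fit exactly and return p = 1.
#'
#' @param nAA,nAB,nBB non-negative genotype counts.
#' @return p-value in \[0, 1\].
#' @export
hwe_test <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n < 1) stop("at least one genotyped sample required")
  p <- (2 * nBB + nAB) / (2 * n)        # B allele frequency
  if (p == 0 || p == 1) return(1.0)
  exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(nAA, nAB, nBB) - exp_cnt)^2 / exp_cnt)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-probe HWE screen across populations
#'
#' Genotype counts are tallied separately within each population label
#' (QC-passing samples only should be supplied) and a probe is flagged if it
#' fails HWE in any population.
#'
#' @param signals named list of per-sample signal data.frames.
#' @param manifest sample manifest.
#' @param threshold exclusion threshold on the HWE p-value (default 1e-5).
#' @return data.frame \code{probe_id, population, nAA, nAB, nBB, p_value,
#'   excluded}, one row per probe x population.
#' @export
hwe_scan <- function(signals, manifest, threshold = 1e-5) {
  probe_ids <- signals[[1]]$probe_id
  pops <- unique(manifest$population[manifest$sample_id %in% names(signals)])
  out <- list()
  for (pop in pops) {
    ids <- intersect(manifest$sample_id[manifest$population == pop],
                     names(signals))
    geno <- vapply(ids, function(sid) signals[[sid]]$genotype,
                   character(length(probe_ids)))
    nAA <- rowSums(geno == "AA")
    nAB <- rowSums(geno == "AB")
    nBB <- rowSums(geno == "BB")
    pval <- vapply(seq_along(probe_ids), function(i) {
      if (nAA[i] + nAB[i] + nBB[i] < 1) return(1.0)
      hwe_test(nAA[i], nAB[i], nBB[i])
    }, numeric(1))
    out[[pop]] <- data.frame(probe_id = probe_ids, population = pop,
                             nAA = nAA, nAB = nAB, nBB = nBB,
                             p_value = pval, excluded = pval < threshold,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Remove HWE-failing probes from every sample
#'
#' @param signals named list of per-sample signal data.frames.
#' @param hwe_results output of [hwe_scan()] (or any data.frame with
#'   \code{probe_id} and \code{excluded}).
#' @param threshold re-applied on \code{p_value} if present; probes with
#'   \code{p_value < threshold} in any row are dropped.
#' @return list with \code{signals} (filtered) and \code{removed}
#'   (character vector of probe ids).
#' @export
filter_probes <- function(signals, hwe_results, threshold = 1e-5) {
  bad <- if ("p_value" %in% names(hwe_results)) {
    unique(hwe_results$probe_id[hwe_results$p_value < threshold])
  } else {
    unique(hwe_results$probe_id[hwe_results$excluded])
  }
  if (length(bad)) {
    signals <- lapply(signals, function(s) s[!(s$probe_id %in% bad), , drop = FALSE])
    message(length(bad), " probe(s) removed by HWE filter")
  }
  list(signals = signals, removed = bad)
}
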