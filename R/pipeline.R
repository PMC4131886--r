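#' Pipeline configuration
#'
#' Bundles every tunable of the workflow: QC thresholds, caller parameters,
#' consensus/filter thresholds, comparison parameters and the global seed.
#' Serializes losslessly to YAML via [write_pipeline_config()].
#'
#' @param lrr_sd_max,call_rate_min sample QC thresholds.
#' @param hwe_threshold probe-level HWE exclusion threshold.
#' @param hmm [hmm_params()].
#' @param cbs_alpha,cbs_n_perm,cbs_min_width CBS caller parameters.
#' @param thresholds [classify_thresholds()].
#' @param filters [filter_config()].
#' @param seed global RNG seed; per-stage seeds are derived from it.
#' @return named list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(lrr_sd_max = 0.3, call_rate_min = 0.98,
                            hwe_threshold = 1e-5, hmm = hmm_params(),
                            cbs_alpha = 0.01, cbs_n_perm = 1000L,
                            cbs_min_width = 2L,
                            thresholds = classify_thresholds(),
                            filters = filter_config(), seed = 1L) {
  structure(list(lrr_sd_max = lrr_sd_max, call_rate_min = call_rate_min,
                 hwe_threshold = hwe_threshold, hmm = hmm,
                 cbs_alpha = cbs_alpha, cbs_n_perm = cbs_n_perm,
                 cbs_min_width = cbs_min_width, thresholds = thresholds,
                 filters = filters, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    lrr_sd_max = raw$lrr_sd_max, call_rate_min = raw$call_rate_min,
    hwe_threshold = raw$hwe_threshold,
    hmm = do.call(hmm_params, raw$hmm[setdiff(names(raw$hmm), "states")]),
    cbs_alpha = raw$cbs_alpha, cbs_n_perm = raw$cbs_n_perm,
    cbs_min_width = raw$cbs_min_width,
    thresholds = do.call(classify_thresholds, raw$thresholds),
    filters = do.call(filter_config, raw$filters), seed = raw$seed)
  cfg
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Run the full CNV discovery and comparison pipeline
#'
#' Stages, in order: sample QC; per-population HWE probe filter; HMM and
#' CBS CNV calling on QC-passing samples; per-sample reciprocal-overlap
#' consensus; CNV-level and sample-level filters; CNVR merging, frequencies
#' and catalog summary; optional syndrome/gene annotation. Identical
#' inputs, configuration and seed give identical outputs.
#'
#' @param signals named list of per-sample signal data.frames.
#' @param map probe map.
#' @param manifest sample manifest.
#' @param excluded_regions centromere/telomere intervals (1-based closed)
#'   or NULL.
#' @param genes gene table (\code{symbol, chrom, start, end}) or NULL.
#' @param syndromes syndrome regions with \code{direction} or NULL.
#' @param config [pipeline_config()].
#' @param out_dir if non-NULL, every stage's tables are written there.
#' @return list with elements \code{qc, hwe_removed, hmm_calls, cbs_calls,
#'   consensus, kept, rejected, concordance, cnvrs, summary, genes_by_cnvr,
#'   syndrome}.
#' @export
run_pipeline <- function(signals, map, manifest, excluded_regions = NULL,
                         genes = NULL, syndromes = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, length(signals))

  # --- stage 1: sample QC -------------------------------------------------
  qc <- sample_qc(signals, manifest, config$lrr_sd_max, config$call_rate_min)
  pass <- qc$sample_id[qc$pass]
  signals_pass <- signals[pass]
  if (!length(signals_pass)) stop("pipeline aborted at stage sample_qc: no sample passed")

  # --- stage 2: probe-level HWE filter -----------------------------------
  hwe <- hwe_scan(signals_pass, manifest, config$hwe_threshold)
  fp <- filter_probes(signals_pass, hwe, config$hwe_threshold)
  signals_pass <- fp$signals
  map_kept <- map[!(map$probe_id %in% fp$removed), , drop = FALSE]

  # --- stage 3: dual-algorithm CNV calling -------------------------------
  hmm_calls <- do.call(rbind, lapply(names(signals_pass), function(sid)
    viterbi_call(signals_pass[[sid]], map_kept, config$hmm, sample_id = sid)))
  cbs_calls <- do.call(rbind, lapply(names(signals_pass), function(sid) {
    cbs_call(signals_pass[[sid]], map_kept, alpha = config$cbs_alpha,
             n_perm = config$cbs_n_perm, min_width = config$cbs_min_width,
             thresholds = config$thresholds,
             seed = sample_seeds[match(sid, names(signals))], sample_id = sid)
  }))
  if (is.null(hmm_calls)) hmm_calls <- empty_calls()
  if (is.null(cbs_calls)) cbs_calls <- empty_calls()

  # --- stage 4: consensus + filters --------------------------------------
  cons <- consensus_calls(hmm_calls, cbs_calls, map_kept, config$filters)
  concord <- list(
    fraction = if (nrow(cbs_calls))
      length(unique(cons$calls$cbs_idx)) / nrow(cbs_calls) else NA_real_,
    n_replicated = length(unique(cons$calls$cbs_idx)),
    n_total = nrow(cbs_calls))
  filt <- apply_filters(cons$calls, map_kept, excluded_regions, config$filters)

  # --- stage 5: CNVR catalog ---------------------------------------------
  kept <- filt$kept
  cnvrs <- merge_cnvrs(kept)
  cnvrs <- cnvr_frequency(cnvrs, kept, manifest[manifest$sample_id %in% pass, ],
                          config$filters$common_freq)
  auto_len <- tapply(map$pos, map$chrom, max)[AUTOSOMES]
  summary <- summarize_catalog(kept, cnvrs, auto_len,
                               manifest[manifest$sample_id %in% pass, ])
  genes_by_cnvr <- if (!is.null(genes)) gene_overlap(cnvrs, genes) else NULL
  syn <- if (!is.null(syndromes)) syndrome_overlap(kept, syndromes) else NULL

  res <- list(qc = qc, hwe_removed = fp$removed, hmm_calls = hmm_calls,
              cbs_calls = cbs_calls, consensus = cons$calls, kept = kept,
              rejected = filt$rejected, concordance = concord, cnvrs = cnvrs,
              summary = summary, genes_by_cnvr = genes_by_cnvr,
              syndrome = syn, config = config)
  class(res) <- "popcnv_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.popcnv_result <- function(x, ...) {
  cat("popcnv pipeline result\n")
  cat(sprintf("  samples passing QC : %d / %d\n", sum(x$qc$pass), nrow(x$qc)))
  cat(sprintf("  HMM / CBS calls    : %d / %d\n",
              nrow(x$hmm_calls), nrow(x$cbs_calls)))
  cat(sprintf("  consensus (kept)   : %d (%d)\n",
              nrow(x$consensus), nrow(x$kept)))
  cat(sprintf("  CBS concordance    : %.3f\n", x$concordance$fraction))
  cat(sprintf("  CNVRs              : %d (del %d, dup %d, complex %d)\n",
              x$summary$n_cnvr, x$summary$n_cnvr_del, x$summary$n_cnvr_dup,
              x$summary$n_cnvr_complex))
  cat(sprintf("  median calls/genome: %s\n", x$summary$calls_per_genome_median))
  invisible(x)
}

# Internal: write every stage table of a pipeline result.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(res$qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(res$hwe_removed, file.path(out_dir, "excluded_probes.txt"))
  write_cnv_table(res$hmm_calls, file.path(out_dir, "calls_hmm.cnv"))
  write_cnv_table(res$cbs_calls, file.path(out_dir, "calls_cbs.cnv"))
  write_cnv_table(res$kept, file.path(out_dir, "calls_consensus.cnv"))
  write.table(res$rejected, file.path(out_dir, "rejections.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cn <- res$cnvrs
  attr(cn, "members") <- NULL
  write.table(cn, file.path(out_dir, "cnvrs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_pipeline_config(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Gene-level carrier matrix for association and clustering
#'
#' A sample carries a gene when at least one of its filtered calls overlaps
#' the gene interval. Returns per-population carrier counts per gene.
#'
#' @param calls filtered calls.
#' @param genes gene table.
#' @param manifest sample manifest.
#' @return data.frame \code{locus, chrom, start, end} plus one
#'   \code{count_<pop>} column per population.
#' @export
gene_carrier_counts <- function(calls, genes, manifest) {
  pop_of <- manifest$population[match(calls$sample_id, manifest$sample_id)]
  pops <- unique(manifest$population)
  out <- genes
  names(out)[names(out) == "symbol"] <- "locus"
  for (p in pops) out[[paste0("count_", p)]] <- 0L
  for (g in seq_len(nrow(genes))) {
    ov <- calls$chrom == genes$chrom[g] & calls$start <= genes$end[g] &
      calls$end >= genes$start[g]
    who <- unique(data.frame(s = calls$sample_id[ov], p = pop_of[ov]))
    for (p in pops)
      out[[paste0("count_", p)]][g] <- sum(who$p == p)
  }
  out
}
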