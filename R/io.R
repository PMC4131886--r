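#' Read a per-sample signal TSV
#'
#' Expected columns: \code{probe_id, chrom, pos, genotype, lrr, baf}.
#' Rows with BAF outside \[0, 1\] or non-numeric positions are rejected
#' with their line numbers.
#'
#' @param path file path.
#' @return signal data.frame.
#' @export
read_signal_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(chrom = "character"))
  need <- c("probe_id", "chrom", "pos", "genotype", "lrr", "baf")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (!nrow(d)) {
    warning("empty signal file: ", path)
    return(d[, need])
  }
  bad <- which(is.na(d$baf) | d$baf < 0 | d$baf > 1 | is.na(d$pos))
  if (length(bad))
    stop("invalid signal row(s) in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  d[, need]
}

#' Write a per-sample signal TSV
#'
#' @param signal signal data.frame.
#' @param path output path.
#' @export
write_signal_tsv <- function(signal, path) {
  write.table(signal, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a BED file as 1-based closed intervals
#'
#' BED coordinates are 0-based half-open; on read, start becomes
#' \code{start + 1} and end is preserved. Rows with \code{start >= end} in
#' source coordinates are errors. Output is sorted by (chrom, start).
#'
#' @param path BED file (3+ columns, no header).
#' @return data.frame \code{chrom, start, end} (plus \code{name} if a 4th
#'   column is present).
#' @export
read_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = c(V1 = "character"))
  if (ncol(d) < 3) stop("BED file needs at least 3 columns: ", path)
  bad <- which(d[[2]] >= d[[3]])
  if (length(bad))
    stop("BED start >= end at line(s) ", paste(bad, collapse = ", "))
  out <- data.frame(chrom = sub("^chr", "", d[[1]]),
                    start = as.integer(d[[2]]) + 1L,
                    end = as.integer(d[[3]]), stringsAsFactors = FALSE)
  if (ncol(d) >= 4) out$name <- d[[4]]
  out[order(chrom_order(out$chrom), out$start), , drop = FALSE]
}

#' Write / read PLINK-style .cnv call tables
#'
#' Columns \code{FID IID CHR BP1 BP2 TYPE SCORE SITES}; TYPE is the integer
#' copy number (0, 1 or 3), SITES the probe count. The round-trip is
#' lossless for the canonical calls schema (FID carries the source tag).
#'
#' @param calls calls data.frame.
#' @param path file path.
#' @export
write_cnv_table <- function(calls, path) {
  check_calls(calls)
  d <- data.frame(FID = if (nrow(calls)) calls$source else character(0),
                  IID = calls$sample_id, CHR = calls$chrom,
                  BP1 = calls$start, BP2 = calls$end, TYPE = calls$cn,
                  SCORE = if ("score" %in% names(calls)) calls$score else 0,
                  SITES = calls$n_probes)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_cnv_table
#' @return \code{read_cnv_table}: calls data.frame.
#' @export
read_cnv_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(CHR = "character"))
  need <- c("FID", "IID", "CHR", "BP1", "BP2", "TYPE", "SCORE", "SITES")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (any(d$BP1 > d$BP2)) stop("BP1 > BP2 in ", path)
  data.frame(sample_id = as.character(d$IID), chrom = d$CHR,
             start = as.integer(d$BP1), end = as.integer(d$BP2),
             cn = as.integer(d$TYPE), n_probes = as.integer(d$SITES),
             score = as.numeric(d$SCORE), source = as.character(d$FID),
             stringsAsFactors = FALSE)
}

#' Read / write sample manifests and probe maps
#'
#' Tab-separated, headered tables: the manifest has columns
#' \code{sample_id, population, reported_sex}; the probe map
#' \code{probe_id, chrom, pos, pfb}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "reported_sex")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname read_manifest
#' @export
read_probe_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(chrom = "character"))
  need <- c("probe_id", "chrom", "pos", "pfb")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (any(d$pfb < 0 | d$pfb > 1)) stop("pfb outside [0,1] in ", path)
  d
}

#' @rdname read_manifest
#' @param map probe map data.frame.
#' @export
write_probe_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort to a directory
#'
#' Writes the probe map, manifest, truth table (BED-like TSV with a
#' copy-number column) and one signal TSV per sample under \code{dir}.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  write_probe_map(cohort$map, file.path(dir, "probes.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  if (!is.null(cohort$truth))
    write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (sid in names(cohort$signals))
    write_signal_tsv(cohort$signals[[sid]],
                     file.path(dir, "signals", paste0(sid, ".tsv")))
  invisible(dir)
}

#' Read a directory of per-sample signal TSVs
#'
#' @param dir directory of \code{<sample_id>.tsv} files.
#' @return named list of signal data.frames.
#' @export
read_signal_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, read_signal_tsv)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
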