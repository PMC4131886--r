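# Small shared cohort used across test files: 2 populations x 6 samples,
# 80 probes on each of 10 autosomes + X (loci rescaled accordingly).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lens <- setNames(rep(1085000L, 11L), c(as.character(1:10), "X"))
      map <- make_probe_map(80L, lens, seed = 42)
      d <- default_truth_loci(map, c("A", "B"))
      spikes <- spike_cnvs(map, c(A = 6L, B = 6L), d$loci, d$freq, seed = 43)
      signals <- emit_signals(map, spikes, signal_model(), seed = 44)
      cache <<- list(map = map, manifest = spikes$manifest,
                     truth = spikes$truth, carriers = spikes$carriers,
                     signals = signals)
    }
    cache
  }
})

# Noise-free diploid signal for one chromosome: LRR exactly 0, BAF at exact
# genotype clusters; handy for degenerate-input checks.
flat_signal <- function(n = 50, chrom = "1", spacing = 5000L) {
  data.frame(probe_id = sprintf("p%03d", 1:n), chrom = chrom,
             pos = seq(spacing, by = spacing, length.out = n),
             genotype = "AB", lrr = 0, baf = 0.5, stringsAsFactors = FALSE)
}

flat_map <- function(signal, pfb = 0.5) {
  data.frame(probe_id = signal$probe_id, chrom = signal$chrom,
             pos = signal$pos, pfb = pfb, stringsAsFactors = FALSE)
}
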