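mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], chrom = r[[2]], start = r[[3]], end = r[[4]],
               cn = r[[5]], n_probes = 10L, score = 1, source = "CONSENSUS",
               stringsAsFactors = FALSE)))
}

test_that("CNVR merging unions overlapping calls and types them", {
  calls <- mk_calls(list("s1", "1", 100, 200, 1L),
                    list("s2", "1", 150, 300, 1L),
                    list("s3", "1", 400, 500, 1L))
  r <- merge_cnvrs(calls)
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(100, 400))
  expect_equal(r$end, c(300, 500))
  expect_equal(r$type, c("DEL", "DEL"))
  # single call: identity
  one <- merge_cnvrs(calls[1, ])
  expect_equal(c(one$start, one$end), c(100, 200))
  # DEL + DUP overlap: COMPLEX
  cx <- merge_cnvrs(mk_calls(list("s1", "1", 100, 200, 1L),
                             list("s2", "1", 150, 250, 3L)))
  expect_equal(cx$type, "COMPLEX")
  expect_equal(c(cx$start, cx$end), c(100, 250))
  # abutting at one shared base merges; one-apart does not
  ab <- merge_cnvrs(mk_calls(list("s1", "1", 100, 200, 1L),
                             list("s2", "1", 200, 300, 1L)))
  expect_equal(nrow(ab), 1L)
  apart <- merge_cnvrs(mk_calls(list("s1", "1", 100, 200, 1L),
                                list("s2", "1", 202, 300, 1L)))
  expect_equal(nrow(apart), 2L)
})

test_that("merged CNVRs are disjoint and conserve covered bases", {
  set.seed(100)
  calls <- do.call(rbind, lapply(1:60, function(i) {
    st <- sample(1:5e5, 1)
    mk_calls(list(sprintf("s%d", sample(1:10, 1)), sample(c("1", "2"), 1),
                  st, st + sample(1e3:5e4, 1), sample(c(0L, 1L, 3L), 1)))
  }))
  r <- merge_cnvrs(calls)
  for (ch in unique(r$chrom)) {
    rc <- r[r$chrom == ch, ]
    rc <- rc[order(rc$start), ]
    if (nrow(rc) > 1) expect_true(all(rc$start[-1] > rc$end[-nrow(rc)] + 1))
    # conservation: union of call bases equals union of CNVR bases
    cc <- calls[calls$chrom == ch, ]
    call_bases <- unique(unlist(Map(seq, cc$start, cc$end)))
    cnvr_bases <- unlist(Map(seq, rc$start, rc$end))
    expect_setequal(call_bases, cnvr_bases)
  }
})

test_that("CNVR frequencies count each individual once", {
  man <- data.frame(sample_id = sprintf("s%d", 1:10),
                    population = rep(c("A", "B"), each = 5),
                    reported_sex = "female", stringsAsFactors = FALSE)
  calls <- mk_calls(list("s1", "1", 100, 200, 1L),
                    list("s1", "1", 250, 300, 1L),   # same carrier, same CNVR
                    list("s2", "1", 150, 280, 1L),
                    list("s6", "1", 100, 150, 1L))
  r <- merge_cnvrs(calls)
  f <- cnvr_frequency(r, calls, man)
  expect_equal(f$count_A, 2L)        # s1 counted once despite two calls
  expect_equal(f$count_B, 1L)
  expect_equal(f$freq_A, 0.4)
  expect_equal(f$freq_B, 0.2)
  expect_true(f$common)              # >= 5% in a population
  expect_error(cnvr_frequency(r, mk_calls(list("zz", "1", 1, 5, 1L)), man),
               "not in the manifest")
})

test_that("singleton filter retains exactly the multi-carrier subset", {
  man <- data.frame(sample_id = sprintf("s%d", 1:4), population = "A",
                    reported_sex = "male", stringsAsFactors = FALSE)
  calls <- mk_calls(list("s1", "1", 100, 200, 1L),
                    list("s2", "1", 150, 250, 1L),
                    list("s3", "2", 100, 200, 1L))
  f <- cnvr_frequency(merge_cnvrs(calls), calls, man)
  multi <- singleton_filter(f)
  expect_equal(nrow(multi), 1L)
  expect_equal(multi$chrom, "1")
  expect_identical(singleton_filter(multi), multi)      # idempotent
  # all singletons -> empty
  expect_equal(nrow(singleton_filter(f[f$n_carriers == 1, ])), 0L)
})

test_that("catalog summary statistics are computed as stated", {
  man <- data.frame(sample_id = c("s1", "s2", "s3"), population = "A",
                    reported_sex = "male", stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s)
    mk_calls(list(s, "1", 1, 1e6, 1L),
             list(s, "2", 1, 2e6, 3L),
             list(s, "3", 1, 3e6, 1L),
             list(s, "4", 1, 4e6, 1L),
             list(s, "5", 1, 5e6, 1L),
             list(s, "6", 1, 6e6, 1L),
             list(s, "7", 1, 7e6, 1L),
             list(s, "8", 1, 8e6, 1L))))
  r <- merge_cnvrs(calls)
  lens <- setNames(rep(1e8, 22), as.character(1:22))
  sm <- summarize_catalog(calls, r, lens, man)
  expect_equal(sm$calls_per_genome_median, 8)
  expect_equal(sm$calls_per_genome_mean, 8)
  expect_equal(sm$n_del, 21L)
  expect_equal(sm$n_dup, 3L)
  expect_equal(sm$call_size_median, 4.5e6)
  # one 1 Mb CNVR on a 100 Mb genome = 1%
  one <- merge_cnvrs(mk_calls(list("s1", "1", 1, 1e6, 1L)))
  sm1 <- summarize_catalog(mk_calls(list("s1", "1", 1, 1e6, 1L)), one,
                           c("1" = 1e8), man)
  expect_equal(sm1$genome_coverage_pct, 1)
  # empty catalog: zeros, no crash
  sm0 <- summarize_catalog(calls[0, ], r[0, ], lens, man)
  expect_equal(sm0$n_calls, 0L)
  expect_equal(sm0$genome_coverage_bp, 0)
})

test_that("syndrome overlap requires matched direction", {
  syn <- data.frame(chrom = c("1", "2"), start = c(100, 100),
                    end = c(500, 500), direction = c("DEL", "DUP"),
                    stringsAsFactors = FALSE)
  calls <- mk_calls(list("s1", "1", 200, 300, 1L),   # DEL in DEL region: hit
                    list("s2", "2", 200, 300, 1L),   # DEL in DUP region: miss
                    list("s3", "2", 200, 300, 3L),   # DUP in DUP region: hit
                    list("s4", "3", 200, 300, 1L))   # no region: miss
  so <- syndrome_overlap(calls, syn)
  expect_equal(so$count, 2L)
  expect_equal(so$percent, 50.00)
  expect_equal(syndrome_overlap(calls, syn[0, ])$count, 0L)
  # published ratio arithmetic reproduces at 2 decimals
  expect_equal(round(100 * 766 / 23458, 2), 3.27)
})

test_that("gene overlap lists genes in positional order", {
  genes <- data.frame(symbol = c("G2", "G1", "G3"), chrom = "1",
                      start = c(5000, 1000, 9000), end = c(6000, 2000, 9500),
                      stringsAsFactors = FALSE)
  r <- merge_cnvrs(mk_calls(list("s1", "1", 500, 7000, 1L)))
  ov <- gene_overlap(r, genes)
  expect_equal(ov[[1]], c("G1", "G2"))       # both, positional order
  r2 <- merge_cnvrs(mk_calls(list("s1", "1", 2500, 4000, 1L)))
  expect_equal(length(gene_overlap(r2, genes)[[1]]), 0L)
  # malformed row skipped with warning
  genes$start[3] <- NA
  expect_warning(gene_overlap(r, genes), "malformed")
})

test_that("degree of match reports per-frequency-bin overlap fractions", {
  a <- data.frame(cnvr_id = sprintf("R%d", 1:4), chrom = "1",
                  start = c(100, 5000, 9000, 20000),
                  end = c(200, 6000, 9500, 21000),
                  freq = c(0.02, 0.08, 0.15, 0.5), stringsAsFactors = FALSE)
  # B overlaps loci 2 and 4 only
  b <- data.frame(chrom = "1", start = c(5500, 20500), end = c(5600, 20600))
  dm <- degree_of_match(a, b)
  expect_equal(dm$fraction[dm$bin == "(0.01,0.05]"], 0)
  expect_equal(dm$fraction[dm$bin == "(0.05,0.1]"], 1)
  expect_equal(dm$fraction[dm$bin == "(0.2,1]"], 1)
  # A matched against itself: fraction 1 in every occupied bin
  dm_self <- degree_of_match(a, a)
  expect_true(all(dm_self$fraction[dm_self$n > 0] == 1))
  # disjoint: all zero
  far <- data.frame(chrom = "2", start = 1, end = 10)
  dm0 <- degree_of_match(a, far)
  expect_true(all(dm0$fraction[dm0$n > 0] == 0))
})
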