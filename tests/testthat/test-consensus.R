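mk_call <- function(sample_id = "s1", chrom = "1", start, end, cn = 1L,
                    n_probes = 10L, source = "HMM") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cn = cn, n_probes = n_probes, score = 1, source = source,
             stringsAsFactors = FALSE)
}

grid_map <- function(n = 400L, chrom = "1", spacing = 1000L) {
  data.frame(probe_id = sprintf("g%04d", 1:n), chrom = chrom,
             pos = seq(spacing, by = spacing, length.out = n), pfb = 0.5,
             stringsAsFactors = FALSE)
}

test_that("reciprocal overlap uses closed-interval arithmetic", {
  ro <- reciprocal_overlap("1", 10000, 20000, "1", 14000, 22000)
  expect_equal(ro$frac_a, 6001 / 10001)
  expect_equal(ro$frac_b, 6001 / 8001)
  expect_equal(c(ro$inter_start, ro$inter_end), c(14000, 20000))
  # identity
  ro2 <- reciprocal_overlap("1", 5, 10, "1", 5, 10)
  expect_equal(c(ro2$frac_a, ro2$frac_b), c(1, 1))
  # disjoint and different chromosomes
  expect_equal(reciprocal_overlap("1", 1, 10, "1", 20, 30)$frac_a, 0)
  expect_equal(reciprocal_overlap("1", 1, 10, "2", 1, 10)$frac_b, 0)
  expect_true(is.na(reciprocal_overlap("1", 1, 10, "2", 1, 10)$inter_start))
})

test_that("consensus pairs same-direction calls above the overlap threshold", {
  map <- grid_map()
  h <- mk_call(start = 10000, end = 20000)                  # HETDEL
  b <- mk_call(start = 14000, end = 22000, source = "CBS")  # fractions .60/.75
  cons <- consensus_calls(h, b, map)$calls
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(14000, 20000))
  expect_equal(cons$cn, 1L)                 # class from the HMM call
  expect_equal(cons$source, "CONSENSUS")
  expect_equal(cons$n_probes, 7L)           # probes at 14,15,...,20 kb

  # 50% overlap: no pair
  b50 <- mk_call(start = 15001, end = 25001, source = "CBS")
  expect_equal(nrow(consensus_calls(h, b50, map)$calls), 0L)
  # direction mismatch kills a 100% overlap
  bdup <- mk_call(start = 10000, end = 20000, cn = 3L, source = "CBS")
  expect_equal(nrow(consensus_calls(h, bdup, map)$calls), 0L)
  # HOMDEL vs HETDEL share direction DEL: pair allowed, class from HMM
  bhom <- mk_call(start = 10000, end = 20000, cn = 0L, source = "CBS")
  expect_equal(consensus_calls(h, bhom, map)$calls$cn, 1L)
})

test_that("consensus interval geometry is symmetric in the two call sets", {
  map <- grid_map()
  set.seed(90)
  a <- do.call(rbind, lapply(1:8, function(i) {
    st <- sample(1e4:3e5, 1)
    mk_call(start = st, end = st + sample(2e4:5e4, 1), cn = sample(c(0L, 1L, 3L), 1))
  }))
  b <- do.call(rbind, lapply(1:8, function(i) {
    st <- sample(1e4:3e5, 1)
    mk_call(start = st, end = st + sample(2e4:5e4, 1),
            cn = sample(c(0L, 1L, 3L), 1), source = "CBS")
  }))
  ab <- consensus_calls(a, b, map)$calls
  ba <- consensus_calls(b, a, map)$calls
  expect_equal(ab[, c("chrom", "start", "end")], ba[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("quality filters reject by the stated rules and tag reasons", {
  map <- grid_map()
  cfg <- filter_config()
  calls <- rbind(
    mk_call(start = 10000, end = 18000, n_probes = 4L),          # del_min probes
    mk_call(start = 10000, end = 14999, n_probes = 5L),          # del_min length (=5 kb fails ">")
    mk_call(start = 100000, end = 199999, n_probes = 2L),        # density 1/50kb
    mk_call(start = 200000, end = 215000, cn = 3L, n_probes = 9L),  # dup_min
    mk_call(start = 300000, end = 320000, n_probes = 21L),       # clean DEL
    mk_call("s1", "X", 10000, 30000, n_probes = 21L)             # sex chrom
  )
  res <- apply_filters(calls, map, excluded_regions = NULL, config = cfg)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$kept$start, 300000)
  expect_setequal(res$rejected$reason,
                  c("del_min", "del_min", "density", "dup_min", "sex_chrom"))

  # centromere rule: call 60% inside an excluded interval is rejected
  centro <- data.frame(chrom = "1", start = 300000, end = 312000)
  res2 <- apply_filters(calls[5, ], map, centro, cfg)
  expect_equal(nrow(res2$kept), 0L)
  expect_equal(res2$rejected$reason, "region")
  # 50% exactly is tolerated (rule is "more than 50%")
  centro2 <- data.frame(chrom = "1", start = 300000, end = 310000)
  fr <- (310000 - 300000 + 1) / (320000 - 300000 + 1)
  expect_gt(fr, 0.5)  # closed arithmetic: 10001/20001 just above half
  centro3 <- data.frame(chrom = "1", start = 300001, end = 310000)
  expect_equal(nrow(apply_filters(calls[5, ], map, centro3, cfg)$kept), 1L)
})

test_that("per-sample cap drops whole samples and the ledger balances", {
  map <- grid_map()
  cfg <- filter_config(per_sample_max = 3L)
  many <- do.call(rbind, lapply(1:5, function(i)
    mk_call(start = 50000 * i, end = 50000 * i + 30000, n_probes = 31L)))
  ok <- mk_call("s2", start = 50000, end = 80000, n_probes = 31L)
  res <- apply_filters(rbind(many, ok), map, NULL, cfg)
  expect_equal(unique(res$kept$sample_id), "s2")
  expect_equal(sum(res$rejected$reason == "per_sample_max"), 5L)
  expect_equal(nrow(res$kept) + nrow(res$rejected), 6L)
})

test_that("every kept call re-satisfies all filter predicates", {
  co <- small_cohort()
  calls <- do.call(rbind, lapply(names(co$signals), function(sid)
    viterbi_call(co$signals[[sid]], co$map, sample_id = sid)))
  cbs <- do.call(rbind, lapply(names(co$signals), function(sid)
    cbs_call(co$signals[[sid]], co$map, seed = 91, sample_id = sid)))
  cons <- consensus_calls(calls, cbs, co$map)$calls
  cfg <- filter_config()
  res <- apply_filters(cons, co$map, NULL, cfg)
  k <- res$kept
  if (nrow(k)) {
    len <- k$end - k$start + 1
    dir <- cn_direction(k$cn)
    expect_true(all(is_autosome(k$chrom)))
    expect_true(all(k$n_probes / len >= 1 / cfg$density_min_bp))
    expect_true(all(dir != "DEL" |
                      (k$n_probes >= cfg$del_min_probes & len > cfg$del_min_bp)))
    expect_true(all(dir != "DUP" |
                      (k$n_probes >= cfg$dup_min_probes & len > cfg$dup_min_bp)))
    expect_true(all(table(k$sample_id) <= cfg$per_sample_max))
  }
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(cons))
})

test_that("concordance fraction uses CBS calls as the denominator", {
  map <- grid_map()
  a <- mk_call(start = 10000, end = 20000)
  b <- rbind(mk_call(start = 14000, end = 22000, source = "CBS"),
             mk_call(start = 100000, end = 120000, source = "CBS"))
  cf <- concordance_fraction(a, b, map)
  expect_equal(cf$fraction, 0.5)
  expect_equal(cf$n_total, 2L)
  # identical sets: 1.0; empty CBS set: undefined
  expect_equal(concordance_fraction(a, mk_call(start = 10000, end = 20000,
                                               source = "CBS"), map)$fraction, 1)
  expect_true(is.na(concordance_fraction(a, a[0, ], map)$fraction))
  # the published ratio arithmetic: 29,436 of 42,290 rounds to 70%
  expect_equal(round(100 * 29436 / 42290), 70)
})
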