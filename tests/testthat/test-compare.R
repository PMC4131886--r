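test_that("permutation association behaves at the null, floor and zero", {
  # equal frequencies: p well away from significance
  r <- permutation_association(10, 100, 10, 100, n_perm = 2000, seed = 1)
  expect_gt(r$p_value, 0.5)
  # maximally separated locus: p at the attainable floor 1/(R+1); no
  # permutation can beat a 30/0 split of 30 carriers
  r2 <- permutation_association(30, 100, 0, 100, n_perm = 5000, seed = 2)
  expect_equal(r2$p_value, 1 / 5001)
  expect_true(r2$significant)
  # cross-check with the exact hypergeometric tail: the most extreme table
  # (all 30 carriers in group 1) has probability choose(100,30)/choose(200,30)
  p_extreme <- exp(lchoose(100, 30) - lchoose(200, 30))
  expect_lt(p_extreme, 1e-9)  # so b = 0 is near-certain, p = floor
  # observed statistic 0: every permutation ties, p = 1
  r3 <- permutation_association(0, 50, 0, 60, n_perm = 500, seed = 3)
  expect_equal(r3$p_value, 1)
  expect_error(permutation_association(1, 10, 1, 10, n_perm = 0), "n_perm")
})

test_that("empirical p decreases with the true frequency gap", {
  set.seed(4)
  gaps <- c(0, 0.1, 0.2, 0.4)
  ps <- vapply(gaps, function(g) {
    mean(vapply(1:30, function(i) {
      c1 <- rbinom(1, 200, 0.1 + g)
      c2 <- rbinom(1, 200, 0.1)
      permutation_association(c1, 200, c2, 200, n_perm = 500)$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("row scaling centres, scales, flags constants and inverts", {
  m <- rbind(a = c(0.2, 0.4, 0.6), b = c(0.1, 0.1, 0.1))
  s <- scale_rows(m)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_equal(unname(s["b", ]), c(0, 0, 0))
  expect_identical(unname(attr(s, "constant_rows")), c(FALSE, TRUE))
  expect_lt(max(abs(rowMeans(s))), 1e-12)
  # un-scale reproduces the input for non-constant rows
  back <- s["a", ] * sd(m["a", ]) + mean(m["a", ])
  expect_equal(unname(back), unname(m["a", ]), tolerance = 1e-12)
  expect_error(scale_rows(matrix(1:3, 3, 1)), "2 columns")
})

test_that("Ward clustering matches a brute-force minimum-variance oracle", {
  set.seed(5)
  for (k in c(3, 5, 6)) {
    m <- matrix(rnorm(10 * k), 10, k,
                dimnames = list(NULL, paste0("P", 1:k)))
    got <- hierarchical_cluster(m)
    want <- brute_ward(lapply(seq_len(k), function(j) m[, j]))
    expect_equal(sort(got$height), sort(want$heights), tolerance = 1e-9)
  }
})

test_that("clustering has the expected metric behaviour and guards", {
  m <- cbind(P1 = c(1, 2, 3), P2 = c(1, 2, 3), P3 = c(9, 9, 9))
  hc <- hierarchical_cluster(m)
  # identical columns merge first, at height 0
  expect_equal(hc$height[1], 0)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_match(hc$newick, "P1")
  m2 <- m; m2[2, 2] <- NaN; rownames(m2) <- c("l1", "l2", "l3")
  expect_error(hierarchical_cluster(m2), "l2")
})

test_that("top-gene selection ranks by signed difference within pairs", {
  mk <- function(n, sig = TRUE, seed) {
    set.seed(seed)
    data.frame(locus = sprintf("g%02d_%d", 1:n, seed), chrom = "1",
               start = seq_len(n) * 1000 + seed, diff = seq(-1, 1, length.out = n),
               p_value = 1e-5, significant = sig, stringsAsFactors = FALSE)
  }
  # 25 significant loci in one pair -> exactly 20 selected
  sel <- top_gene_selection(list(p1 = mk(25, seed = 1)))
  expect_equal(nrow(sel), 20L)
  # the extremes are taken
  expect_true(all(range(mk(25, seed = 1)$diff) %in% sel$diff))
  # overlapping selections across pairs deduplicate
  sel2 <- top_gene_selection(list(p1 = mk(25, seed = 1), p2 = mk(25, seed = 1)))
  expect_equal(nrow(sel2), 20L)
  # no significant loci: empty with a warning
  expect_warning(s0 <- top_gene_selection(list(p1 = mk(5, sig = FALSE, seed = 2))),
                 "no significant")
  expect_true(is.null(s0) || nrow(s0) == 0L)
})

test_that("homozygous-deletion bookkeeping splits carriers by zygosity", {
  man <- data.frame(sample_id = sprintf("s%d", 1:10),
                    population = rep(c("A", "B"), each = 5),
                    reported_sex = "male", stringsAsFactors = FALSE)
  zyg <- data.frame(sample_id = c("s1", "s2", "s3", "s6"),
                    class = c("HOMDEL", "HOMDEL", "HETDEL", "HETDEL"),
                    stringsAsFactors = FALSE)
  hb <- homdel_bookkeeping(zyg, man)
  a <- hb[hb$population == "A", ]
  expect_equal(a$total_freq, 0.6)
  expect_equal(a$homdel_freq, 0.4)
  expect_equal(a$proportion, round(0.4 / 0.6, 3))
  b <- hb[hb$population == "B", ]
  expect_equal(b$proportion, 0)          # carriers but no homozygotes
  # published ratio arithmetic (population frequency tables)
  expect_equal(homdel_proportion(0.522, 0.482), 0.923)
  expect_equal(homdel_proportion(0.988, 0.779), 0.788)
  expect_true(is.na(homdel_proportion(0, 0)))
})
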