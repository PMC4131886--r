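# Independent brute-force oracles, deliberately written from first
# principles rather than via the package's code paths.

# Exhaustive Viterbi: enumerate all 4^n state paths, score each with the
# supplied emission matrix (n x 4, log) and the same transition structure,
# and return the best log-probability.
brute_best_path <- function(emis, dist, params) {
  n <- nrow(emis)
  m <- params$p_off * (1 - exp(-dist / params$D))
  log_init <- log(c(params$p_off, params$p_off, 1 - 3 * params$p_off, params$p_off))
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    lp <- log_init[st[1]] + emis[1, st[1]]
    if (n > 1) for (t in 2:n) {
      lp <- lp + if (st[t] == st[t - 1]) log(1 - m[t - 1]) else log(m[t - 1] / 3)
      lp <- lp + emis[t, st[t]]
    }
    if (lp > best) best <- lp
  }
  best
}

# Brute-force circular max-T: double loop over all (i, j), computing group
# means and the pooled-variance t statistic directly.
brute_max_t <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(i = 0L, j = n, T = 0)
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    n1 <- j - i; n2 <- n - n1
    if (n1 < min_width || n2 < min_width) next
    arc <- x[(i + 1):j]
    comp <- x[-((i + 1):j)]
    sse <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
    s2 <- sse / (n - 2)
    Tv <- if (s2 <= 0) {
      if (mean(arc) == mean(comp)) 0 else Inf
    } else {
      abs(mean(arc) - mean(comp)) / sqrt(s2 * (1 / n1 + 1 / n2))
    }
    if (Tv > best$T) best <- list(i = i, j = j, T = Tv)
  }
  best
}

# Brute-force Ward clustering from the minimum-variance definition: at each
# step merge the two clusters whose union minimizes the increase in total
# within-cluster sum of squares; report heights on the hclust ward.D2
# scale, sqrt(2 * delta ESS).
brute_ward <- function(cols) {        # cols: list of column vectors
  k <- length(cols)
  clusters <- lapply(seq_len(k), function(i) list(idx = -i, xs = cols[i]))
  heights <- numeric(0)
  merges <- list()
  step <- 0L
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ess <- function(xs) {
        m <- Reduce(`+`, xs) / length(xs)
        sum(vapply(xs, function(x) sum((x - m)^2), numeric(1)))
      }
      d <- ess(c(clusters[[a]]$xs, clusters[[b]]$xs)) -
        ess(clusters[[a]]$xs) - ess(clusters[[b]]$xs)
      if (is.null(best) || d < best$d - 1e-12) best <- list(a = a, b = b, d = d)
    }
    step <- step + 1L
    heights <- c(heights, sqrt(2 * best$d))
    merges[[step]] <- c(clusters[[best$a]]$idx[1], clusters[[best$b]]$idx[1])
    merged <- list(idx = step,
                   xs = c(clusters[[best$a]]$xs, clusters[[best$b]]$xs))
    clusters <- c(clusters[-c(best$a, best$b)], list(merged))
  }
  list(heights = heights, merges = merges)
}

# HWE chi-square assembled step by step (allele counting first, then
# expected genotype counts, then the statistic).
brute_hwe_p <- function(a, b, c) {
  n <- a + b + c
  nB <- 2 * c + b
  nA <- 2 * a + b
  if (nB == 0 || nA == 0) return(1.0)
  q <- nB / (2 * n)
  e <- c(n * (1 - q)^2, n * 2 * q * (1 - q), n * q^2)
  stat <- (a - e[1])^2 / e[1] + (b - e[2])^2 / e[2] + (c - e[3])^2 / e[3]
  1 - pchisq(stat, 1)
}
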