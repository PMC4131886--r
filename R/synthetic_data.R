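#' Default miniature genome for simulation
#'
#' Chromosome lengths used by the synthetic-data generator: 22 autosomes plus
#' X, each 1.085 Mb. With the default 217 probes per chromosome this gives a
#' 5 kb probe spacing, the density of a typical ~600k Illumina genotyping
#' array, so that probe-density and size filters behave as they would on real
#' data while the whole genome stays small enough to simulate quickly.
#'
#' @param chrom_length length in bp of every chromosome.
#' @return named integer vector of chromosome lengths ("1".."22", "X").
#' @export
default_chrom_lengths <- function(chrom_length = 1085000L) {
  setNames(rep(as.integer(chrom_length), 23L), c(AUTOSOMES, "X"))
}

#' Per-state LRR/BAF emission model
#'
#' The signal model shared by the generator and the HMM caller. LRR for copy
#' number k is Normal(lrr_mean[k], lrr_sd[k]); BAF is a mixture of Gaussian
#' clusters whose centres depend on the copy number (\{0, 1/2, 1\} for the
#' diploid state, \{0, 1\} for a heterozygous deletion, \{0, 1/3, 2/3, 1\}
#' for a duplication) plus uniform noise for copy number 0, where no allelic
#' signal remains.
#'
#' @param lrr_mean,lrr_sd length-4 numeric vectors indexed by copy number
#'   0,1,2,3 (log2-ratio scale). Means must be strictly increasing in copy
#'   number; SDs positive.
#' @param baf_sd SD of each BAF genotype cluster.
#' @param no_call_rate fraction of probes emitted with a missing genotype
#'   call (drives call-rate QC).
#' @return object of class \code{signal_model}.
#' @export
signal_model <- function(lrr_mean = c(-3.5, -0.66, 0, 0.40),
                         lrr_sd = c(1.3, 0.25, 0.18, 0.20),
                         baf_sd = 0.03,
                         no_call_rate = 0.005) {
  stopifnot(length(lrr_mean) == 4, length(lrr_sd) == 4,
            all(diff(lrr_mean) > 0), all(lrr_sd > 0), baf_sd > 0,
            no_call_rate >= 0, no_call_rate < 1)
  structure(list(lrr_mean = lrr_mean, lrr_sd = lrr_sd, baf_sd = baf_sd,
                 no_call_rate = no_call_rate),
            class = "signal_model")
}

#' Generate a probe map
#'
#' Probes are laid out with uniform spacing plus jitter within each
#' chromosome, then sorted and deduplicated; the population frequency of the
#' B allele (PFB) of each probe is drawn uniformly on \[0.05, 0.95\].
#'
#' @param n_probes_per_chrom number of probes on each chromosome (>= 2).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{probe_id, chrom, pos, pfb};
#'   positions strictly increasing within each chromosome.
#' @export
make_probe_map <- function(n_probes_per_chrom = 217L,
                           chrom_lengths = default_chrom_lengths(),
                           seed = 1L) {
  if (!is.numeric(n_probes_per_chrom) || n_probes_per_chrom < 2)
    stop("n_probes_per_chrom must be a positive integer >= 2")
  set.seed(seed)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    spacing <- L / n_probes_per_chrom
    pos <- round(spacing * (seq_len(n_probes_per_chrom) - 0.5) +
                   runif(n_probes_per_chrom, -0.3, 0.3) * spacing)
    pos <- sort(unique(pmin(pmax(pos, 1L), L)))
    data.frame(probe_id = sprintf("chr%s_p%04d", ch, seq_along(pos)),
               chrom = ch, pos = as.integer(pos),
               pfb = runif(length(pos), 0.05, 0.95),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign ground-truth CNV carriers per population
#'
#' Each locus is spiked into each population by independent Bernoulli draws
#' at that population's target frequency, so realized carrier counts are
#' Binomial(n, freq).
#'
#' @param map probe map from [make_probe_map()].
#' @param populations named integer vector: population label -> sample count.
#' @param loci data.frame with columns \code{chrom, start, end, cn}
#'   (1-based closed intervals on autosomes; \code{cn} in 0, 1, 3).
#' @param freq numeric matrix (nrow = nrow(loci), columns named by
#'   population) of target carrier frequencies in \[0, 1\].
#' @param seed integer RNG seed.
#' @return list with \code{truth} (loci plus locus_id, n_probes, per-pop
#'   target and realized frequencies), \code{carriers} (locus_id x sample_id
#'   pairs) and \code{manifest} (sample_id, population, reported_sex).
#' @export
spike_cnvs <- function(map, populations, loci, freq, seed = 1L) {
  stopifnot(is.numeric(populations), !is.null(names(populations)))
  if (nrow(loci)) {
    stopifnot(all(loci$cn %in% c(0L, 1L, 3L)),
              all(loci$start <= loci$end))
    if (!all(is_autosome(loci$chrom)))
      stop("spiked loci must lie on autosomes")
    freq <- as.matrix(freq)
    stopifnot(nrow(freq) == nrow(loci),
              all(names(populations) %in% colnames(freq)),
              all(freq >= 0 & freq <= 1))
  }
  set.seed(seed)
  manifest <- do.call(rbind, lapply(names(populations), function(p) {
    n <- populations[[p]]
    data.frame(sample_id = sprintf("%s_%03d", p, seq_len(n)),
               population = p,
               reported_sex = sample(c("male", "female"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  truth <- carriers <- NULL
  if (nrow(loci)) {
    loci$locus_id <- sprintf("L%02d", seq_len(nrow(loci)))
    loci$n_probes <- vapply(seq_len(nrow(loci)), function(i) {
      sum(map$chrom == loci$chrom[i] &
            map$pos >= loci$start[i] & map$pos <= loci$end[i])
    }, integer(1))
    empty <- loci$n_probes == 0L
    if (any(empty)) {
      warning("skipping ", sum(empty), " locus/loci containing no probes")
      loci <- loci[!empty, , drop = FALSE]
      freq <- freq[!empty, , drop = FALSE]
    }
    carriers <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      hit <- unlist(lapply(names(populations), function(p) {
        ids <- manifest$sample_id[manifest$population == p]
        ids[runif(length(ids)) < freq[i, p]]
      }))
      if (!length(hit)) return(NULL)
      data.frame(locus_id = loci$locus_id[i], sample_id = hit,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(carriers))
      carriers <- data.frame(locus_id = character(), sample_id = character(),
                             stringsAsFactors = FALSE)
    for (p in names(populations)) {
      ids <- manifest$sample_id[manifest$population == p]
      loci[[paste0("target_", p)]] <- freq[, p]
      loci[[paste0("realized_", p)]] <- vapply(loci$locus_id, function(l) {
        sum(carriers$sample_id[carriers$locus_id == l] %in% ids) / length(ids)
      }, numeric(1))
    }
    truth <- loci
  } else {
    truth <- cbind(loci, locus_id = character(0), n_probes = integer(0))
    carriers <- data.frame(locus_id = character(), sample_id = character(),
                           stringsAsFactors = FALSE)
  }
  list(truth = truth, carriers = carriers, manifest = manifest)
}

# Internal: draw BAF and genotype for n probes at copy number cn.
draw_baf_genotype <- function(n, cn, pfb, baf_sd) {
  geno <- character(n)
  baf <- numeric(n)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  if (cn == 0L) {                      # no allelic signal: uniform noise
    baf <- runif(n)
    geno <- rep("NC", n)
  } else if (cn == 1L) {               # hemizygous: A or B only
    b <- runif(n) < pfb
    baf <- clamp(rnorm(n, ifelse(b, 1, 0), baf_sd))
    geno <- ifelse(b, "BB", "AA")
  } else if (cn == 2L) {
    u <- runif(n)
    pAA <- (1 - pfb)^2; pAB <- 2 * pfb * (1 - pfb)
    g <- ifelse(u < pAA, 0L, ifelse(u < pAA + pAB, 1L, 2L))
    baf <- clamp(rnorm(n, g / 2, baf_sd))
    geno <- c("AA", "AB", "BB")[g + 1L]
  } else {                             # cn 3: AAA/AAB/ABB/BBB
    u <- runif(n)
    p0 <- (1 - pfb)^3; p1 <- 3 * (1 - pfb)^2 * pfb; p2 <- 3 * (1 - pfb) * pfb^2
    g <- ifelse(u < p0, 0L, ifelse(u < p0 + p1, 1L, ifelse(u < p0 + p1 + p2, 2L, 3L)))
    baf <- clamp(rnorm(n, g / 3, baf_sd))
    geno <- c("AA", "AB", "AB", "BB")[g + 1L]  # array software calls het for AAB/ABB
  }
  list(baf = baf, genotype = geno)
}

#' Emit per-sample LRR/BAF signal tables
#'
#' Outside any carried CNV a sample is diploid: LRR ~ Normal(mean2, sd2) and
#' BAF clusters at \{0, 1/2, 1\} with Hardy-Weinberg weights from the probe
#' PFB. Inside a carried CNV the corresponding copy-number emission applies.
#' On chromosome X, males are hemizygous (single-allele BAF, shifted LRR).
#' A configurable fraction of probes is emitted with genotype "NC" (no call).
#'
#' @param map probe map.
#' @param spikes result of [spike_cnvs()] (truth + carriers + manifest).
#' @param model [signal_model()].
#' @param seed integer RNG seed.
#' @return named list of per-sample data.frames with columns
#'   \code{probe_id, chrom, pos, genotype, lrr, baf}.
#' @export
emit_signals <- function(map, spikes, model = signal_model(), seed = 1L) {
  stopifnot(inherits(model, "signal_model"))
  set.seed(seed)
  manifest <- spikes$manifest
  truth <- spikes$truth
  carriers <- spikes$carriers
  n_probe <- nrow(map)
  is_x <- map$chrom == "X"

  signals <- vector("list", nrow(manifest))
  names(signals) <- manifest$sample_id
  for (si in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[si]
    cn_vec <- rep(2L, n_probe)
    if (!is.null(truth) && nrow(truth)) {
      mine <- carriers$locus_id[carriers$sample_id == sid]
      for (l in mine) {
        row <- truth[truth$locus_id == l, ]
        in_l <- map$chrom == row$chrom & map$pos >= row$start & map$pos <= row$end
        cn_vec[in_l] <- row$cn
      }
    }
    male <- manifest$reported_sex[si] == "male"
    if (male) cn_vec[is_x] <- 1L   # hemizygous X

    lrr <- rnorm(n_probe, model$lrr_mean[cn_vec + 1L], model$lrr_sd[cn_vec + 1L])
    if (male) # male X LRR sits between het-del and diploid on these arrays
      lrr[is_x] <- rnorm(sum(is_x), model$lrr_mean[2] / 2, model$lrr_sd[3])
    baf <- numeric(n_probe)
    geno <- character(n_probe)
    for (cn in unique(cn_vec)) {
      idx <- which(cn_vec == cn)
      d <- draw_baf_genotype(length(idx), cn, map$pfb[idx], model$baf_sd)
      baf[idx] <- d$baf
      geno[idx] <- d$genotype
    }
    if (model$no_call_rate > 0) {
      nc <- runif(n_probe) < model$no_call_rate
      geno[nc] <- "NC"
    }
    signals[[si]] <- data.frame(probe_id = map$probe_id, chrom = map$chrom,
                                pos = map$pos, genotype = geno,
                                lrr = lrr, baf = baf,
                                stringsAsFactors = FALSE)
  }
  signals
}

#' Bundled simulation scenario: spiked loci
#'
#' Ten ground-truth loci on distinct autosomes spanning deletions (copy
#' number 1 and 0) and duplications (copy number 3), sized 15-40 probes,
#' with per-population carrier frequencies covering \{0.01, 0.05, 0.2, 0.5\}
#' and several loci whose frequency differs strongly between populations
#' (fuel for the association and clustering stages).
#'
#' @param map probe map the loci are laid on.
#' @param populations character vector of population labels (3 expected).
#' @return list with \code{loci} data.frame and \code{freq} matrix.
#' @export
default_truth_loci <- function(map, populations = c("POP_A", "POP_B", "POP_C")) {
  # probe indices below assume the canonical 217-probe chromosome; they are
  # rescaled proportionally for smaller maps
  span <- function(ch, i1, i2) {
    p <- map$pos[map$chrom == ch]
    n <- length(p)
    j1 <- max(1L, round(i1 * n / 217))
    j2 <- min(n, max(j1 + 1L, round(i2 * n / 217)))
    c(p[j1], p[j2])
  }
  def <- list( # chrom, probe index range, cn, freq in each population
    list("1",  40, 79,  1L, c(0.50, 0.50, 0.05)),
    list("2", 130, 159, 1L, c(0.20, 0.01, 0.01)),
    list("3",  30, 59,  3L, c(0.20, 0.20, 0.20)),
    list("4",  60, 74,  0L, c(0.05, 0.30, 0.30)),
    list("5", 130, 169, 3L, c(0.05, 0.05, 0.40)),
    list("6",  20, 44,  1L, c(0.01, 0.20, 0.20)),
    list("7", 120, 159, 1L, c(0.50, 0.50, 0.50)),
    list("8",  40, 63,  3L, c(0.20, 0.01, 0.01)),
    list("9", 130, 144, 0L, c(0.01, 0.01, 0.01)),
    list("10", 10, 24,  1L, c(0.20, 0.20, 0.20))
  )
  loci <- do.call(rbind, lapply(def, function(d) {
    s <- span(d[[1]], d[[2]], d[[3]])
    data.frame(chrom = d[[1]], start = s[1], end = s[2], cn = d[[4]],
               stringsAsFactors = FALSE)
  }))
  freq <- do.call(rbind, lapply(def, function(d)
    rep_len(d[[5]], length(populations))))
  colnames(freq) <- populations
  list(loci = loci, freq = freq)
}

#' Simulate a complete multi-population cohort
#'
#' One-call wrapper producing the bundled study scenario: a probe map,
#' sample manifest, spiked truth CNVs and per-sample LRR/BAF signal tables.
#'
#' @param populations named integer vector of samples per population.
#' @param n_probes_per_chrom probes per chromosome.
#' @param loci,freq spiked loci and their per-population frequencies;
#'   defaults to [default_truth_loci()] on the generated map. Pass a
#'   zero-row \code{loci} for a pure-noise cohort.
#' @param model [signal_model()].
#' @param seed integer RNG seed controlling every draw.
#' @return list with \code{map, manifest, truth, carriers, signals, model}.
#' @export
simulate_cohort <- function(populations = c(POP_A = 50L, POP_B = 50L, POP_C = 50L),
                            n_probes_per_chrom = 217L,
                            loci = NULL, freq = NULL,
                            model = signal_model(), seed = 1L) {
  map <- make_probe_map(n_probes_per_chrom, seed = seed)
  if (is.null(loci)) {
    d <- default_truth_loci(map, names(populations))
    loci <- d$loci
    freq <- d$freq
  }
  spikes <- spike_cnvs(map, populations, loci, freq, seed = seed + 1L)
  signals <- emit_signals(map, spikes, model, seed = seed + 2L)
  list(map = map, manifest = spikes$manifest, truth = spikes$truth,
       carriers = spikes$carriers, signals = signals, model = model)
}
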