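#' Two-group permutation test of CNV carrier frequency
#'
#' The observed statistic is the absolute carrier-frequency difference.
#' The null is generated by permuting group labels over the pooled carrier
#' indicator vector, which for a two-group comparison is equivalent to
#' drawing the first group's carrier count from a hypergeometric
#' distribution; the empirical p-value is (b+1)/(n_perm+1) where b counts
#' permutations with a statistic at least as large as observed. A locus is
#' flagged significant at \code{p < sig_threshold} or at the attainable
#' floor \code{p = 1/(n_perm+1)}.
#'
#' @param carriers_1,n_1 carrier count and total for group 1.
#' @param carriers_2,n_2 carrier count and total for group 2.
#' @param n_perm number of permutations (default 5000).
#' @param seed optional RNG seed.
#' @param sig_threshold significance cutoff on the empirical p-value.
#' @return list \code{carriers_1, n_1, carriers_2, n_2, freq_1, freq_2,
#'   statistic, p_value, significant}.
#' @export
permutation_association <- function(carriers_1, n_1, carriers_2, n_2,
                                    n_perm = 5000L, seed = NULL,
                                    sig_threshold = 2e-4) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  stopifnot(carriers_1 >= 0, carriers_2 >= 0,
            carriers_1 <= n_1, carriers_2 <= n_2)
  if (!is.null(seed)) set.seed(seed)
  f1 <- carriers_1 / n_1
  f2 <- carriers_2 / n_2
  obs <- abs(f1 - f2)
  m <- carriers_1 + carriers_2
  k1 <- rhyper(n_perm, m, n_1 + n_2 - m, n_1)
  stat <- abs(k1 / n_1 - (m - k1) / n_2)
  b <- sum(stat >= obs - 1e-12)
  p <- (b + 1) / (n_perm + 1)
  list(carriers_1 = carriers_1, n_1 = n_1, carriers_2 = carriers_2, n_2 = n_2,
       freq_1 = f1, freq_2 = f2, statistic = obs, p_value = p,
       significant = p < sig_threshold || p <= 1 / (n_perm + 1))
}

#' Pairwise association scan over loci
#'
#' Runs [permutation_association()] for every locus (row) of two carrier
#' count vectors.
#'
#' @param loci data.frame with at least \code{locus, chrom, start} columns.
#' @param carriers_1,carriers_2 per-locus carrier counts.
#' @param n_1,n_2 group totals.
#' @param n_perm,seed,sig_threshold see [permutation_association()].
#' @return loci with added columns \code{freq_1, freq_2, diff (freq_1 -
#'   freq_2), statistic, p_value, significant}.
#' @export
association_scan <- function(loci, carriers_1, carriers_2, n_1, n_2,
                             n_perm = 5000L, seed = NULL,
                             sig_threshold = 2e-4) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nrow(loci)), function(i)
    permutation_association(carriers_1[i], n_1, carriers_2[i], n_2,
                            n_perm = n_perm, sig_threshold = sig_threshold))
  loci$freq_1 <- vapply(res, `[[`, numeric(1), "freq_1")
  loci$freq_2 <- vapply(res, `[[`, numeric(1), "freq_2")
  loci$diff <- loci$freq_1 - loci$freq_2
  loci$statistic <- vapply(res, `[[`, numeric(1), "statistic")
  loci$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  loci$significant <- vapply(res, `[[`, logical(1), "significant")
  loci
}

#' Select the top differentiated genes across population pairs
#'
#' For each pair's association scan, ranks significant loci by signed
#' frequency difference (reference minus other) and takes the
#' \code{k_each} most positive and \code{k_each} most negative; ties are
#' broken by smaller p-value then genome order. The union across pairs is
#' deduplicated and returned in genome order.
#'
#' @param pair_results named list of [association_scan()] outputs, each
#'   with columns \code{locus, chrom, start, diff, p_value, significant}.
#' @param k_each genes to take in each direction per pair (default 10).
#' @return data.frame of unique selected loci in (chrom, start) order.
#' @export
top_gene_selection <- function(pair_results, k_each = 10L) {
  picked <- lapply(pair_results, function(res) {
    sig <- res[res$significant, , drop = FALSE]
    if (!nrow(sig)) return(sig)
    ord_key <- order(-sig$diff, sig$p_value, chrom_order(sig$chrom), sig$start)
    up <- sig[ord_key, , drop = FALSE]
    up <- up[up$diff > 0, , drop = FALSE]
    if (nrow(up) < k_each)
      message("only ", nrow(up), " significant loci with higher frequency")
    dn <- sig[order(sig$diff, sig$p_value, chrom_order(sig$chrom), sig$start), ,
              drop = FALSE]
    dn <- dn[dn$diff < 0, , drop = FALSE]
    if (nrow(dn) < k_each)
      message("only ", nrow(dn), " significant loci with lower frequency")
    rbind(head(up, k_each), head(dn, k_each))
  })
  all <- do.call(rbind, picked)
  if (is.null(all) || !nrow(all)) {
    warning("no significant loci in any pair")
    return(all)
  }
  all <- all[!duplicated(all$locus), , drop = FALSE]
  all <- all[order(chrom_order(all$chrom), all$start), , drop = FALSE]
  rownames(all) <- NULL
  all
}

# Internal: numeric ordering key for chromosome labels ("1" < "2" < ... "X").
chrom_order <- function(chrom) {
  v <- suppressWarnings(as.numeric(chrom))
  v[is.na(v)] <- 100 + as.integer(factor(chrom[is.na(v)]))
  v
}

#' Scale frequency-matrix rows to mean 0, variance 1
#'
#' Each row is centred and divided by its sample SD (n-1 denominator).
#' Constant rows cannot be scaled; they are left centred at 0 and flagged
#' in the \code{constant_rows} attribute.
#'
#' @param m numeric matrix (loci x populations, >= 2 columns).
#' @return scaled matrix with attribute \code{constant_rows} (logical).
#' @export
scale_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns to scale")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0
  out <- (m - mu) / ifelse(const, 1, s)
  attr(out, "constant_rows") <- const
  out
}

#' Ward hierarchical clustering of populations by CNV frequency
#'
#' Euclidean distances between the (scaled) frequency columns, clustered by
#' Ward's minimum-variance criterion. Merge order, heights, leaf order and
#' a Newick rendering of the dendrogram are returned.
#'
#' @param m scaled frequency matrix (loci x populations).
#' @return list \code{hclust} (the stats::hclust object), \code{labels} in
#'   leaf order, \code{merge}, \code{height}, and \code{newick}.
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 populations")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite frequency at locus ",
         paste(rownames(m)[unique(bad[, 1])], collapse = ", "))
  hc <- hclust(dist(t(m)), method = "ward.D2")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = hc$labels[hc$order], merge = hc$merge,
       height = hc$height, newick = nwk)
}

#' Homozygous-deletion bookkeeping at a locus
#'
#' Splits a locus's carriers by zygosity within each population: the total
#' carrier frequency, the homozygous-deletion frequency, and the proportion
#' of carriers that are homozygous (rounded to 3 decimals; undefined when
#' the total is zero).
#'
#' @param zygosity data.frame \code{sample_id, class} with class in
#'   \{"HOMDEL", "HETDEL"\} — one row per carrier at the locus.
#' @param manifest sample manifest.
#' @return data.frame \code{population, total_freq, homdel_freq,
#'   proportion}.
#' @export
homdel_bookkeeping <- function(zygosity, manifest) {
  stopifnot(all(zygosity$class %in% c("HOMDEL", "HETDEL")))
  pop_of <- manifest$population[match(zygosity$sample_id, manifest$sample_id)]
  if (any(is.na(pop_of))) stop("carrier(s) missing from manifest")
  out <- lapply(unique(manifest$population), function(p) {
    n <- sum(manifest$population == p)
    z <- zygosity[pop_of == p, , drop = FALSE]
    z <- z[order(z$class != "HOMDEL"), , drop = FALSE]  # HOMDEL wins a tie
    z <- z[!duplicated(z$sample_id), , drop = FALSE]
    total <- nrow(z) / n
    hom <- sum(z$class == "HOMDEL") / n
    data.frame(population = p, total_freq = total, homdel_freq = hom,
               proportion = homdel_proportion(total, hom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proportion of carriers that are homozygous deletions
#'
#' @param total_freq,homdel_freq per-population frequencies.
#' @return \code{round(homdel_freq / total_freq, 3)}; NA where the total is
#'   zero.
#' @export
homdel_proportion <- function(total_freq, homdel_freq) {
  ifelse(total_freq > 0, round(homdel_freq / total_freq, 3), NA_real_)
}
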