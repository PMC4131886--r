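#' Parameters of the four-state copy-number HMM
#'
#' States are HOMDEL (copy number 0), HETDEL (1), NORMAL (2) and DUP (3 or
#' more). Each state emits LRR ~ Normal(mean, sd) and BAF from a
#' state-specific genotype-cluster mixture whose weights depend on the probe
#' PFB. Transitions decay with inter-probe distance: the off-diagonal mass
#' at distance d is \code{p_off * (1 - exp(-d / D))}, split evenly among the
#' other three states, so adjacent probes almost surely share a state and
#' distant probes approach a fixed leaving probability.
#'
#' @param lrr_mean,lrr_sd per-state LRR Normal parameters, indexed by copy
#'   number 0..3.
#' @param baf_sd SD of each BAF genotype cluster.
#' @param p_off baseline off-diagonal transition mass (in (0, 0.5)).
#' @param D distance scale in bp of the transition decay.
#' @return object of class \code{hmm_params}.
#' @export
hmm_params <- function(lrr_mean = c(-3.5, -0.66, 0, 0.40),
                       lrr_sd = c(1.3, 0.25, 0.18, 0.20),
                       baf_sd = 0.03, p_off = 1e-4, D = 1e5) {
  stopifnot(length(lrr_mean) == 4, length(lrr_sd) == 4, all(lrr_sd > 0),
            p_off > 0, p_off < 0.5, D > 0, baf_sd > 0)
  structure(list(states = names(CN_CLASSES), lrr_mean = lrr_mean,
                 lrr_sd = lrr_sd, baf_sd = baf_sd, p_off = p_off, D = D),
            class = "hmm_params")
}

# Internal: BAF cluster centres and PFB-dependent weights for one state.
baf_mixture <- function(state, pfb) {
  p <- pfb
  switch(state,
    HETDEL = list(centers = c(0, 1), w = cbind(1 - p, p)),
    NORMAL = list(centers = c(0, 0.5, 1),
                  w = cbind((1 - p)^2, 2 * p * (1 - p), p^2)),
    DUP = list(centers = c(0, 1/3, 2/3, 1),
               w = cbind((1 - p)^3, 3 * (1 - p)^2 * p, 3 * (1 - p) * p^2, p^3)),
    stop("no BAF mixture for state ", state))
}

# Internal: BAF log-density under one state, vectorized over probes.
# Values exactly 0 or 1 are treated as the truncated-cluster point mass
# (all mixture mass falling at or beyond the boundary).
baf_loglik <- function(baf, pfb, state, params) {
  if (state == "HOMDEL") return(rep(0, length(baf)))  # uniform on [0,1]
  mix <- baf_mixture(state, pfb)
  s <- params$baf_sd
  dens <- numeric(length(baf))
  interior <- baf > 0 & baf < 1
  for (k in seq_along(mix$centers)) {
    ck <- mix$centers[k]
    wk <- mix$w[, k]
    dens <- dens + wk * ifelse(interior, dnorm(baf, ck, s),
                               ifelse(baf <= 0, pnorm(0, ck, s),
                                      pnorm(1, ck, s, lower.tail = FALSE)))
  }
  log(pmax(dens, 1e-300))
}

#' Per-probe emission log-likelihood
#'
#' Sum of the LRR Normal log-density and the BAF mixture log-density for a
#' given copy-number state. For the NORMAL state the heterozygote cluster
#' weight is \code{2 * pfb * (1 - pfb)} with homozygote weights
#' \code{(1-pfb)^2} and \code{pfb^2}; HETDEL clusters at \{0, 1\} with
#' weights \code{(1 - pfb, pfb)}; HOMDEL BAF is uniform on \[0, 1\]; DUP
#' clusters at \{0, 1/3, 2/3, 1\} with trisomic Hardy-Weinberg weights.
#'
#' @param lrr,baf,pfb numeric vectors (recycled to common length).
#' @param state one of "HOMDEL", "HETDEL", "NORMAL", "DUP".
#' @param params [hmm_params()].
#' @return numeric vector of log-densities.
#' @export
emission_loglik <- function(lrr, baf, pfb, state, params = hmm_params()) {
  state <- match.arg(state, names(CN_CLASSES))
  if (any(baf < 0 | baf > 1)) stop("baf must lie in [0, 1]")
  cn <- CN_CLASSES[[state]]
  dnorm(lrr, params$lrr_mean[cn + 1L], params$lrr_sd[cn + 1L], log = TRUE) +
    baf_loglik(baf, pfb, state, params)
}

#' Distance-dependent transition matrix
#'
#' @param distance_bp positive inter-probe distance in bp.
#' @param params [hmm_params()].
#' @return 4x4 row-stochastic matrix (rows/cols ordered HOMDEL, HETDEL,
#'   NORMAL, DUP).
#' @export
transition_matrix <- function(distance_bp, params = hmm_params()) {
  stopifnot(distance_bp > 0)
  m <- params$p_off * (1 - exp(-distance_bp / params$D))
  A <- matrix(m / 3, 4, 4, dimnames = list(params$states, params$states))
  diag(A) <- 1 - m
  A
}

# Internal: Viterbi decoding of one chromosome. emis is n x 4 (log), dist
# the n-1 inter-probe distances. Ties are broken toward NORMAL (state 3).
viterbi_decode <- function(emis, dist, params) {
  n <- nrow(emis)
  k <- 4L
  NORMAL <- 3L
  log_init <- log(c(params$p_off, params$p_off, 1 - 3 * params$p_off, params$p_off))
  v <- log_init + emis[1, ]
  ptr <- matrix(NA_integer_, n, k)
  if (n > 1) {
    for (t in 2:n) {
      m <- params$p_off * (1 - exp(-dist[t - 1] / params$D))
      l_stay <- log(1 - m)
      l_move <- log(m / 3)
      vnew <- numeric(k)
      for (s in 1:k) {
        cand <- v + l_move
        cand[s] <- v[s] + l_stay
        best <- max(cand)
        # tie-break toward NORMAL, else lowest state index
        from <- which(cand >= best - 1e-12)
        from <- if (NORMAL %in% from) NORMAL else from[1]
        ptr[t, s] <- from
        vnew[s] <- cand[from] + emis[t, s]
      }
      v <- vnew
    }
  }
  best <- max(v)
  last <- which(v >= best - 1e-12)
  last <- if (NORMAL %in% last) NORMAL else last[1]
  path <- integer(n)
  path[n] <- last
  if (n > 1) for (t in n:2) path[t - 1] <- ptr[t, path[t]]
  list(path = path, logp = v[last])
}

#' HMM CNV calling by Viterbi decoding
#'
#' Decodes the most likely copy-number state path per chromosome and emits
#' each maximal run of non-NORMAL states as a CNV call spanning the first to
#' the last probe of the run. The call score is the summed per-probe
#' log-likelihood margin of the decoded state over the NORMAL state.
#'
#' @param signal one sample's signal data.frame
#'   (\code{probe_id, chrom, pos, lrr, baf}).
#' @param map probe map supplying \code{pfb} (matched by \code{probe_id}).
#' @param params [hmm_params()].
#' @param sample_id id recorded in the output calls.
#' @return calls data.frame (\code{sample_id, chrom, start, end, cn,
#'   n_probes, score, source = "HMM"}).
#' @export
viterbi_call <- function(signal, map, params = hmm_params(),
                         sample_id = "sample") {
  pfb <- map$pfb[match(signal$probe_id, map$probe_id)]
  if (any(is.na(pfb))) stop("probes in signal missing from map")
  calls <- list()
  for (ch in unique(signal$chrom)) {
    idx <- which(signal$chrom == ch)
    if (length(idx) < 2) {
      warning("chromosome ", ch, " has fewer than 2 probes; skipped")
      next
    }
    idx <- idx[order(signal$pos[idx])]
    emis <- vapply(names(CN_CLASSES), function(st)
      emission_loglik(signal$lrr[idx], signal$baf[idx], pfb[idx], st, params),
      numeric(length(idx)))
    dec <- viterbi_decode(emis, diff(signal$pos[idx]), params)
    st <- dec$path
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values != 3L)) {
      pr <- starts[seg]:ends[seg]
      cn <- r$values[seg] - 1L              # state index -> copy number
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start = signal$pos[idx[pr[1]]], end = signal$pos[idx[pr[length(pr)]]],
        cn = cn, n_probes = length(pr),
        score = sum(emis[pr, r$values[seg]] - emis[pr, 3L]),
        source = "HMM", stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_calls())
  do.call(rbind, calls)
}
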