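# Independent literal-formula oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its printed definition with
# naive arithmetic, and never call the package functions they check.

# TMM factor for one sample against a reference, straight from the recipe:
# M/A values on library-scaled counts, double trimming, precision weights.
oracle_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  nn <- length(m)
  lo_m <- floor(nn * trim_m) + 1; hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * trim_a) + 1; hi_a <- nn + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
           rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# Audic-Claverie: direct log-space summation of the printed conditional
# probability p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))
oracle_ac_logpmf <- function(y, x, n1, n2) {
  y * log(n2 / n1) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log(1 + n2 / n1)
}

oracle_ac_p <- function(x, y, n1, n2, y_max = NULL) {
  if (is.null(y_max)) y_max <- max(50L, 20L * (x + y + 5L))
  lp <- oracle_ac_logpmf(0:y_max, x, n1, n2)
  logsum <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  lo <- logsum(lp[1:(y + 1)])                 # P(Y <= y)
  hi <- logsum(lp[(y + 1):(y_max + 1)])       # P(Y >= y)
  min(1, 2 * min(exp(lo), exp(hi)))
}

# hypergeometric upper tail by exhaustive enumeration of C(K,i)C(N-K,n-i)
oracle_hyper_p <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Borda median aggregation, literal: median rank per gene, sort
oracle_borda <- function(lists) {
  universe <- Reduce(intersect, lists)
  med <- sapply(universe, function(g)
    stats::median(sapply(lists, function(l) match(g, l))))
  mn <- sapply(universe, function(g)
    mean(sapply(lists, function(l) match(g, l))))
  universe[order(med, mn, universe)]
}

# small helper: a matched two-phase count dataset with given per-gene
# log2 means per phase (no confounder), deterministic Poisson-free option
toy_count_dataset <- function(log2_g, log2_s, levels = c("l1", "l2"),
                              exact = TRUE, seed = 1) {
  set.seed(seed)
  meta <- expand.grid(confounder_level = levels, phase = c("G", "S"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- paste0(meta$confounder_level, "_", meta$phase)
  mu <- cbind(sapply(seq_len(nrow(meta)), function(i)
    2^(if (meta$phase[i] == "G") log2_g else log2_s)))
  counts <- if (exact) round(mu) else matrix(stats::rpois(length(mu), mu),
                                             nrow(mu))
  rownames(counts) <- paste0("g", seq_along(log2_g))
  expression_dataset(counts, meta, kind = "counts")
}
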