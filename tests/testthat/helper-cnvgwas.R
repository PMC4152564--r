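# Shared helpers: independent oracles and small builders used across tests.

# Brute-force Benjamini-Hochberg: sorted p_i * m / i with a cumulative
# minimum from the largest p down, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive pooled sum-of-squares gain of splitting rows 1..k vs (k+1)..m,
# missing-aware, used as the exhaustive-search segmentation oracle.
split_gain_oracle <- function(x, k) {
  per_sample <- vapply(seq_len(ncol(x)), function(s) {
    v <- x[, s]
    ss <- function(idx) {
      vv <- v[idx][!is.na(v[idx])]
      if (length(vv) == 0) return(0)
      sum((vv - mean(vv))^2)
    }
    ss(seq_len(nrow(x))) - ss(seq_len(k)) - ss((k + 1):nrow(x))
  }, numeric(1))
  sum(per_sample)
}

best_split_oracle <- function(x, min_markers = 3) {
  m <- nrow(x)
  ks <- seq(min_markers, m - min_markers)
  gains <- vapply(ks, function(k) split_gain_oracle(x, k), numeric(1))
  list(k = ks[which.max(gains)], gain = max(gains))
}

# Direct evaluation of the two-locus LD formulas, independent of the
# package path (no shared code).
ld_oracle <- function(f) {
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  D <- f[1] - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  c(D = D,
    Dprime = if (D == 0) 0 else abs(D) / dmax,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Direct gamete counting when no double heterozygotes are present.
gamete_count_oracle <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  stopifnot(!any(g1 == 1 & g2 == 1))
  n_A <- function(g) c(`0` = 0, `1` = 1, `2` = 2)[as.character(g)]
  counts <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_along(g1)) {
    a <- g1[i]; b <- g2[i]
    if (a == 1 && b == 1) stop("ambiguous")
    # with at most one heterozygous locus the two haplotypes are determined
    # (when one locus is het, both phasings give the same gamete multiset)
    ha <- if (a == 0) c(0, 0) else if (a == 2) c(1, 1) else c(1, 0)
    hb <- if (b == 0) c(0, 0) else if (b == 2) c(1, 1) else c(1, 0)
    for (h in 1:2) {
      g <- paste0(ifelse(ha[h] == 1, "A", "a"), ifelse(hb[h] == 1, "B", "b"))
      counts[g] <- counts[g] + 1
    }
  }
  counts / sum(counts)
}

# dosage matrix -> signed CNV dose codes
state_dose <- function(states) {
  d <- matrix(0, nrow(states), ncol(states), dimnames = dimnames(states))
  d[states == "loss"] <- -1
  d[states == "gain"] <- 1
  d[is.na(states)] <- NA
  d
}

# tiny marker map builder: m markers, one chromosome, fixed spacing
toy_map <- function(m, chrom = "chr1", spacing = 1000L, gc = NULL) {
  tibble::tibble(marker = sprintf("m%03d", seq_len(m)), chrom = chrom,
                 pos = as.integer(seq_len(m) * spacing),
                 gc = gc %||% (0.3 + 0.4 * (seq_len(m) %% 7) / 7))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
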