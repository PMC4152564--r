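# Two-locus LD machinery. Genotypes are unphased allele dosages 0/1/2; the
# only phase ambiguity is the double heterozygote, resolved by EM.

# 3x3 genotype count table from two dosage vectors (complete cases only)
genotype_counts <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2)
    tab[i + 1, j + 1] <- sum(g1[keep] == i & g2[keep] == j)
  tab
}

# haplotype-pair probabilities of the 9 genotype cells given hap freqs
# order of freqs: AB, Ab, aB, ab  (A/B = allele counted by the dosage)
cell_probs <- function(f) {
  pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
  m <- matrix(0, 3, 3)
  m[3, 3] <- pAB^2
  m[3, 2] <- 2 * pAB * pAb
  m[3, 1] <- pAb^2
  m[2, 3] <- 2 * pAB * paB
  m[2, 2] <- 2 * pAB * pab + 2 * pAb * paB
  m[2, 1] <- 2 * pAb * pab
  m[1, 3] <- paB^2
  m[1, 2] <- 2 * paB * pab
  m[1, 1] <- pab^2
  m
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased dosages. Only the double heterozygote is phase-ambiguous; the EM
#' iterates the expected phase split until the largest frequency change is
#' below `tol` (default 1e-10) or 1000 iterations. A monomorphic locus makes
#' LD undefined; the result is flagged non-informative.
#'
#' @param g1,g2 Dosage vectors (0/1/2, `NA` allowed).
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A list: `freqs` (named AB, Ab, aB, ab; sums to 1), `loglik`
#'   (trace over iterations), `n` (complete individuals), `informative`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  tab <- genotype_counts(g1, g2)
  n <- sum(tab)
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  informative <- n >= 10 && pA > 0 && pA < 1 && pB > 0 && pB < 1
  # gamete counts fixed by unambiguous cells; double het split by EM
  base <- c(AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
            Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
            aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  dh <- tab[2, 2]
  f <- rep(0.25, 4)
  names(f) <- c("AB", "Ab", "aB", "ab")
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (dh > 0 && denom > 0) f[1] * f[4] / denom else 0.5
    new <- base + dh * c(w, 1 - w, 1 - w, w)
    new <- new / sum(new)
    pr <- cell_probs(new)
    ll <- c(ll, sum(tab[pr > 0] * log(pr[pr > 0])))
    if (max(abs(new - f)) < tol) { f <- new; break }
    f <- new
  }
  list(freqs = f, loglik = ll, n = n, informative = informative)
}

#' LD statistics from haplotype frequencies
#'
#' `D = p(AB) - p(A)p(B)`; `D'` is `|D|` over its frequency-constrained
#' maximum (`min(p(A)p(b), p(a)p(B))` when D > 0, else
#' `min(p(A)p(B), p(a)p(b))`); `r^2 = D^2 / (p(A)p(a)p(B)p(b))`.
#'
#' @param freqs Numeric length-4 vector (AB, Ab, aB, ab) summing to 1, or
#'   the list returned by [em_haplotype_freqs()].
#' @return One-row tibble: `D`, `Dprime`, `r2`, `informative`.
#' @export
ld_from_freqs <- function(freqs) {
  if (is.list(freqs)) freqs <- freqs$freqs
  if (abs(sum(freqs) - 1) > 1e-6) stop_bad_arg("haplotype frequencies must sum to 1")
  pA <- freqs[1] + freqs[2]; pB <- freqs[1] + freqs[3]
  qa <- 1 - pA; qb <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(tibble::tibble(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                          informative = FALSE))
  D <- freqs[1] - pA * pB
  Dmax <- if (D > 0) min(pA * qb, qa * pB) else min(pA * pB, qa * qb)
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * qa * pB * qb)
  tibble::tibble(D = unname(D), Dprime = unname(Dprime), r2 = unname(r2),
                 informative = TRUE)
}

#' Pairwise LD between two markers
#'
#' Convenience wrapper: EM haplotype frequencies then [ld_from_freqs()].
#'
#' @inheritParams em_haplotype_freqs
#' @return One-row tibble as from [ld_from_freqs()] plus `n`.
#' @export
ld_pair <- function(g1, g2) {
  em <- em_haplotype_freqs(g1, g2)
  out <- if (em$informative) ld_from_freqs(em$freqs)
         else tibble::tibble(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                             informative = FALSE)
  mutate(out, n = em$n)
}

#' Likelihood-based confidence interval for D'
#'
#' The genotype-table likelihood is profiled over D' on a grid of `step` in
#' \[0, 1\], with allele frequencies held at their sample MLEs and the sign
#' of D taken from the EM estimate (D' itself is sign-free). The normalised
#' likelihood mass over the grid is treated as a density; `ci_low` and
#' `ci_high` are its 5th and 95th percentiles. This is the interval the
#' Gabriel-criteria block definition consumes.
#'
#' @inheritParams em_haplotype_freqs
#' @param step Grid resolution (default 0.001).
#' @return A list: `ci_low`, `ci_high`, `grid`, `mass` (normalised, sums to
#'   1), `informative`.
#' @export
dprime_ci <- function(g1, g2, step = 0.001) {
  em <- em_haplotype_freqs(g1, g2)
  if (!em$informative)
    return(list(ci_low = NA_real_, ci_high = NA_real_, grid = numeric(0),
                mass = numeric(0), informative = FALSE))
  tab <- genotype_counts(g1, g2)
  pA <- em$freqs[1] + em$freqs[2]
  pB <- em$freqs[1] + em$freqs[3]
  D_hat <- em$freqs[1] - pA * pB
  # orient locus 2 so the ML D is non-negative; D' is unchanged
  if (D_hat < 0) {
    tab <- tab[, 3:1]
    pB <- 1 - pB
  }
  qa <- 1 - pA; qb <- 1 - pB
  Dmax <- min(pA * qb, qa * pB)
  grid <- seq(0, 1, by = step)
  counts <- as.numeric(tab)  # column-major: g1 runs fastest
  eps <- 1e-12
  D <- grid * Dmax
  f1 <- pmax(pA * pB + D, eps)  # AB
  f2 <- pmax(pA * qb - D, eps)  # Ab
  f3 <- pmax(qa * pB - D, eps)  # aB
  f4 <- pmax(qa * qb + D, eps)  # ab
  # genotype-cell probabilities in the count layout
  M <- cbind(f4^2, 2 * f2 * f4, f2^2,
             2 * f3 * f4, 2 * f1 * f4 + 2 * f2 * f3, 2 * f1 * f2,
             f3^2, 2 * f1 * f3, f1^2)
  ll <- as.numeric(log(pmax(M, eps)) %*% counts)
  w <- exp(ll - max(ll))
  mass <- w / sum(w)
  cdf <- cumsum(mass)
  list(ci_low = grid[which(cdf >= 0.05)[1]],
       ci_high = grid[which(cdf >= 0.95)[1]],
       grid = grid, mass = mass, informative = TRUE)
}

#' Haplotype blocks by the Gabriel confidence-interval criteria
#'
#' A marker pair is in "strong LD" when its D' interval satisfies
#' `ci_low >= strong_low` and `ci_high >= strong_high`, and shows "strong
#' evidence of recombination" when `ci_high < recomb_high`. A contiguous run
#' of markers is a candidate block when, among its informative pairs,
#' strong-LD pairs make up at least `min_strong_frac` of the classified
#' (strong LD + recombination) pairs and at least one strong-LD pair exists.
#' Markers with minor-allele frequency below `maf_min` are ignored as
#' non-informative. Candidate spans are capped at `max_span_bp` (default
#' 1.26 Mb, the longest block reported for this array in Holsteins); blocks
#' are chosen greedily, longest run first, ties to the leftmost start,
#' without overlap.
#'
#' @param geno Dosage matrix, markers (window, genomic order) x samples.
#' @param map_window Marker map rows for the window (same order).
#' @param strong_low,strong_high CI bounds defining strong LD.
#' @param recomb_high CI upper bound defining strong recombination.
#' @param min_strong_frac Minimum strong-LD fraction among classified pairs.
#' @param maf_min Minor-allele-frequency floor for informativeness.
#' @param max_span_bp Maximum allowed block span in bp.
#' @return Tibble of blocks: `block`, `chrom`, `start`, `end` (bp of the
#'   first/last member markers), `first_idx`, `last_idx` (window indices),
#'   `n_markers`, `markers` (list column of member names). Zero rows when no
#'   block qualifies.
#' @export
gabriel_blocks <- function(geno, map_window, strong_low = 0.70,
                           strong_high = 0.98, recomb_high = 0.90,
                           min_strong_frac = 0.95, maf_min = 0.05,
                           max_span_bp = 1.26e6) {
  m <- nrow(geno)
  empty <- tibble::tibble(block = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          first_idx = integer(), last_idx = integer(),
                          n_markers = integer(), markers = list())
  if (m < 2) return(empty)
  if (length(unique(map_window$chrom)) > 1)
    stop_bad_arg("window spans multiple chromosomes")
  maf <- apply(geno, 1, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  informative <- !is.na(maf) & maf >= maf_min
  # pairwise classification: 1 strong LD, -1 recombination, 0 uninformative
  cls <- matrix(0L, m, m)
  inf_idx <- which(informative)
  if (length(inf_idx) >= 2) {
    pairs <- utils::combn(inf_idx, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      # pairs further apart than the span cap can never share a block
      if (map_window$pos[j] - map_window$pos[i] + 1 > max_span_bp) next
      ci <- dprime_ci(geno[i, ], geno[j, ])
      if (!ci$informative) next
      if (ci$ci_low >= strong_low && ci$ci_high >= strong_high)
        cls[i, j] <- cls[j, i] <- 1L
      else if (ci$ci_high < recomb_high)
        cls[i, j] <- cls[j, i] <- -1L
    }
  }
  # candidate runs, longest first, leftmost on ties
  cand <- tidyr::expand_grid(first = seq_len(m), last = seq_len(m)) |>
    filter(.data$last > .data$first,
           map_window$pos[.data$last] - map_window$pos[.data$first] + 1 <= max_span_bp) |>
    mutate(len = .data$last - .data$first + 1L) |>
    arrange(dplyr::desc(.data$len), .data$first)
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    f <- cand$first[r]; l <- cand$last[r]
    if (any(taken[f:l])) next
    sub <- cls[f:l, f:l]
    strong <- sum(sub[upper.tri(sub)] == 1L)
    recomb <- sum(sub[upper.tri(sub)] == -1L)
    if (strong == 0) next
    if (strong / (strong + recomb) < min_strong_frac) next
    taken[f:l] <- TRUE
    blocks[[length(blocks) + 1]] <- tibble::tibble(
      chrom = map_window$chrom[1],
      start = map_window$pos[f], end = map_window$pos[l],
      first_idx = f, last_idx = l, n_markers = l - f + 1L,
      markers = list(map_window$marker[f:l]))
  }
  if (length(blocks) == 0) return(empty)
  dplyr::bind_rows(blocks) |>
    arrange(.data$first_idx) |>
    mutate(block = dplyr::row_number(), .before = 1)
}

#' Flanking marker window around a CNV
#'
#' Returns the `n_flank` nearest markers strictly upstream of the CNV start,
#' every marker inside \[start, end\], and the `n_flank` nearest strictly
#' downstream of the end, truncated silently at chromosome boundaries. The
#' default of 25 markers per side corresponds, at the ~50 kb spacing of the
#' 54K bovine array, to the longest haplotype block reported for Holsteins
#' (1.26 Mb).
#'
#' @param cnv One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param map Marker map.
#' @param n_flank Markers per side.
#' @return Tibble of window markers with a `role` column
#'   (`upstream` / `inside` / `downstream`), sorted by position.
#' @export
flank_window <- function(cnv, map, n_flank = 25) {
  chrom_map <- filter(map, .data$chrom == cnv$chrom) |> arrange(.data$pos)
  if (nrow(chrom_map) == 0)
    stop_bad_arg("CNV chromosome '", cnv$chrom, "' absent from map")
  up <- filter(chrom_map, .data$pos < cnv$start) |> tail(n_flank) |>
    mutate(role = "upstream")
  inside <- filter(chrom_map, .data$pos >= cnv$start, .data$pos <= cnv$end) |>
    mutate(role = "inside")
  down <- filter(chrom_map, .data$pos > cnv$end) |> head(n_flank) |>
    mutate(role = "downstream")
  dplyr::bind_rows(up, inside, down)
}
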