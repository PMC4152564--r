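test_that("EM with no ambiguity equals direct gamete counting", {
  # all AABB homozygotes
  em <- em_haplotype_freqs(rep(2, 20), rep(2, 20))
  expect_equal(unname(em$freqs), c(1, 0, 0, 0))
  # mixed data without double heterozygotes
  set.seed(24)
  for (rep in 1:5) {
    g1 <- sample(0:2, 40, replace = TRUE)
    g2 <- sample(0:2, 40, replace = TRUE)
    g2[g1 == 1 & g2 == 1] <- 0
    em <- em_haplotype_freqs(g1, g2)
    expect_equal(em$freqs, gamete_count_oracle(g1, g2), tolerance = 1e-8)
  }
})

test_that("EM frequencies are a simplex and the log-likelihood is monotone", {
  set.seed(19)
  for (rep in 1:10) {
    g1 <- rbinom(60, 2, runif(1, 0.2, 0.8))
    g2 <- rbinom(60, 2, runif(1, 0.2, 0.8))
    em <- em_haplotype_freqs(g1, g2)
    expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
    expect_true(all(em$freqs >= 0))
    if (length(em$loglik) > 1)
      expect_true(all(diff(em$loglik) >= -1e-9))
  }
})

test_that("LD statistics follow the standard formulas", {
  # independent loci
  ind <- ld_from_freqs(c(0.35 * 0.6, 0.35 * 0.4, 0.65 * 0.6, 0.65 * 0.4))
  expect_equal(ind$D, 0, tolerance = 1e-12)
  expect_equal(ind$Dprime, 0)
  expect_equal(ind$r2, 0, tolerance = 1e-12)
  # complete LD, two haplotypes only
  comp <- ld_from_freqs(c(0.5, 0, 0, 0.5))
  expect_equal(comp$Dprime, 1)
  expect_equal(comp$r2, 1)
  # the worked example
  ex <- ld_from_freqs(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(ex$D, 0.15)
  expect_equal(ex$Dprime, 0.6)
  expect_equal(ex$r2, 0.36)
  expect_error(ld_from_freqs(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("ld_from_freqs matches direct evaluation over a frequency grid", {
  grid <- seq(0.05, 0.9, by = 0.05)
  for (f1 in grid) for (f2 in grid) {
    f3 <- (1 - f1 - f2) * 0.3
    f4 <- 1 - f1 - f2 - f3
    if (any(c(f3, f4) < 0.01)) next
    f <- c(f1, f2, f3, f4)
    got <- ld_from_freqs(f)
    want <- ld_oracle(f)
    expect_equal(got$D, unname(want["D"]), tolerance = 1e-12)
    expect_equal(got$Dprime, unname(want["Dprime"]), tolerance = 1e-12)
    expect_equal(got$r2, unname(want["r2"]), tolerance = 1e-12)
  }
})

test_that("EM agrees with enumeration on tiny unambiguous genotype tables", {
  # all 3x3 tables with n <= 6, no double heterozygote, both loci polymorphic
  combos <- expand.grid(replicate(9, 0:2, simplify = FALSE))
  combos <- combos[rowSums(combos) >= 2 & rowSums(combos) <= 6, ]
  combos <- combos[combos[, 5] == 0, ]   # cell (g1=1, g2=1)
  set.seed(1)
  combos <- combos[sample(nrow(combos), 300), ]
  for (r in seq_len(nrow(combos))) {
    tab <- matrix(as.numeric(combos[r, ]), 3, 3)
    g1 <- rep(rep(0:2, 3), as.numeric(combos[r, ]))
    g2 <- rep(rep(0:2, each = 3), as.numeric(combos[r, ]))
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    em <- em_haplotype_freqs(g1, g2)
    expect_equal(em$freqs, gamete_count_oracle(g1, g2), tolerance = 1e-8)
  }
})

test_that("monomorphic loci are flagged non-informative", {
  em <- em_haplotype_freqs(rep(0, 30), rbinom(30, 2, 0.5))
  expect_false(em$informative)
  ld <- ld_pair(rep(0, 30), rbinom(30, 2, 0.5))
  expect_true(is.na(ld$Dprime))
  expect_false(ld$informative)
})

test_that("D' confidence interval concentrates at 1 under complete LD", {
  # deterministic genotype counts: only AB and ab haplotypes, n = 200
  g1 <- c(rep(2, 50), rep(1, 100), rep(0, 50))
  g2 <- c(rep(2, 50), rep(1, 100), rep(0, 50))
  ci <- dprime_ci(g1, g2)
  expect_gte(ci$ci_low, 0.9)
  expect_equal(ci$ci_high, 1.0)
  expect_equal(sum(ci$mass), 1, tolerance = 1e-12)
})

test_that("the D' interval narrows with sample size", {
  make <- function(n) {
    # same composition at both sizes: 70% parallel homozygotes, 30% repulsion
    k <- n / 10
    list(g1 = c(rep(2, 4 * k), rep(0, 4 * k), rep(2, k), rep(0, k)),
         g2 = c(rep(2, 4 * k), rep(0, 4 * k), rep(0, k), rep(2, k)))
  }
  small <- do.call(dprime_ci, make(20))
  large <- do.call(dprime_ci, make(500))
  expect_lt(large$ci_high - large$ci_low, small$ci_high - small$ci_low)
})

test_that("two markers in complete LD form one block", {
  n <- 100
  g <- rbind(m1 = c(rep(2, 30), rep(1, 40), rep(0, 30)),
             m2 = c(rep(2, 30), rep(1, 40), rep(0, 30)))
  mapw <- tibble::tibble(marker = c("m1", "m2"), chrom = "chr1",
                         pos = c(1000L, 2000L), gc = 0.4)
  blocks <- gabriel_blocks(g, mapw)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_markers, 2L)
})

test_that("independent markers yield zero blocks", {
  cfg <- sim_config(n_samples = 500, n_markers = 20, founder_pool_size = 50,
                    block_length_range = c(1, 1), cnv_specs = NULL, seed = 23)
  hap <- simulate_haplotypes(cfg)
  blocks <- gabriel_blocks(hap$genotypes, hap$map)
  expect_equal(nrow(blocks), 0)
})

test_that("blocks are non-overlapping, sorted, and span-capped", {
  cfg <- sim_config(n_samples = 200, n_markers = 30, founder_pool_size = 6,
                    block_length_range = c(8, 12), cnv_specs = NULL, seed = 31)
  hap <- simulate_haplotypes(cfg)
  blocks <- gabriel_blocks(hap$genotypes, hap$map)
  expect_gt(nrow(blocks), 0)
  expect_true(all(diff(blocks$first_idx) > 0))
  if (nrow(blocks) > 1)
    expect_true(all(blocks$first_idx[-1] > head(blocks$last_idx, -1)))
  expect_true(all(blocks$end - blocks$start + 1 <= 1.26e6))
})

test_that("flanking windows take 25 markers a side and truncate at ends", {
  map <- toy_map(100, spacing = 1000L)
  # CNV covering markers 41..47 (7 markers)
  cnv <- list(chrom = "chr1", start = 41000L, end = 47000L)
  w <- flank_window(cnv, map)
  expect_equal(nrow(w), 25 + 7 + 25)
  expect_equal(sum(w$role == "inside"), 7)
  expect_true(all(diff(w$pos) > 0))
  # CNV starting at the first marker has no upstream flank
  w2 <- flank_window(list(chrom = "chr1", start = 1000L, end = 5000L), map)
  expect_equal(sum(w2$role == "upstream"), 0)
  # deterministic
  expect_identical(w, flank_window(cnv, map))
  expect_error(flank_window(list(chrom = "chrX", start = 1, end = 2), map),
               "absent from map")
})
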