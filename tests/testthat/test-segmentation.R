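test_that("gc correction removes a constructed GC dependence exactly", {
  map <- toy_map(60)
  # flat intensities stay flat
  zero <- matrix(0, 60, 5, dimnames = list(map$marker, paste0("s", 1:5)))
  expect_equal(unname(gc_correct(zero, map)), unname(zero),
               ignore_attr = TRUE)
  # a pure linear GC wave is removed to numerical zero
  wave <- matrix(rep(2 * map$gc - 1, 3), ncol = 3,
                 dimnames = list(map$marker, paste0("s", 1:3)))
  corr <- gc_correct(wave, map)
  expect_lt(max(abs(corr)), 1e-10)
})

test_that("corrected intensities are orthogonal to GC", {
  set.seed(4)
  map <- toy_map(80)
  x <- matrix(rnorm(80 * 6) + rep(0.5 * map$gc, 6), ncol = 6,
              dimnames = list(map$marker, paste0("s", 1:6)))
  corr <- gc_correct(x, map)
  for (s in 1:6) expect_lt(abs(cor(corr[, s], map$gc)), 1e-8)
  expect_true(attr(corr, "corrected"))
})

test_that("gc correction errors on an all-missing sample and keeps NAs", {
  map <- toy_map(10)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(map$marker, c("s1", "s2")))
  x[3, 1] <- NA
  corr <- gc_correct(x, map)
  expect_true(is.na(corr[3, 1]))
  x[, 2] <- NA
  expect_error(gc_correct(x, map), "all-missing")
})

test_that("a constant window yields a single segment", {
  x <- matrix(0, 100, 50)
  seg <- segment_multivariate(x, n_perm = 200, seed = 1)
  expect_equal(nrow(seg$segments), 1)
  expect_length(seg$breakpoints, 0)
})

test_that("a planted step is segmented within one marker of the truth", {
  set.seed(5)
  n <- 200; m <- 150
  carriers <- seq_len(n) <= 0.2 * n
  x <- matrix(rnorm(m * n, sd = 0.2), m, n)
  x[50:100, carriers] <- x[50:100, carriers] + 1.0
  seg <- segment_multivariate(x, n_perm = 500, seed = 5)
  bp <- seg$breakpoints
  expect_true(any(abs(bp - 50) <= 1))
  expect_true(any(abs(bp - 101) <= 1))
})

test_that("the first split matches the exhaustive-search oracle", {
  set.seed(8)
  for (rep in 1:5) {
    m <- sample(10:30, 1)
    x <- matrix(rnorm(m * 8), m, 8)
    if (rep == 3) x[sample(length(x), 10)] <- NA  # missing-aware too
    got <- cnvgwas:::cpp_best_split(x, 3L)
    want <- best_split_oracle(x, 3)
    expect_equal(got$k, want$k)
    expect_equal(got$gain, want$gain, tolerance = 1e-10)
  }
})

test_that("segments always partition the window", {
  set.seed(12)
  for (rep in 1:3) {
    m <- sample(40:120, 1)
    x <- matrix(rnorm(m * 20), m, 20)
    x[10:20, 1:5] <- x[10:20, 1:5] + 2
    seg <- segment_multivariate(x, n_perm = 200, seed = rep)
    expect_equal(sum(seg$segments$n_markers), m)
    expect_equal(seg$segments$start_idx[1], 1L)
    expect_equal(seg$segments$end_idx[nrow(seg$segments)], m)
    expect_true(all(seg$segments$start_idx[-1] ==
                      head(seg$segments$end_idx, -1) + 1L))
    expect_true(all(seg$segments$n_markers >= 3))
  }
})

test_that("recovered breakpoints are monotone in step amplitude", {
  m <- 120; n <- 60
  truth <- c(41, 81)
  recovered <- vapply(c(0.05, 0.3, 0.8, 1.5), function(amp) {
    set.seed(99)
    x <- matrix(rnorm(m * n, sd = 0.2), m, n)
    x[41:80, 1:20] <- x[41:80, 1:20] + amp
    seg <- segment_multivariate(x, n_perm = 200, seed = 42)
    sum(vapply(truth, function(b) any(abs(seg$breakpoints - b) <= 1), logical(1)))
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
})

test_that("short windows return a single segment with a warning", {
  x <- matrix(rnorm(4 * 5), 4, 5)
  expect_warning(seg <- segment_multivariate(x), "single segment")
  expect_equal(nrow(seg$segments), 1)
})

test_that("three-state calling uses strict thresholds", {
  expect_equal(call_state(-0.6), "loss")
  expect_equal(call_state(0.0), "neutral")
  expect_equal(call_state(0.5), "neutral")   # boundary is neutral
  expect_equal(call_state(-0.5), "neutral")
  expect_equal(call_state(0.51), "gain")
  expect_true(is.na(call_state(NA_real_)))
  # exhaustive and idempotent over a grid
  grid <- seq(-2, 2, by = 0.01)
  states <- call_state(grid)
  expect_true(all(states %in% c("loss", "neutral", "gain")))
})

test_that("region merging unions overlaps and is order-independent", {
  segs <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr2"),
                         start = c(100L, 150L, 300L, 100L),
                         end = c(200L, 300L, 400L, 120L))
  merged <- merge_regions(segs)
  # chr1: [100,200]+[150,300] overlap, and [300,400] shares bp 300 -> one region
  expect_equal(nrow(merged), 2)
  chr1 <- dplyr::filter(merged, chrom == "chr1")
  expect_equal(chr1$start, 100L)
  expect_equal(chr1$end, 400L)
  set.seed(77)
  for (i in 1:5) {
    shuffled <- segs[sample(nrow(segs)), ]
    expect_equal(merge_regions(shuffled)$start, merged$start)
    expect_equal(merge_regions(shuffled)$end, merged$end)
  }
  # identical duplicated segments collapse to one region
  expect_equal(nrow(merge_regions(segs[c(1, 1), ])), 1)
  # disjoint stay apart
  dis <- tibble::tibble(chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L))
  expect_equal(nrow(merge_regions(dis)), 2)
})

test_that("frequency filter retains strictly above the threshold", {
  states <- rbind(c(rep("loss", 5), rep("neutral", 95)),
                  c(rep("gain", 3), rep("neutral", 97)),
                  rep("neutral", 100))
  rownames(states) <- paste0("cnv", 1:3)
  colnames(states) <- paste0("s", 1:100)
  gt <- list(states = states,
             means = matrix(0, 3, 100, dimnames = dimnames(states)),
             regions = tibble::tibble(cnv_id = paste0("cnv", 1:3),
                                      chrom = "chr1", start = 1L, end = 10L,
                                      n_markers = 3L,
                                      frequency = c(0.05, 0.03, 0)))
  kept <- frequency_filter(gt, min_freq = 0.04)
  expect_equal(kept$regions$cnv_id, "cnv1")
})

test_that("region length follows the closed-interval convention", {
  expect_equal(region_length(11250157, 11307423), 57267)
  expect_equal(region_length(100, 100), 1)
  expect_equal(region_length(73055503, 75058715), 2003213)
  expect_error(region_length(200, 100), "end must be >= start")
})
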