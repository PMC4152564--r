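#' Correct GC-content intensity waves
#'
#' SNP-array total-intensity tracks drift with local GC content ("waviness").
#' For each sample the least-squares fit of LRR on (gc, gc^2) is subtracted,
#' leaving OLS residuals that are exactly uncorrelated with gc. Missing cells
#' are preserved as missing.
#'
#' @param lrr LRR matrix, markers x samples, rownames matching `map$marker`.
#' @param map Marker map with a `gc` column.
#' @return The corrected matrix with attribute `corrected = TRUE`.
#' @export
gc_correct <- function(lrr, map) {
  check_assay_matrix(lrr, map, "LRR matrix")
  gc <- map$gc[match(rownames(lrr), map$marker)]
  X <- cbind(1, gc, gc^2)
  out <- lrr
  for (s in seq_len(ncol(lrr))) {
    y <- lrr[, s]
    ok <- !is.na(y)
    if (!any(ok)) stop_bad_arg("sample '", colnames(lrr)[s], "' is all-missing")
    fit <- lm.fit(X[ok, , drop = FALSE], y[ok])
    out[ok, s] <- fit$residuals
  }
  attr(out, "corrected") <- TRUE
  out
}

#' Multivariate recursive binary segmentation of a marker window
#'
#' Segments a window of contiguous markers jointly across all samples in two
#' phases. First, recursive binary splitting: at each round the current
#' segment offering the largest reduction in within-segment sum of squares
#' pooled over samples is split at its best position, until `max_segments`
#' is reached, no segment admits a split of at least `min_markers` a side,
#' or no split reduces the pooled sum of squares. Second, pairwise
#' permutation pruning: each boundary between adjacent segments is tested by
#' comparing its pooled gain with the best-split gain under marker-order
#' permutations of the pair's union (add-one convention); the least
#' significant boundary is merged and testing repeats until every remaining
#' adjacent pair has p below `perm_alpha`. Merging least-significant-first
#' lets homogeneous runs coalesce before a genuine boundary between them is
#' retested on the larger, better-resolved union. The split-then-prune order
#' lets interior copy-number bumps be found even when no single binary split
#' of the whole window is itself significant. Missing cells are excluded
#' from segment sums.
#'
#' @param x Numeric matrix, markers (window, in genomic order) x samples.
#' @param min_markers Minimum markers per segment.
#' @param max_segments Maximum segments in the window.
#' @param perm_alpha Significance level for the pairwise permutation test.
#' @param n_perm Number of marker-order permutations per tested split.
#' @param seed Optional integer seed for the permutation stream.
#' @return A list of class `"cnv_segmentation"` with `segments` (tibble:
#'   `segment`, `start_idx`, `end_idx`, `n_markers`), `breakpoints` (marker
#'   indices starting each segment after the first) and `seg_means` (matrix
#'   segments x samples of per-sample segment means; `NA` when fewer than 2
#'   markers are observed).
#' @export
segment_multivariate <- function(x, min_markers = 3, max_segments = 20,
                                 perm_alpha = 0.01, n_perm = 1000,
                                 seed = NULL) {
  if (!is.matrix(x)) stop_bad_arg("x must be a matrix (markers x samples)")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(x)
  segs <- list(c(1L, m))
  if (m < 2 * min_markers) {
    warn("window shorter than 2 * min_markers; returning a single segment")
  } else {
    # phase 1: greedy recursive splitting on the pooled SSE reduction
    repeat {
      if (length(segs) >= max_segments) break
      cand <- purrr::map(segs, function(sg) {
        if (sg[2] - sg[1] + 1 < 2 * min_markers) return(NULL)
        bs <- cpp_best_split(x[sg[1]:sg[2], , drop = FALSE], as.integer(min_markers))
        if (is.na(bs$k)) return(NULL)
        list(seg = sg, k = bs$k, gain = bs$gain)
      })
      cand <- purrr::compact(cand)
      if (length(cand) == 0) break
      best <- cand[[which.max(purrr::map_dbl(cand, "gain"))]]
      if (best$gain <= 1e-12) break
      sg <- best$seg
      cut <- sg[1] + best$k - 1L
      segs <- c(segs[!vapply(segs, identical, logical(1), y = sg)],
                list(c(sg[1], cut)), list(c(cut + 1L, sg[2])))
    }
    # phase 2: pairwise permutation pruning of adjacent boundaries
    segs <- segs[order(vapply(segs, `[`, integer(1), 1))]
    pair_cache <- new.env(parent = emptyenv())
    boundary_p <- function(lo, bnd, hi) {
      key <- paste(lo, bnd, hi, sep = "-")
      if (is.null(pair_cache[[key]])) {
        pt <- cpp_pair_perm(x[lo:hi, , drop = FALSE],
                            as.integer(bnd - lo + 1L),
                            as.integer(min_markers), as.integer(n_perm),
                            perm_alpha)
        pair_cache[[key]] <- pt$p
      }
      pair_cache[[key]]
    }
    # merge the least significant boundary first and re-test: homogeneous
    # neighbours coalesce before a true boundary between them is retested
    while (length(segs) > 1) {
      pvals <- vapply(seq_len(length(segs) - 1), function(i)
        boundary_p(segs[[i]][1], segs[[i]][2], segs[[i + 1]][2]), numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] < perm_alpha) break
      segs[[worst]] <- c(segs[[worst]][1], segs[[worst + 1]][2])
      segs <- segs[-(worst + 1)]
    }
  }
  starts <- sort(vapply(segs, `[`, integer(1), 1))
  ends <- sort(vapply(segs, `[`, integer(1), 2))
  seg_tbl <- tibble::tibble(segment = seq_along(starts),
                            start_idx = starts, end_idx = ends,
                            n_markers = ends - starts + 1L)
  seg_means <- t(vapply(seq_len(nrow(seg_tbl)), function(i) {
    block <- x[seg_tbl$start_idx[i]:seg_tbl$end_idx[i], , drop = FALSE]
    nobs <- colSums(!is.na(block))
    mu <- colMeans(block, na.rm = TRUE)
    mu[nobs < 2] <- NA_real_
    mu
  }, numeric(ncol(x))))
  rownames(seg_means) <- paste0("seg", seg_tbl$segment)
  structure(list(segments = seg_tbl,
                 breakpoints = seg_tbl$start_idx[-1],
                 seg_means = seg_means),
            class = "cnv_segmentation")
}

#' Three-state copy-number call from a segment mean
#'
#' Strict thresholding of the per-sample segment mean LRR: `loss` below
#' `-threshold`, `gain` above `+threshold`, `neutral` otherwise. Values
#' exactly at the threshold call neutral. `NA` means (fewer than 2 observed
#' markers) give `NA` calls.
#'
#' @param segment_mean Numeric vector of segment mean LRR values.
#' @param threshold Call threshold in LRR units (default 0.5).
#' @return Character vector in \{"loss", "neutral", "gain"\} (or `NA`).
#' @export
call_state <- function(segment_mean, threshold = 0.5) {
  if (threshold <= 0) stop_bad_arg("threshold must be positive")
  out <- ifelse(segment_mean < -threshold, "loss",
                ifelse(segment_mean > threshold, "gain", "neutral"))
  out[is.na(segment_mean)] <- NA_character_
  out
}

#' Length of a 1-based closed genomic interval
#'
#' @param start,end Interval bounds, 1-based fully closed.
#' @return `end - start + 1`, in bp.
#' @examples
#' region_length(11250157, 11307423)  # 57267
#' @export
region_length <- function(start, end) {
  if (any(end < start)) stop_bad_arg("interval end must be >= start")
  end - start + 1L
}

#' Merge per-sample variant segments into nonredundant CNV regions
#'
#' Union-merges segments that share at least 1 bp on the same chromosome
#' (closed-interval convention); region bounds are the min start / max end of
#' each merged set. Merging is order-independent.
#'
#' @param segments Tibble with columns `chrom`, `start`, `end` (1-based
#'   closed); extra columns are ignored.
#' @return Tibble of regions: `cnv_id`, `chrom`, `start`, `end`,
#'   `n_segments`.
#' @export
merge_regions <- function(segments) {
  if (nrow(segments) == 0)
    return(tibble::tibble(cnv_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_segments = integer()))
  check_interval(segments$chrom, segments$start, segments$end)
  merged <- segments |>
    group_by(.data$chrom) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(new_run = .data$start > cummax(dplyr::lag(.data$end, default = dplyr::first(.data$end))),
           run = cumsum(dplyr::coalesce(.data$new_run, FALSE))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_segments = dplyr::n(), .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    select(-"run")
  merged |> mutate(cnv_id = paste0("cnv", dplyr::row_number()),
                   .before = 1)
}

#' Genotype CNV regions across samples
#'
#' For each region, computes the per-sample mean of (corrected) LRR over the
#' markers inside the region and calls a three-state genotype. A sample is
#' callable only with at least 2 observed markers in the region.
#'
#' @param lrr (Corrected) LRR matrix, markers x samples.
#' @param map Marker map.
#' @param regions Tibble with `cnv_id`, `chrom`, `start`, `end`.
#' @param threshold Call threshold passed to [call_state()].
#' @return A list with `states` (character matrix regions x samples),
#'   `means` (numeric matrix regions x samples) and `regions` (the input with
#'   `n_markers` and `frequency` columns appended; frequency = non-neutral
#'   fraction among called samples).
#' @export
genotype_regions <- function(lrr, map, regions, threshold = 0.5) {
  check_assay_matrix(lrr, map, "LRR matrix")
  ns <- ncol(lrr)
  states <- matrix(NA_character_, nrow(regions), ns,
                   dimnames = list(regions$cnv_id, colnames(lrr)))
  means <- matrix(NA_real_, nrow(regions), ns,
                  dimnames = list(regions$cnv_id, colnames(lrr)))
  n_markers <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    idx <- which(map$chrom == regions$chrom[i] &
                   map$pos >= regions$start[i] & map$pos <= regions$end[i])
    n_markers[i] <- length(idx)
    if (length(idx) == 0) next
    block <- lrr[map$marker[idx], , drop = FALSE]
    nobs <- colSums(!is.na(block))
    mu <- colMeans(block, na.rm = TRUE)
    mu[nobs < 2] <- NA_real_
    means[i, ] <- mu
    states[i, ] <- call_state(mu, threshold)
  }
  freq <- vapply(seq_len(nrow(regions)), function(i) {
    called <- !is.na(states[i, ])
    if (!any(called)) return(NA_real_)
    mean(states[i, called] != "neutral")
  }, numeric(1))
  regions <- regions |> mutate(n_markers = n_markers, frequency = freq)
  list(states = states, means = means, regions = regions)
}

#' Filter CNV regions by population frequency
#'
#' Frequency is the fraction of called samples with a non-neutral state; a
#' region is retained when frequency strictly exceeds `min_freq`. The default
#' 0.04 follows the 4% reading of the source protocol; pass 0.004 for the
#' 0.4% reading. Regions with no callable sample are dropped with a warning.
#'
#' @param genotyped Output of [genotype_regions()].
#' @param min_freq Retention threshold (exclusive).
#' @return The `genotyped` list with regions, states and means subset to the
#'   retained regions.
#' @export
frequency_filter <- function(genotyped, min_freq = 0.04) {
  regions <- genotyped$regions
  uncalled <- is.na(regions$frequency)
  if (any(uncalled))
    warn(paste0("dropping region(s) with no callable sample: ",
                paste(regions$cnv_id[uncalled], collapse = ", ")))
  keep <- !uncalled & regions$frequency > min_freq
  list(states = genotyped$states[keep, , drop = FALSE],
       means = genotyped$means[keep, , drop = FALSE],
       regions = regions[keep, , drop = FALSE])
}

#' Discover CNV regions from an LRR matrix
#'
#' End-to-end discovery: per-chromosome multivariate segmentation, three-state
#' calling of every segment for every sample, conversion of non-neutral
#' (sample, segment) pairs to genomic intervals, cross-sample union merging,
#' re-genotyping of the merged regions and frequency filtering.
#'
#' @param lrr (Corrected) LRR matrix, markers x samples.
#' @param map Marker map.
#' @inheritParams segment_multivariate
#' @inheritParams frequency_filter
#' @param threshold Three-state call threshold.
#' @return A list as returned by [genotype_regions()], frequency-filtered,
#'   plus `segmentation` (per-chromosome segmentation objects).
#' @export
discover_cnvs <- function(lrr, map, min_markers = 3, max_segments = 20,
                          perm_alpha = 0.01, n_perm = 1000, threshold = 0.5,
                          min_freq = 0.04, seed = NULL) {
  check_assay_matrix(lrr, map, "LRR matrix")
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  seg_list <- list()
  variant_segments <- list()
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    seg <- segment_multivariate(lrr[map$marker[idx], , drop = FALSE],
                                min_markers = min_markers,
                                max_segments = max_segments,
                                perm_alpha = perm_alpha, n_perm = n_perm)
    seg_list[[ch]] <- seg
    st <- apply(seg$seg_means, 2, call_state, threshold = threshold)
    if (is.null(dim(st))) st <- matrix(st, nrow = 1)
    variant <- which(!is.na(st) & st != "neutral", arr.ind = TRUE)
    if (nrow(variant) > 0) {
      variant_segments[[ch]] <- tibble::tibble(
        chrom = ch,
        start = map$pos[idx[seg$segments$start_idx[variant[, 1]]]],
        end = map$pos[idx[seg$segments$end_idx[variant[, 1]]]])
    }
  }
  segments <- dplyr::bind_rows(variant_segments)
  regions <- merge_regions(segments) |> select("cnv_id", "chrom", "start", "end")
  gt <- genotype_regions(lrr, map, regions, threshold = threshold)
  out <- frequency_filter(gt, min_freq = min_freq)
  out$segmentation <- seg_list
  out
}
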