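#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the synthetic-cohort generators. Defaults describe
#' the standing test-bed conditions used throughout the package: 2,000
#' diploid samples on one chromosome of 100 markers spaced 50 kb apart,
#' block-structured LD from a small founder pool, a single deletion
#' polymorphism at 20% carrier frequency whose loss shift (-0.7) straddles
#' the +/-0.5 three-state call threshold under intensity noise of sd 0.2, a
#' mild GC wave, and one trait with a 0.5 SD additive CNV effect and
#' reliabilities between 0.5 and 0.99.
#'
#' @param n_samples Number of diploid individuals.
#' @param n_markers Markers per chromosome.
#' @param n_chromosomes Number of chromosomes (markers are split evenly).
#' @param marker_spacing_bp Distance between adjacent markers, bp.
#' @param founder_pool_size Haplotypes in the per-block founder pool (>= 2).
#'   Pool haplotypes derive from two complementary ancestral haplotypes with
#'   per-marker flip probability `founder_mut_rate`, so small pools give
#'   strong within-block LD.
#' @param block_length_range Min/max planted LD block length, in markers.
#' @param founder_mut_rate Per-marker flip probability for pool haplotypes
#'   beyond the first two ancestors.
#' @param cnv_specs Tibble of planted CNVs: columns `chrom`, `start`, `end`
#'   (bp, 1-based closed), `frequency` (carrier fraction in \[0,1\]) and
#'   `kind` (`"loss"` or `"gain"`).
#' @param lrr_noise_sd Gaussian intensity noise sd (LRR units).
#' @param lrr_shift_loss,lrr_shift_gain LRR shift for carriers of a loss /
#'   gain, in intensity units.
#' @param gc_wave_amplitude Amplitude of the GC-coupled intensity wave: the
#'   wave term is `gc_wave_amplitude * (gc - mean(gc))`.
#' @param effect_table Tibble of additive effects: columns `variant_id`
#'   (a `cnv_specs` id such as `"cnv1"` or a marker name), `trait`, `effect`
#'   (trait SD units per dose; CNV dose is loss = -1, neutral = 0,
#'   gain = +1; SNP dose is the 0/1/2 allele count).
#' @param reliability_range Uniform sampling range for per-animal PTA
#'   reliability, within (0, 1].
#' @param seed Integer master seed; each generator derives its own stream
#'   from it, so output is bit-reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 2000,
                       n_markers = 100,
                       n_chromosomes = 1,
                       marker_spacing_bp = 50000,
                       founder_pool_size = 8,
                       block_length_range = c(8, 12),
                       founder_mut_rate = 0.03,
                       cnv_specs = tibble::tibble(
                         chrom = "chr1",
                         start = 30 * 50000 + 1,
                         end = 40 * 50000,
                         frequency = 0.2,
                         kind = "loss"),
                       lrr_noise_sd = 0.2,
                       lrr_shift_loss = -0.7,
                       lrr_shift_gain = 0.5,
                       gc_wave_amplitude = 0.1,
                       effect_table = tibble::tibble(
                         variant_id = "cnv1", trait = "MY", effect = 0.5),
                       reliability_range = c(0.5, 0.99),
                       seed = 1L) {
  if (founder_pool_size < 2) stop_bad_arg("founder_pool_size must be >= 2")
  if (!is.null(cnv_specs) && nrow(cnv_specs) > 0)
    check_fraction(cnv_specs$frequency, "cnv frequency")
  if (any(reliability_range <= 0) || any(reliability_range > 1))
    stop_bad_arg("reliability_range must lie in (0, 1]")
  if (max(block_length_range) > n_markers)
    stop_bad_arg("n_markers is smaller than the largest LD block")
  structure(list(n_samples = n_samples, n_markers = n_markers,
                 n_chromosomes = n_chromosomes,
                 marker_spacing_bp = marker_spacing_bp,
                 founder_pool_size = founder_pool_size,
                 block_length_range = block_length_range,
                 founder_mut_rate = founder_mut_rate,
                 cnv_specs = cnv_specs,
                 lrr_noise_sd = lrr_noise_sd,
                 lrr_shift_loss = lrr_shift_loss,
                 lrr_shift_gain = lrr_shift_gain,
                 gc_wave_amplitude = gc_wave_amplitude,
                 effect_table = effect_table,
                 reliability_range = reliability_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derived per-generator seeds; offsets keep the three streams independent of
# call order while remaining fully determined by cfg$seed.
sim_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

sim_marker_map <- function(cfg) {
  per_chrom <- rep(cfg$n_markers, cfg$n_chromosomes)
  purrr::map2_dfr(seq_len(cfg$n_chromosomes), per_chrom, function(c, m) {
    idx <- seq_len(m)
    tibble::tibble(
      marker = sprintf("chr%d_m%04d", c, idx),
      chrom = paste0("chr", c),
      pos = as.integer(idx * cfg$marker_spacing_bp - cfg$marker_spacing_bp + 1L),
      # smooth deterministic GC profile, clipped to a realistic array range
      gc = pmin(0.75, pmax(0.25,
        0.45 + 0.12 * sin(2 * pi * idx / 37) + 0.05 * cos(2 * pi * idx / 11))))
  })
}

#' Simulate block-LD genotypes and a marker map
#'
#' Haplotypes are copied block-wise from a small founder pool: markers are
#' partitioned into contiguous blocks (lengths drawn from
#' `block_length_range`), each block carries its own founder pool derived
#' from two complementary ancestral haplotypes, and each individual haplotype
#' picks a founder independently per block. Within-block LD is therefore
#' strong (complete when `founder_pool_size = 2`) and between-block LD is
#' absent by construction. Setting `block_length_range = c(1, 1)` with a
#' large pool yields effectively independent markers.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (0/1/2 dosage matrix, markers x samples),
#'   `map` (marker map tibble) and `blocks` (tibble of planted block spans:
#'   `chrom`, `start_idx`, `end_idx` in within-chromosome marker indices).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 1L))
  map <- sim_marker_map(cfg)
  n <- cfg$n_samples
  geno <- matrix(0L, nrow = nrow(map), ncol = n,
                 dimnames = list(map$marker,
                                 sprintf("s%04d", seq_len(n))))
  blocks <- list()
  offset <- 0L
  for (c in seq_len(cfg$n_chromosomes)) {
    m <- cfg$n_markers
    # partition this chromosome's markers into blocks
    lens <- integer(0)
    lo <- cfg$block_length_range[1]; hi <- cfg$block_length_range[2]
    while (sum(lens) < m) {
      # sample.int guards against sample()'s scalar expansion when lo == hi
      lens <- c(lens, lo + sample.int(hi - lo + 1L, 1L) - 1L)
    }
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - m)
    lens <- lens[lens > 0]
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1) + 1L)
    blocks[[c]] <- tibble::tibble(chrom = paste0("chr", c),
                                  start_idx = as.integer(starts),
                                  end_idx = as.integer(ends))
    for (b in seq_along(lens)) {
      len <- lens[b]
      anc <- sample(c(0L, 1L), len, replace = TRUE)
      pool <- matrix(0L, nrow = len, ncol = cfg$founder_pool_size)
      pool[, 1] <- anc
      if (cfg$founder_pool_size >= 2) pool[, 2] <- 1L - anc
      if (cfg$founder_pool_size > 2) {
        for (f in 3:cfg$founder_pool_size) {
          base <- pool[, 1 + (f %% 2)]
          flip <- runif(len) < cfg$founder_mut_rate
          pool[, f] <- ifelse(flip, 1L - base, base)
        }
      }
      # two founder picks per individual -> dosage
      f1 <- sample.int(cfg$founder_pool_size, n, replace = TRUE)
      f2 <- sample.int(cfg$founder_pool_size, n, replace = TRUE)
      rows <- offset + starts[b]:ends[b]
      geno[rows, ] <- pool[, f1, drop = FALSE] + pool[, f2, drop = FALSE]
    }
    offset <- offset + m
  }
  list(genotypes = geno, map = map, blocks = dplyr::bind_rows(blocks))
}

#' Simulate true CNV carrier states
#'
#' Draws carriers for each planted CNV independently with its configured
#' frequency. States are coded loss = -1, neutral = 0, gain = +1.
#'
#' @param cfg A [sim_config()].
#' @param map Marker map (from [simulate_haplotypes()]).
#' @return A list with `regions` (tibble: `cnv_id`, `chrom`, `start`, `end`,
#'   `kind`, `frequency`, `marker_first`, `marker_last`) and `states`
#'   (integer matrix regions x samples in \{-1, 0, +1\}).
#' @export
simulate_cnv_states <- function(cfg, map) {
  stopifnot(inherits(cfg, "sim_config"))
  specs <- cfg$cnv_specs
  samples <- sprintf("s%04d", seq_len(cfg$n_samples))
  if (is.null(specs) || nrow(specs) == 0) {
    return(list(regions = tibble::tibble(), states = matrix(integer(0), 0, cfg$n_samples,
                                                            dimnames = list(NULL, samples))))
  }
  ov <- specs |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    filter(.data$start <= dplyr::lag(.data$end, default = -Inf)) |>
    ungroup()
  if (nrow(ov) > 0)
    stop_bad_arg("overlapping cnv_specs on one chromosome; truth must be unambiguous")
  set.seed(sim_seed(cfg, 2L))
  regions <- specs |>
    mutate(cnv_id = paste0("cnv", dplyr::row_number())) |>
    rowwise() |>
    mutate(marker_first = {
      idx <- which(map$chrom == .data$chrom & map$pos >= .data$start & map$pos <= .data$end)
      if (length(idx) == 0) stop_bad_arg("cnv_spec ", .data$cnv_id, " spans no markers")
      min(idx)
    },
    marker_last = max(which(map$chrom == .data$chrom & map$pos >= .data$start &
                              map$pos <= .data$end))) |>
    ungroup() |>
    select("cnv_id", "chrom", "start", "end", "kind", "frequency",
           "marker_first", "marker_last")
  states <- matrix(0L, nrow = nrow(regions), ncol = cfg$n_samples,
                   dimnames = list(regions$cnv_id, samples))
  for (i in seq_len(nrow(regions))) {
    carrier <- runif(cfg$n_samples) < regions$frequency[i]
    states[i, carrier] <- if (regions$kind[i] == "loss") -1L else 1L
  }
  list(regions = regions, states = states)
}

#' Simulate a Log R Ratio matrix with embedded CNVs and a GC wave
#'
#' LRR is a 0 baseline plus the carrier state shift over the markers inside
#' each planted CNV, plus a GC-coupled wave
#' `gc_wave_amplitude * (gc - mean(gc))`, plus Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param map Marker map.
#' @param truth Output of [simulate_cnv_states()].
#' @return Numeric matrix, markers x samples.
#' @export
simulate_lrr <- function(cfg, map, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 3L))
  n <- cfg$n_samples
  samples <- sprintf("s%04d", seq_len(n))
  lrr <- matrix(0, nrow = nrow(map), ncol = n,
                dimnames = list(map$marker, samples))
  if (nrow(truth$regions) > 0) {
    for (i in seq_len(nrow(truth$regions))) {
      rows <- truth$regions$marker_first[i]:truth$regions$marker_last[i]
      st <- truth$states[i, ]
      shift <- ifelse(st < 0, cfg$lrr_shift_loss, ifelse(st > 0, cfg$lrr_shift_gain, 0))
      lrr[rows, ] <- lrr[rows, ] + rep(shift, each = length(rows))
    }
  }
  wave <- cfg$gc_wave_amplitude * (map$gc - mean(map$gc))
  lrr <- lrr + wave
  if (cfg$lrr_noise_sd > 0)
    lrr <- lrr + matrix(rnorm(length(lrr), sd = cfg$lrr_noise_sd), nrow = nrow(lrr))
  lrr
}

#' Simulate phenotypes with known additive effects
#'
#' The true additive value of an animal for a trait is the sum of
#' `effect * dose` over the effect table (CNV dose coded loss = -1,
#' neutral = 0, gain = +1; SNP dose = allele count). PTA = true value +
#' Gaussian noise with variance `(1 - reliability) / reliability` (zero when
#' reliability is 1); reliability is drawn uniformly per animal from
#' `reliability_range`.
#'
#' @param cfg A [sim_config()].
#' @param genotypes SNP dosage matrix (markers x samples) or `NULL`.
#' @param cnv_truth Output of [simulate_cnv_states()] or `NULL`.
#' @return A list with `phenotypes` (tibble `animal_id`, `trait`, `pta`,
#'   `reliability`, `dpta`) and `truth` (tibble of true additive values per
#'   animal and trait).
#' @export
simulate_phenotypes <- function(cfg, genotypes = NULL, cnv_truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 4L))
  n <- cfg$n_samples
  samples <- if (!is.null(genotypes)) colnames(genotypes)
             else sprintf("s%04d", seq_len(n))
  eff <- cfg$effect_table
  traits <- unique(eff$trait)
  if (length(traits) == 0) traits <- "MY"
  dose_of <- function(id) {
    if (!is.null(cnv_truth) && nrow(cnv_truth$regions) > 0 &&
        id %in% rownames(cnv_truth$states))
      return(as.numeric(cnv_truth$states[id, ]))
    if (!is.null(genotypes) && id %in% rownames(genotypes))
      return(as.numeric(genotypes[id, ]))
    stop_bad_arg("effect_table variant '", id, "' not found among CNVs or markers")
  }
  out <- purrr::map_dfr(traits, function(tr) {
    g <- rep(0, n)
    rows <- eff[eff$trait == tr, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      g <- g + rows$effect[i] * dose_of(rows$variant_id[i])
    rel <- runif(n, cfg$reliability_range[1], cfg$reliability_range[2])
    noise_sd <- sqrt((1 - rel) / rel)
    pta <- g + rnorm(n) * noise_sd
    tibble::tibble(animal_id = samples, trait = tr, pta = pta,
                   reliability = rel, true_value = g)
  })
  phen <- out |>
    mutate(dpta = deregress(.data$pta, .data$reliability)) |>
    select("animal_id", "trait", "pta", "reliability", "dpta")
  truth <- select(out, "animal_id", "trait", "true_value")
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete cohort
#'
#' Runs the three generators in sequence and returns every input the pipeline
#' consumes plus the truth set.
#'
#' @param cfg A [sim_config()].
#' @return A list: `map`, `genotypes`, `blocks`, `cnv_truth`, `lrr`,
#'   `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  hap <- simulate_haplotypes(cfg)
  truth <- simulate_cnv_states(cfg, hap$map)
  lrr <- simulate_lrr(cfg, hap$map, truth)
  ph <- simulate_phenotypes(cfg, hap$genotypes, truth)
  list(map = hap$map, genotypes = hap$genotypes, blocks = hap$blocks,
       cnv_truth = truth, lrr = lrr, phenotypes = ph$phenotypes,
       truth = ph$truth)
}
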