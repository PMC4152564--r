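#' Read a marker map
#'
#' The marker map anchors every other input: a tab-delimited file with one row
#' per array probe and columns `marker` (unique probe name), `chrom`, `pos`
#' (1-based bp) and `gc` (local GC fraction in \[0, 1\], used for intensity
#' wave correction).
#'
#' Positions must be strictly increasing within each chromosome as given in
#' the file; the map is returned sorted by (chrom, pos) with chromosomes kept
#' in order of first appearance.
#'
#' @param path Path to a tab-delimited file with a header line
#'   `marker  chrom  pos  gc`.
#' @return A tibble with columns `marker`, `chrom`, `pos`, `gc`.
#' @export
read_marker_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           chrom = readr::col_character(),
                           pos = readr::col_double(),
                           gc = readr::col_double()))
  validate_marker_map(tbl)
}

validate_marker_map <- function(tbl) {
  need <- c("marker", "chrom", "pos", "gc")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0)
    stop_bad_arg("marker map is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tbl$gc)) stop_bad_arg("marker map has missing gc values")
  check_fraction(tbl$gc, "gc")
  dup <- tbl$marker[duplicated(tbl$marker)]
  if (length(dup) > 0)
    stop_bad_arg("duplicated marker name(s): ", paste(unique(head(dup, 5)), collapse = ", "))
  bad <- tbl |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chrom) |>
    filter(.data$pos <= dplyr::lag(.data$pos, default = -Inf)) |>
    ungroup()
  if (nrow(bad) > 0)
    stop_bad_arg("positions not strictly increasing within chromosome at marker '",
                 bad$marker[[1]], "'")
  tbl |>
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom))) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos)) |>
    tibble::as_tibble()
}

read_assay_matrix <- function(path, map, what, integer_values = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tbl) < 2) stop_bad_arg("no samples in ", what, " file")
  names(tbl)[1] <- "marker"
  unmapped <- setdiff(tbl$marker, map$marker)
  if (length(unmapped) > 0)
    stop_bad_arg("markers absent from the map: ", paste(head(unmapped, 5), collapse = ", "))
  samples <- names(tbl)[-1]
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  missing_cell <- is.na(vals) | vals == "" | vals == "NA"
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_bad_arg("non-numeric value in ", what, " at marker '",
                 tbl$marker[bad[1, 1]], "', sample '", samples[bad[1, 2]], "'")
  dimnames(num) <- list(tbl$marker, samples)
  absent <- setdiff(map$marker, tbl$marker)
  if (length(absent) > 0) {
    warn(paste0(length(absent), " mapped marker(s) absent from ", what,
                "; filled with NA"))
    pad <- matrix(NA_real_, nrow = length(absent), ncol = ncol(num),
                  dimnames = list(absent, samples))
    num <- rbind(num, pad)
  }
  num <- num[map$marker, , drop = FALSE]
  if (integer_values) {
    ok <- is.na(num) | num %in% c(0, 1, 2)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      stop_bad_arg("genotype dosage must be 0/1/2 or missing; offending marker '",
                   rownames(num)[bad[1]], "', sample '", colnames(num)[bad[2]], "'")
    }
  }
  num
}

#' Read a Log R Ratio matrix aligned to a marker map
#'
#' Rows are keyed by marker name (first column), remaining columns are sample
#' ids. The returned matrix follows map order; missing cells stay `NA` (they
#' are later excluded from segment means, never zero-filled).
#'
#' @param path Tab-delimited file, first column marker names, header of
#'   sample ids.
#' @param map A marker map from [read_marker_map()].
#' @return A numeric matrix, markers x samples, rownames in map order.
#' @export
read_lrr_matrix <- function(path, map) {
  read_assay_matrix(path, map, what = "LRR matrix")
}

#' Read a genotype dosage matrix (0/1/2) aligned to a marker map
#'
#' @inheritParams read_lrr_matrix
#' @return An integer-valued numeric matrix, markers x samples.
#' @export
read_genotype_matrix <- function(path, map) {
  read_assay_matrix(path, map, what = "genotype matrix", integer_values = TRUE)
}

#' Write a markers-x-samples matrix as TSV
#'
#' Inverse of [read_lrr_matrix()] / [read_genotype_matrix()].
#'
#' @param x Matrix with marker rownames and sample colnames.
#' @param path Output path.
#' @export
write_assay_matrix <- function(x, path) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_bad_arg("matrix must have marker rownames and sample colnames")
  tbl <- tibble::as_tibble(x, rownames = "marker")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects columns `animal_id`, `trait`, `pta`, `reliability`. The de-regressed
#' response is added with [add_dpta()].
#'
#' @param path Tab-delimited phenotype file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           animal_id = readr::col_character(),
                           trait = readr::col_character(),
                           pta = readr::col_double(),
                           reliability = readr::col_double()))
  need <- c("animal_id", "trait", "pta", "reliability")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0)
    stop_bad_arg("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  check_fraction(tbl$reliability, "reliability", allow_zero = FALSE)
  tbl
}

#' Write genomic regions to BED
#'
#' Internal coordinates are 1-based fully closed (the convention in which a
#' region printed as chr14:11,250,157-11,307,423 has length
#' end - start + 1 = 57,267 bp). BED is the only 0-based half-open surface:
#' the written start is `start - 1`, the end is unchanged, so
#' `bed_end - bed_start` equals the internal length.
#'
#' @param regions Tibble with columns `chrom`, `start`, `end` and optionally
#'   an id column (`cnv_id` or `name`); extra columns are ignored.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  check_interval(regions$chrom, regions$start, regions$end)
  name <- regions[["cnv_id"]] %||% regions[["name"]] %||%
    paste0("region", seq_len(nrow(regions)))
  bed <- tibble::tibble(chrom = regions$chrom,
                        start = as.integer(regions$start - 1L),
                        end = as.integer(regions$end),
                        name = as.character(name))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based closed intervals
#'
#' @param path BED path (first four columns chrom, start, end, name; name
#'   optional).
#' @return Tibble with columns `chrom`, `start`, `end`, `name` in the internal
#'   1-based closed convention.
#' @export
read_regions_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(tbl) < 3) stop_bad_arg("BED file must have at least 3 columns")
  out <- tibble::tibble(chrom = as.character(tbl[[1]]),
                        start = as.integer(tbl[[2]] + 1L),
                        end = as.integer(tbl[[3]]),
                        name = if (ncol(tbl) >= 4) as.character(tbl[[4]]) else NA_character_)
  check_interval(out$chrom, out$start, out$end)
  out
}

#' Write an association results table
#'
#' @param results Tibble as produced by [assoc_scan()] (optionally annotated
#'   with region coordinates).
#' @param path Output path.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
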