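# Relation categories between a trait-associated CNV and neighbouring
# significant SNPs, in precedence order.
TAG_LEVELS <- c("IN", "IN*", "IN**", "LD", "LD*", "LD NS", "LD* NS", "NN")

# compound printed labels ("IN + LD") resolve to their overlap component:
# overlap is considered first and used instead of linkage
resolve_label <- function(x) {
  dplyr::case_match(x, "IN + LD" ~ "IN", "IN* + LD" ~ "IN*",
                    "IN** + LD" ~ "IN**", .default = x)
}

#' Classify how a trait-associated CNV relates to significant SNPs
#'
#' Assigns one of eight relation categories to a significant (CNV, trait)
#' pair, in strict precedence order: `IN` (a significant SNP lies inside the
#' CNV), `IN*` (the nearest flanking SNP on either side is significant),
#' `IN**` (the second-nearest flanking SNP is significant), `LD` (the CNV
#' lies in a haplotype block containing a significant SNP), `LD*` (the block
#' immediately adjacent to the CNV contains a significant SNP), `LD NS` /
#' `LD* NS` (the same geometry but the block holds no significant SNP), and
#' `NN` (none of the above). Overlap beats linkage: when both apply, the
#' `IN`-type label is used. A CNV is adjacent to a block when the block's
#' boundary marker is one of the CNV's two nearest flanking markers on that
#' side; a CNV is in a block when a block member lies inside the CNV or the
#' block span contains the whole CNV.
#'
#' CNVs of 400 kb or more are excluded with an explicit `excluded` status
#' (large regions are unreliable units for tagging analysis), never silently
#' dropped.
#'
#' @param cnv One-row tibble (or list) with `cnv_id`, `chrom`, `start`,
#'   `end`.
#' @param trait Trait name the classification refers to.
#' @param sig_snps Tibble of significant SNPs for that trait: `marker`,
#'   `chrom`, `pos` (a `trait` column, if present, is filtered on).
#' @param blocks Haplotype block tibble from [gabriel_blocks()] (columns
#'   `chrom`, `start`, `end`, `markers`).
#' @param map Marker map.
#' @param max_len_bp Exclusion threshold on CNV length (default 4e5).
#' @return One-row tibble: `cnv_id`, `trait`, `category`, `status`
#'   (`"classified"` or `"excluded"`), `evidence` (semicolon-joined SNP or
#'   block identifiers behind the call).
#' @export
classify_relation <- function(cnv, trait, sig_snps, blocks, map,
                              max_len_bp = 4e5) {
  row <- function(category, status = "classified", evidence = NA_character_) {
    tibble::tibble(cnv_id = cnv$cnv_id, trait = trait, category = category,
                   status = status, evidence = evidence)
  }
  if (region_length(cnv$start, cnv$end) >= max_len_bp)
    return(row(NA_character_, status = "excluded"))
  if (!cnv$chrom %in% map$chrom)
    stop_bad_arg("CNV chromosome '", cnv$chrom, "' absent from map")
  if ("trait" %in% names(sig_snps))
    sig_snps <- filter(sig_snps, .data$trait == !!trait)
  sig_snps <- filter(sig_snps, .data$chrom == cnv$chrom)

  chrom_map <- filter(map, .data$chrom == cnv$chrom) |> arrange(.data$pos)
  up <- filter(chrom_map, .data$pos < cnv$start) |> tail(2)
  down <- filter(chrom_map, .data$pos > cnv$end) |> head(2)
  flank1 <- c(tail(up$marker, 1), head(down$marker, 1))
  flank2 <- c(head(up$marker, 1)[nrow(up) == 2], down$marker[2][nrow(down) == 2])
  flank12 <- c(flank1, flank2)

  # IN / IN* / IN**
  inside <- filter(sig_snps, .data$pos >= cnv$start, .data$pos <= cnv$end)
  if (nrow(inside) > 0)
    return(row("IN", evidence = paste(inside$marker, collapse = ";")))
  hit1 <- intersect(flank1, sig_snps$marker)
  if (length(hit1) > 0)
    return(row("IN*", evidence = paste(hit1, collapse = ";")))
  hit2 <- intersect(flank2, sig_snps$marker)
  if (length(hit2) > 0)
    return(row("IN**", evidence = paste(hit2, collapse = ";")))

  # haploblock relations
  if (nrow(blocks) > 0) {
    blocks <- filter(blocks, .data$chrom == cnv$chrom)
  }
  if (nrow(blocks) > 0) {
    member_inside <- purrr::map_lgl(blocks$markers, function(mk) {
      pos <- chrom_map$pos[match(mk, chrom_map$marker)]
      any(pos >= cnv$start & pos <= cnv$end, na.rm = TRUE)
    })
    spans <- blocks$start <= cnv$start & blocks$end >= cnv$end
    containing <- which(member_inside | spans)
    boundary_adjacent <- purrr::map_lgl(blocks$markers, function(mk) {
      any(c(head(mk, 1), tail(mk, 1)) %in% flank12)
    })
    adjacent <- setdiff(which(boundary_adjacent), containing)
    block_has_sig <- function(i) {
      any(sig_snps$pos >= blocks$start[i] & sig_snps$pos <= blocks$end[i])
    }
    block_id <- function(i) paste0(blocks$chrom[i], ":", blocks$start[i], "-",
                                   blocks$end[i])
    if (length(containing) > 0) {
      sig <- containing[vapply(containing, block_has_sig, logical(1))]
      if (length(sig) > 0)
        return(row("LD", evidence = paste(vapply(sig, block_id, character(1)),
                                          collapse = ";")))
    }
    if (length(adjacent) > 0) {
      sig <- adjacent[vapply(adjacent, block_has_sig, logical(1))]
      if (length(sig) > 0)
        return(row("LD*", evidence = paste(vapply(sig, block_id, character(1)),
                                           collapse = ";")))
    }
    if (length(containing) > 0)
      return(row("LD NS", evidence = paste(vapply(containing, block_id,
                                                  character(1)), collapse = ";")))
    if (length(adjacent) > 0)
      return(row("LD* NS", evidence = paste(vapply(adjacent, block_id,
                                                   character(1)), collapse = ";")))
  }
  row("NN")
}

#' Classify every significant (CNV, trait) combination
#'
#' @param cnvs Tibble of CNV regions (`cnv_id`, `chrom`, `start`, `end`).
#' @param sig_pairs Tibble of significant (cnv_id, trait) combinations.
#' @param sig_snps,blocks,map,max_len_bp Passed to [classify_relation()].
#' @return Row-bound classification tibble.
#' @export
classify_relations <- function(cnvs, sig_pairs, sig_snps, blocks, map,
                               max_len_bp = 4e5) {
  purrr::pmap_dfr(sig_pairs, function(cnv_id, trait, ...) {
    cnv <- filter(cnvs, .data$cnv_id == !!cnv_id)
    if (nrow(cnv) != 1) stop_bad_arg("unknown cnv_id '", cnv_id, "'")
    classify_relation(cnv, trait, sig_snps, blocks, map, max_len_bp)
  })
}

#' Summarise tag-SNP capture of CNVs
#'
#' Aggregates classification labels to per-trait and overall counts and
#' percentages per category, with roll-ups: "Tagged" is
#' IN + IN* + IN** + LD + LD* (the CNV's effect is captured by a genotyped
#' SNP, directly or through LD); "Not tagged" is NN + LD NS + LD* NS.
#' Compound labels such as `"IN + LD"` resolve to their overlap component
#' before counting. By default `LD* NS` is lumped into `LD NS`, matching the
#' conventional printed summary layout; set `lump_ld_ns = FALSE` to keep the
#' raw categories.
#'
#' @param labels Tibble with `cnv_id`, `trait` and a label column named
#'   `category` or `label` (rows with `NA` labels are ignored, so the output
#'   of [load_table1_fixture()] can be passed directly).
#' @param lump_ld_ns Lump `LD* NS` into `LD NS`?
#' @return Tibble with columns `trait` (including `"All"`), `category`
#'   (the categories plus `Tagged`, `Not tagged`, `Total`), `n`, `pct`
#'   (percent of the trait's total; `NA` when the total is zero).
#' @export
summarize_tagging <- function(labels, lump_ld_ns = TRUE) {
  col <- if ("category" %in% names(labels)) "category" else "label"
  lab <- labels |>
    filter(!is.na(.data[[col]])) |>
    transmute(cnv_id = .data$cnv_id, trait = .data$trait,
              category = resolve_label(.data[[col]]))
  if (anyDuplicated(lab[c("cnv_id", "trait")]) > 0)
    stop_bad_arg("duplicate (cnv, trait) label")
  bad <- setdiff(lab$category, TAG_LEVELS)
  if (length(bad) > 0)
    stop_bad_arg("unknown category label(s): ", paste(bad, collapse = ", "))
  if (lump_ld_ns)
    lab <- mutate(lab, category = dplyr::if_else(.data$category == "LD* NS",
                                                 "LD NS", .data$category))
  levels <- if (lump_ld_ns) setdiff(TAG_LEVELS, "LD* NS") else TAG_LEVELS
  tagged_set <- c("IN", "IN*", "IN**", "LD", "LD*")
  one_summary <- function(d, trait_name) {
    counts <- table(factor(d$category, levels = levels))
    total <- nrow(d)
    n <- c(as.integer(counts),
           sum(counts[tagged_set]),
           total - sum(counts[tagged_set]),
           total)
    tibble::tibble(trait = trait_name,
                   category = c(levels, "Tagged", "Not tagged", "Total"),
                   n = n,
                   pct = if (total > 0) 100 * n / total else NA_real_)
  }
  per_trait <- if (nrow(lab) > 0) {
    lab |>
      group_by(.data$trait) |>
      dplyr::group_map(~ one_summary(.x, .y$trait)) |>
      dplyr::bind_rows()
  } else {
    NULL
  }
  dplyr::bind_rows(per_trait, one_summary(lab, "All"))
}

#' Overlap two interval sets
#'
#' Reports every pair of intervals on the same chromosome sharing at least
#' 1 bp under the 1-based closed convention (so \[100, 200\] and \[200, 300\]
#' overlap). Typical use: annotating associated CNVs with known QTL
#' intervals.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and an id column
#'   (first non-coordinate column is used).
#' @param annotations Same layout.
#' @return Tibble of overlapping pairs with both ids, coordinates and the
#'   shared width in bp.
#' @export
overlap_intervals <- function(regions, annotations) {
  id_col <- function(tbl) setdiff(names(tbl), c("chrom", "start", "end"))[1]
  ra <- regions |>
    transmute(region_id = .data[[id_col(regions)]], chrom = .data$chrom,
              start = .data$start, end = .data$end)
  an <- annotations |>
    transmute(annotation_id = .data[[id_col(annotations)]], chrom = .data$chrom,
              a_start = .data$start, a_end = .data$end)
  inner_join(ra, an, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start <= .data$a_end, .data$end >= .data$a_start) |>
    mutate(overlap_bp = pmin(.data$end, .data$a_end) -
             pmax(.data$start, .data$a_start) + 1) |>
    select("region_id", "annotation_id", "chrom", "start", "end",
           "a_start", "a_end", "overlap_bp")
}
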