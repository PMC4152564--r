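#' Packaged CNV-by-trait classification table
#'
#' A long-format rendition of the published per-CNV classification of
#' trait-associated copy-number variants against neighbouring tag SNPs in a
#' large Holstein cohort: 31 CNVs (six regions above 400 kb excluded) by five
#' milk production traits (MY, FY, PY, FP, PP), with the FDR-adjusted
#' association p-value of each cell and, for the 82 significant cells, the
#' relation category. Categories come from the closed vocabulary `IN`, `IN*`,
#' `IN**`, `LD`, `LD*`, `LD NS`, `LD* NS`, `NN`; compound entries such as
#' `"IN + LD"` are stored verbatim and resolved to their `IN` component by
#' [summarize_tagging()] (overlap takes precedence over linkage). Three CNVs
#' with no significant trait carry `NA` p-values.
#'
#' @return A tibble with columns `cnv_id`, `trait`, `p_fdr` (numeric, `NA`
#'   where not available) and `label` (`NA` for non-significant cells).
#' @examples
#' tab1 <- load_table1_fixture()
#' dplyr::filter(tab1, !is.na(label)) |> nrow()  # 82 significant combinations
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_classification.tsv",
                      package = "cnvgwas", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = "",
                         col_types = readr::cols(
                           cnv_id = readr::col_character(),
                           trait = readr::col_character(),
                           p_fdr = readr::col_double(),
                           label = readr::col_character()))
  tbl
}
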