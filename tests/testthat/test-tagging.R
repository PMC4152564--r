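# A 30-marker chromosome at 10 kb spacing; the CNV covers markers 15..17.
tag_map <- toy_map(30, spacing = 10000L)
tag_cnv <- tibble::tibble(cnv_id = "cnvA", chrom = "chr1",
                          start = 150000L, end = 170000L)
snp_at <- function(idx, trait = "MY")
  tibble::tibble(marker = tag_map$marker[idx], chrom = "chr1",
                 pos = tag_map$pos[idx], trait = trait)
block_of <- function(first, last)
  tibble::tibble(block = 1L, chrom = "chr1",
                 start = tag_map$pos[first], end = tag_map$pos[last],
                 first_idx = first, last_idx = last,
                 n_markers = last - first + 1L,
                 markers = list(tag_map$marker[first:last]))
no_blocks <- block_of(1, 2)[0, ]

test_that("overlap and flanking relations classify as IN / IN* / IN**", {
  got <- classify_relation(tag_cnv, "MY", snp_at(16), no_blocks, tag_map)
  expect_equal(got$category, "IN")
  expect_equal(got$evidence, "m016")
  # nearest flank on either side
  expect_equal(classify_relation(tag_cnv, "MY", snp_at(14), no_blocks,
                                 tag_map)$category, "IN*")
  expect_equal(classify_relation(tag_cnv, "MY", snp_at(18), no_blocks,
                                 tag_map)$category, "IN*")
  # second-nearest flank
  expect_equal(classify_relation(tag_cnv, "MY", snp_at(13), no_blocks,
                                 tag_map)$category, "IN**")
  expect_equal(classify_relation(tag_cnv, "MY", snp_at(19), no_blocks,
                                 tag_map)$category, "IN**")
  # beyond the two neighbouring positions: not an IN-type relation
  expect_equal(classify_relation(tag_cnv, "MY", snp_at(12), no_blocks,
                                 tag_map)$category, "NN")
})

test_that("haploblock relations classify as LD / LD* / LD NS / LD* NS / NN", {
  blk <- block_of(13, 20)          # contains the CNV markers
  adj <- block_of(10, 14)          # ends at the nearest upstream flank
  far_snp <- snp_at(25)            # significant but unrelated
  blk_snp <- snp_at(20)            # significant, inside blk only
  adj_snp <- snp_at(11)            # significant, inside adj only
  expect_equal(classify_relation(tag_cnv, "MY", blk_snp, blk, tag_map)$category,
               "LD")
  expect_equal(classify_relation(tag_cnv, "MY", adj_snp, adj, tag_map)$category,
               "LD*")
  expect_equal(classify_relation(tag_cnv, "MY", far_snp, blk, tag_map)$category,
               "LD NS")
  expect_equal(classify_relation(tag_cnv, "MY", far_snp, adj, tag_map)$category,
               "LD* NS")
  expect_equal(classify_relation(tag_cnv, "MY", far_snp, no_blocks,
                                 tag_map)$category, "NN")
  # no significant SNPs anywhere on the chromosome
  none <- snp_at(integer(0))
  expect_equal(classify_relation(tag_cnv, "MY", none, no_blocks,
                                 tag_map)$category, "NN")
})

test_that("overlap takes precedence over linkage", {
  blk <- block_of(13, 20)
  snps <- dplyr::bind_rows(snp_at(16), snp_at(20))
  got <- classify_relation(tag_cnv, "MY", snps, blk, tag_map)
  expect_equal(got$category, "IN")
})

test_that("large CNVs are excluded with explicit status", {
  big <- tibble::tibble(cnv_id = "cnvBig", chrom = "chr1",
                        start = 1L, end = 400000L)
  got <- classify_relation(big, "MY", snp_at(16), no_blocks, tag_map)
  expect_equal(got$status, "excluded")
  expect_true(is.na(got$category))
})

test_that("classification ignores SNPs significant only for other traits", {
  snps <- snp_at(16, trait = "FY")
  got <- classify_relation(tag_cnv, "MY", snps, no_blocks, tag_map)
  expect_equal(got$category, "NN")
})

test_that("classification is invariant to input ordering", {
  blk <- dplyr::bind_rows(block_of(13, 20), block_of(22, 25))
  snps <- dplyr::bind_rows(snp_at(25), snp_at(20), snp_at(5))
  ref <- classify_relation(tag_cnv, "MY", snps, blk, tag_map)
  set.seed(33)
  for (i in 1:5) {
    got <- classify_relation(tag_cnv, "MY", snps[sample(nrow(snps)), ],
                             blk[sample(nrow(blk)), ], tag_map)
    expect_equal(got$category, ref$category)
  }
})

test_that("every significant pair receives exactly one category", {
  cnvs <- dplyr::bind_rows(
    tag_cnv,
    tibble::tibble(cnv_id = "cnvB", chrom = "chr1", start = 50000L, end = 60000L))
  pairs <- tidyr::expand_grid(cnv_id = c("cnvA", "cnvB"), trait = c("MY", "PP"))
  labels <- classify_relations(cnvs, pairs, snp_at(16, "MY"),
                               block_of(13, 20), tag_map)
  expect_equal(nrow(labels), 4)
  expect_true(all(labels$category %in% c("IN", "IN*", "IN**", "LD", "LD*",
                                         "LD NS", "LD* NS", "NN")))
  expect_equal(anyDuplicated(labels[c("cnv_id", "trait")]), 0)
})

test_that("fixture aggregation reproduces the published summary counts", {
  tab1 <- load_table1_fixture()
  s <- summarize_tagging(tab1)
  all_n <- function(cat) s$n[s$trait == "All" & s$category == cat]
  expect_equal(all_n("Total"), 82)
  expect_equal(all_n("IN"), 17)
  expect_equal(all_n("IN*"), 26)
  expect_equal(all_n("IN**"), 14)
  expect_equal(all_n("LD"), 3)
  expect_equal(all_n("LD*"), 2)
  expect_equal(all_n("LD NS"), 4)   # lumped with LD* NS
  expect_equal(all_n("NN"), 16)
  expect_equal(all_n("Tagged"), 62)
  expect_equal(all_n("Not tagged"), 20)
  pct <- function(cat) s$pct[s$trait == "All" & s$category == cat]
  expect_equal(pct("Tagged"), 75.61, tolerance = 0.005)
  expect_equal(pct("Not tagged"), 24.39, tolerance = 0.005)
  expect_equal(pct("IN*"), 31.71, tolerance = 0.005)
  # per-trait totals
  tot <- function(tr) s$n[s$trait == tr & s$category == "Total"]
  expect_equal(vapply(c("MY", "FY", "PY", "FP", "PP"), tot, integer(1)),
               c(MY = 17L, FY = 19L, PY = 16L, FP = 7L, PP = 23L))
  # raw (unlumped) view keeps LD* NS separate
  raw <- summarize_tagging(tab1, lump_ld_ns = FALSE)
  expect_equal(raw$n[raw$trait == "All" & raw$category == "LD* NS"], 3)
  expect_equal(raw$n[raw$trait == "All" & raw$category == "LD NS"], 1)
})

test_that("summary rejects duplicates and handles empty input", {
  dup <- tibble::tibble(cnv_id = c("c1", "c1"), trait = "MY",
                        category = c("IN", "NN"))
  expect_error(summarize_tagging(dup), "duplicate")
  empty <- tibble::tibble(cnv_id = character(), trait = character(),
                          category = character())
  s <- summarize_tagging(empty)
  expect_equal(s$n[s$trait == "All" & s$category == "Total"], 0)
  expect_true(all(is.na(s$pct[s$trait == "All"])))
})

test_that("interval overlap uses the closed convention", {
  r <- tibble::tibble(id = "a", chrom = "chr1", start = 100L, end = 200L)
  q1 <- tibble::tibble(qtl = "q1", chrom = "chr1", start = 100L, end = 200L)
  q2 <- tibble::tibble(qtl = "q2", chrom = "chr1", start = 200L, end = 300L)
  q3 <- tibble::tibble(qtl = "q3", chrom = "chr1", start = 201L, end = 300L)
  q4 <- tibble::tibble(qtl = "q4", chrom = "chr2", start = 100L, end = 200L)
  expect_equal(nrow(overlap_intervals(r, q1)), 1)
  got <- overlap_intervals(r, q2)
  expect_equal(nrow(got), 1)          # shares exactly bp 200
  expect_equal(got$overlap_bp, 1)
  expect_equal(nrow(overlap_intervals(r, q3)), 0)
  expect_equal(nrow(overlap_intervals(r, q4)), 0)
})
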