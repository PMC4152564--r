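#' De-regress predicted transmitting abilities
#'
#' Breeding-value predictions (PTA) are shrunken towards the mean in
#' proportion to their information content; de-regression removes that
#' shrinkage so the response used in association testing is on a common
#' scale. The de-regressed value is `pta / reliability^2`.
#'
#' @param pta Numeric vector of predicted transmitting abilities (trait
#'   units).
#' @param reliability Numeric vector in (0, 1]; zero is rejected rather than
#'   producing infinities.
#' @return `pta / reliability^2`, same length as the inputs.
#' @examples
#' deregress(100, 0.5)  # 400
#' deregress(100, 1)    # 100
#' @export
deregress <- function(pta, reliability) {
  if (!is.numeric(pta) || !is.numeric(reliability))
    stop_bad_arg("pta and reliability must be numeric")
  check_fraction(reliability, "reliability", allow_zero = FALSE)
  pta / reliability^2
}

#' Add the de-regressed response to a phenotype table
#'
#' @param phenotypes Tibble with columns `pta` and `reliability`.
#' @return The input with a `dpta` column appended.
#' @export
add_dpta <- function(phenotypes) {
  mutate(phenotypes, dpta = deregress(.data$pta, .data$reliability))
}

#' Pairwise Pearson correlations between traits
#'
#' Pivots a long phenotype table to animals x traits and computes the
#' pairwise-complete Pearson correlation matrix. Animals missing a trait are
#' dropped per pair, not imputed. A zero-variance trait gives `NA` entries
#' with an explicit warning rather than silently propagating `NaN`.
#'
#' @param phenotypes Long tibble with `animal_id`, `trait` and the response
#'   column.
#' @param value Which response to correlate: `"dpta"` (default) or `"pta"`.
#' @return A symmetric correlation matrix with unit diagonal, traits as
#'   dimnames.
#' @export
trait_correlation_matrix <- function(phenotypes, value = c("dpta", "pta")) {
  value <- match.arg(value)
  if (value == "dpta" && !"dpta" %in% names(phenotypes))
    phenotypes <- add_dpta(phenotypes)
  wide <- phenotypes |>
    select("animal_id", "trait", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "trait", values_from = dplyr::all_of(value)) |>
    select(-"animal_id")
  n_complete <- vapply(wide, function(x) sum(!is.na(x)), integer(1))
  if (any(n_complete < 3))
    stop_bad_arg("need >= 3 complete records per trait; offending trait '",
                 names(wide)[which(n_complete < 3)[1]], "'")
  zero_var <- vapply(wide, function(x) isTRUE(sd(x, na.rm = TRUE) == 0), logical(1))
  if (any(zero_var))
    warn(paste0("zero-variance trait(s): ",
                paste(names(wide)[zero_var], collapse = ", "),
                "; correlations set to NA"))
  suppressWarnings(
    cm <- cor(as.matrix(wide), use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm[zero_var, ] <- NA_real_
  cm[, zero_var] <- NA_real_
  diag(cm)[zero_var] <- 1
  cm
}
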