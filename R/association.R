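#' Principal-component covariates for stratification correction
#'
#' Computes the top-k sample scores of the eigendecomposition of the
#' variant-centred dosage (or CNV state) matrix, for use as nuisance
#' covariates in the association model.
#'
#' @param dose Numeric matrix, variants x samples (SNP dosage 0/1/2 or CNV
#'   state codes).
#' @param k Number of components (default 10).
#' @return A list of class `"pca_covariates"`: `scores` (samples x k,
#'   mutually orthogonal), `explained` (non-increasing variance fractions).
#' @export
pca_covariates <- function(dose, k = 10) {
  if (!is.matrix(dose)) stop_bad_arg("dose must be a matrix (variants x samples)")
  n <- ncol(dose)
  if (k >= n) stop_bad_arg("k must be smaller than the number of samples")
  centred <- dose - rowMeans(dose, na.rm = TRUE)
  centred[is.na(centred)] <- 0
  pr <- prcomp(t(centred), center = FALSE, rank. = k)
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 explained = explained[seq_len(min(k, length(explained)))]),
            class = "pca_covariates")
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "pca_covariates")) covariates <- covariates$scores
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop_bad_arg("covariates must have one row per sample")
  covariates
}

#' Additive linear-model association for one variant
#'
#' Ordinary least squares of the de-regressed response on
#' \[intercept, dose, covariates\] with a two-sided t-test on the dose
#' coefficient. Dose coding is the allele count 0/1/2 for SNPs and
#' loss = -1 / neutral = 0 / gain = +1 for CNV states. A dose that is
#' constant across complete cases is flagged untestable instead of returning
#' `NaN` p-values.
#'
#' @param dpta Numeric response vector (de-regressed PTA).
#' @param dose Numeric dose vector, same length.
#' @param covariates Optional samples x k matrix or [pca_covariates()]
#'   object.
#' @return One-row tibble: `beta`, `se`, `t`, `p_raw`, `n`, `untestable`.
#' @export
additive_assoc <- function(dpta, dose, covariates = NULL) {
  Z <- covariate_matrix(covariates, length(dpta))
  keep <- complete.cases(dpta, dose, Z)
  y <- dpta[keep]; d <- dose[keep]
  Zk <- if (is.null(Z)) NULL else Z[keep, , drop = FALSE]
  k <- if (is.null(Zk)) 0L else ncol(Zk)
  if (length(y) < k + 3)
    stop_bad_arg("need at least k + 3 complete cases")
  if (var(d) == 0)
    return(tibble::tibble(beta = NA_real_, se = NA_real_, t = NA_real_,
                          p_raw = NA_real_, n = length(y), untestable = TRUE))
  X <- cbind(`(Intercept)` = 1, dose = d, Zk)
  fit <- lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[["dose"]]
  tval <- beta / se
  p <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  tibble::tibble(beta = beta, se = se, t = tval, p_raw = p,
                 n = length(y), untestable = FALSE)
}

# residualize y on [1, Z]
residualise <- function(y, Z) {
  X <- cbind(rep(1, length(y)), Z)
  lm.fit(X, y)$residuals
}

#' Permutation p-value for the dose coefficient
#'
#' Residual-permutation (Freedman-Lane style) test: the response is
#' residualised on the covariates, residuals are permuted, and the dose
#' t-statistic is recomputed for each permutation; the covariates therefore
#' stay honoured under the null. The add-one convention gives
#' `p = (1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1)`.
#'
#' @inheritParams additive_assoc
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return The permutation p-value (scalar).
#' @export
permutation_pvalue <- function(dpta, dose, covariates = NULL,
                               n_perm = 10000, seed = NULL) {
  if (n_perm < 100) warn("n_perm < 100 gives a very coarse permutation p-value")
  if (!is.null(seed)) set.seed(seed)
  Z <- covariate_matrix(covariates, length(dpta))
  keep <- complete.cases(dpta, dose, Z)
  y <- dpta[keep]; d <- dose[keep]
  Zk <- if (is.null(Z)) NULL else Z[keep, , drop = FALSE]
  if (var(d) == 0) return(NA_real_)
  yr <- residualise(y, Zk)
  dr <- residualise(d, Zk)
  k <- if (is.null(Zk)) 0L else ncol(Zk)
  df <- length(y) - k - 2L
  t_of <- function(yv) {
    r <- sum(yv * dr) / sqrt(sum(yv^2) * sum(dr^2))
    r * sqrt(df / (1 - r^2))
  }
  t_obs <- t_of(yr)
  perms <- vapply(seq_len(n_perm), function(i) sample(yr), numeric(length(yr)))
  t_perm <- vapply(seq_len(n_perm), function(i) t_of(perms[, i]), numeric(1))
  (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop_bad_arg("p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_bad_arg("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag significant associations by variant class
#'
#' CNVs are declared significant at FDR-adjusted p < 0.05; SNPs at the far
#' stricter FDR-adjusted p < 1e-8 (genome-wide SNP scans test vastly more
#' variants).
#'
#' @param results Tibble with a `p_fdr` column.
#' @param variant_class `"cnv"` or `"snp"`.
#' @return The input with a logical `significant` column.
#' @export
select_significant <- function(results, variant_class = c("cnv", "snp")) {
  variant_class <- match.arg(variant_class)
  thr <- if (variant_class == "cnv") 0.05 else 1e-8
  mutate(results, significant = !is.na(.data$p_fdr) & .data$p_fdr < thr)
}

#' Association scan of many variants against many traits
#'
#' Runs [additive_assoc()] for every variant (row of `dose`) and every trait
#' in the phenotype table, optionally adds residual-permutation p-values, and
#' applies Benjamini-Hochberg adjustment per trait within the variant class.
#'
#' @param phenotypes Long tibble with `animal_id`, `trait` and a `dpta`
#'   column (see [add_dpta()]); `animal_id` must match `colnames(dose)`.
#' @param dose Numeric matrix, variants x samples.
#' @param covariates Optional samples x k matrix or [pca_covariates()]
#'   object (rows aligned to `colnames(dose)`).
#' @param variant_class `"cnv"` or `"snp"`: sets the dose semantics recorded
#'   and the significance threshold.
#' @param n_perm Permutations per variant for `p_perm` (0 to skip).
#' @param seed Optional seed for the permutation stream.
#' @return A tibble of class `"cnv_scan"`: one row per (variant, trait) with
#'   `variant_id`, `trait`, `beta`, `se`, `t`, `p_raw`, `p_perm`, `p_fdr`,
#'   `significant`, `n`, `untestable`.
#' @export
assoc_scan <- function(phenotypes, dose, covariates = NULL,
                       variant_class = c("cnv", "snp"),
                       n_perm = 0, seed = NULL) {
  variant_class <- match.arg(variant_class)
  if (!is.matrix(dose) || is.null(rownames(dose)))
    stop_bad_arg("dose must be a matrix with variant rownames")
  if (!is.null(seed)) set.seed(seed)
  traits <- unique(phenotypes$trait)
  out <- purrr::map_dfr(traits, function(tr) {
    ph <- filter(phenotypes, .data$trait == tr)
    idx <- match(colnames(dose), ph$animal_id)
    y <- ph$dpta[idx]
    purrr::map_dfr(rownames(dose), function(v) {
      res <- additive_assoc(y, as.numeric(dose[v, ]), covariates)
      pp <- if (n_perm > 0 && !res$untestable)
        permutation_pvalue(y, as.numeric(dose[v, ]), covariates, n_perm = n_perm)
      else NA_real_
      mutate(res, variant_id = v, trait = tr, p_perm = pp, .before = 1)
    })
  })
  out <- out |>
    group_by(.data$trait) |>
    mutate(p_fdr = fdr_adjust(.data$p_raw)) |>
    ungroup() |>
    select_significant(variant_class) |>
    select("variant_id", "trait", "beta", "se", "t", "p_raw", "p_perm",
           "p_fdr", "significant", "n", "untestable")
  class(out) <- c("cnv_scan", class(out))
  attr(out, "variant_class") <- variant_class
  attr(out, "n_perm") <- n_perm
  out
}
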