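# Internal validation helpers. Kept deliberately blunt: every user-facing
# reader/constructor funnels through these so error wording stays consistent.

stop_bad_arg <- function(...) abort(paste0(...), class = "cnvgwas_error")

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_bad_arg(name, " must be numeric and non-missing")
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!all(lo_ok & hi_ok)) stop_bad_arg(name, " must lie in the unit interval")
  invisible(x)
}

check_interval <- function(chrom, start, end) {
  if (any(start < 1)) stop_bad_arg("interval start must be >= 1 (1-based closed coordinates)")
  if (any(end < start)) stop_bad_arg("interval end must be >= start")
  invisible(NULL)
}

# markers x samples matrix sanity
check_assay_matrix <- function(x, map, what = "matrix") {
  if (!is.matrix(x)) stop_bad_arg(what, " must be a matrix (markers x samples)")
  if (is.null(rownames(x))) stop_bad_arg(what, " must have marker rownames")
  if (ncol(x) == 0) stop_bad_arg("no samples in ", what)
  missing_from_map <- setdiff(rownames(x), map$marker)
  if (length(missing_from_map) > 0)
    stop_bad_arg("markers absent from the map: ", paste(head(missing_from_map, 5), collapse = ", "))
  invisible(x)
}
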