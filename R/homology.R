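#' Homology acceptance criterion
#'
#' Thresholds used to accept protein homology hits when transferring
#' reactions from reference reconstructions into a leaf model: an E-value
#' ceiling together with minimum percent identity and query coverage. All
#' comparisons are inclusive.
#'
#' @param max_evalue maximum E-value (default `1e-10`).
#' @param min_identity_pct minimum percent identity (default 60).
#' @param min_coverage_pct minimum percent coverage (default 80).
#' @return object of class `homology_criterion`.
#' @export
homology_criterion <- function(max_evalue = 1e-10, min_identity_pct = 60,
                               min_coverage_pct = 80) {
  if (!(max_evalue > 0)) stop("max_evalue must be positive")
  for (p in c(min_identity_pct, min_coverage_pct))
    if (p < 0 || p > 100) stop("percentage thresholds must lie in [0, 100]")
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct),
            class = "homology_criterion")
}

#' Filter tabular homology hits
#'
#' Retains rows meeting all three thresholds simultaneously
#' (`evalue <= max_evalue`, `identity_pct >= min_identity_pct`,
#' `coverage_pct >= min_coverage_pct`); input order is preserved. The
#' filter is idempotent and monotone in each threshold.
#'
#' @param hits data.frame with numeric columns `evalue`, `identity_pct`,
#'   `coverage_pct` (a `gene` column is customary but not required).
#' @param criterion a [homology_criterion()].
#' @return the retained rows of `hits`.
#' @export
filter_homology_hits <- function(hits, criterion = homology_criterion()) {
  needed <- c("evalue", "identity_pct", "coverage_pct")
  missing <- setdiff(needed, names(hits))
  if (length(missing))
    stop(sprintf("hits table lacks column(s): %s", paste(missing, collapse = ", ")))
  for (col in needed)
    if (!is.numeric(hits[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
  keep <- hits$evalue <= criterion$max_evalue &
    hits$identity_pct >= criterion$min_identity_pct &
    hits$coverage_pct >= criterion$min_coverage_pct
  hits[keep, , drop = FALSE]
}
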