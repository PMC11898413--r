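#' Variant filter thresholds
#'
#' The standard post-calling site filters for a joint callset: minor allele
#' frequency strictly greater than `min_maf`, site depth strictly greater
#' than `min_depth`, and genotype missing rate strictly less than
#' `max_missing`. Defaults are MAF > 0.01, depth > 3, missing rate < 0.2.
#'
#' @param min_maf minimum (exclusive) minor allele frequency, in \[0, 0.5\].
#' @param min_depth minimum (exclusive) depth in reads.
#' @param max_missing maximum (exclusive) fraction of missing genotypes,
#'   in \[0, 1\].
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_maf = 0.01, min_depth = 3,
                              max_missing = 0.2) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  if (min_depth < 0) stop("min_depth must be non-negative")
  structure(list(min_maf = min_maf, min_depth = min_depth,
                 max_missing = max_missing),
            class = "filter_thresholds")
}

#' Filter variants on MAF, depth and missingness
#'
#' MAF is computed over non-missing genotypes pooled across all samples.
#' The depth criterion is evaluated, by default, on the per-site mean of
#' per-genotype DP (`depth_mode = "site_mean"`, VCFtools-style site
#' filtering); `depth_mode = "genotype"` instead masks individual genotypes
#' with DP at or below the threshold before the MAF/missingness criteria are
#' applied. All inequalities are strict. When the matrix carries no depth
#' information the depth criterion is skipped with a warning.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds a [filter_thresholds()].
#' @param depth_mode `"site_mean"` or `"genotype"` (see Details).
#' @return the filtered `genotype_matrix`, with a `filter_report` attribute:
#'   a data.frame of per-criterion failure counts (a variant can fail several
#'   criteria) plus input/retained totals, retrievable via [filter_report()].
#' @export
filter_variants <- function(geno, thresholds = filter_thresholds(),
                            depth_mode = c("site_mean", "genotype")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  depth_mode <- match.arg(depth_mode)
  if (n_variants(geno) == 0) stop("empty genotype matrix")
  t <- thresholds
  n_in <- n_variants(geno)

  n_fail_depth <- 0L
  pass_depth <- rep(TRUE, n_in)
  if (is.null(geno$depth)) {
    warning("no depth information; depth criterion skipped")
  } else if (depth_mode == "site_mean") {
    mean_dp <- colMeans(geno$depth, na.rm = TRUE)
    pass_depth <- !is.na(mean_dp) & mean_dp > t$min_depth
    n_fail_depth <- sum(!pass_depth)
  } else {
    mask <- !is.na(geno$depth) & geno$depth <= t$min_depth
    n_fail_depth <- 0L  # genotype mode masks rather than removing sites
    geno$dosage[mask] <- NA_integer_
  }

  d <- geno$dosage
  n_obs <- colSums(!is.na(d))
  ac <- colSums(d, na.rm = TRUE)
  p <- ifelse(n_obs > 0, ac / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  pass_maf <- !is.na(maf) & maf > t$min_maf
  miss <- colMeans(is.na(d))
  pass_miss <- miss < t$max_missing

  keep <- pass_maf & pass_depth & pass_miss
  report <- data.frame(
    criterion = c("maf", "depth", "missing"),
    threshold = c(t$min_maf, t$min_depth, t$max_missing),
    n_failed = c(sum(!pass_maf), n_fail_depth, sum(!pass_miss))
  )
  if (!any(keep)) warning("all variants removed by filtering")
  out <- subset_geno(geno, variants = keep)
  attr(out, "filter_report") <- list(criteria = report, n_in = n_in,
                                     n_retained = sum(keep),
                                     depth_mode = depth_mode)
  out
}

#' Retrieve the filtering report from a filtered genotype matrix
#'
#' @param geno a `genotype_matrix` returned by [filter_variants()].
#' @return list with per-criterion failure counts and totals, or `NULL`.
#' @export
filter_report <- function(geno) attr(geno, "filter_report")
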