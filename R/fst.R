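#' Weir-Cockerham per-site variance components for two populations
#'
#' Computes, per site, the among-population component `a` and the total
#' `a + b + c` of the Weir & Cockerham (1984) Fst estimator, with sample
#' sizes counted from non-missing diploid genotypes. Sites where either
#' population has fewer than 2 genotyped individuals are unusable (`NA`).
#'
#' @param geno a [genotype_matrix()].
#' @param popA,popB population names.
#' @return list with numeric vectors `a` and `d` (= a + b + c) per site.
#' @keywords internal
wc_site_components <- function(geno, popA, popB) {
  ca <- pop_site_counts(geno, popA)
  cb <- pop_site_counts(geno, popB)
  nA <- ca$n_ind
  nB <- cb$n_ind
  ok <- nA >= 2 & nB >= 2
  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pA <- ca$p
  pB <- cb$p
  p_bar <- (nA * pA + nB * pB) / (nA + nB)
  s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (nA * ca$het + nB * cb$het) / (nA + nB)
  a <- n_bar / n_c *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  d <- a + b + cc
  a[!ok] <- NA_real_
  d[!ok] <- NA_real_
  list(a = a, d = d)
}

#' Genome-wide Weir-Cockerham Fst between two populations
#'
#' Ratio-of-sums estimate `sum(a) / sum(a+b+c)` over all usable sites
#' (VCFtools' weighted Fst). Sites with a zero denominator are skipped.
#' Negative finite-sample estimates are returned unclamped.
#'
#' @inheritParams wc_site_components
#' @return a single number, or `NA` when no usable sites exist.
#' @export
global_fst <- function(geno, popA, popB) {
  comp <- wc_site_components(geno, popA, popB)
  use <- !is.na(comp$d) & comp$d != 0
  if (!any(use)) return(NA_real_)
  sum(comp$a[use]) / sum(comp$d[use])
}

#' Windowed Weir-Cockerham Fst between two populations
#'
#' Per-window ratio-of-sums of the per-site variance components. Windows
#' with no usable sites get `NA`.
#'
#' @inheritParams wc_site_components
#' @param spec a [window_spec()].
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `fst`, `partial`.
#' @export
windowed_fst <- function(geno, popA, popB, spec = window_spec()) {
  comp <- wc_site_components(geno, popA, popB)
  use <- !is.na(comp$d) & comp$d != 0
  windows <- make_windows(chrom_lengths(geno), spec)
  agg <- window_apply(geno, windows,
                      cbind(a = ifelse(use, comp$a, 0),
                            d = ifelse(use, comp$d, 0),
                            n = as.numeric(use)))
  windows$n_sites <- as.integer(agg[, "n"])
  windows$fst <- ifelse(agg[, "d"] != 0, agg[, "a"] / agg[, "d"], NA_real_)
  windows[c("chrom", "start", "end", "n_sites", "fst", "partial")]
}

#' Pairwise genome-wide Fst matrix over all populations
#'
#' @param geno a [genotype_matrix()].
#' @return symmetric matrix of [global_fst()] values with zero diagonal.
#' @export
pairwise_fst_matrix <- function(geno) {
  pops <- populations(geno)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- global_fst(geno, pops[i], pops[j])
    }
  }
  m
}

#' Genome-wide Hudson Fst between two populations
#'
#' Hudson's estimator (ratio of sums of per-site numerator
#' `(pA-pB)^2 - pA*qA/(nA-1) - pB*qB/(nB-1)` over `pA*qB + pB*qA`, with n in
#' allele copies), provided as a labelled alternative for cross-checks
#' against the default Weir-Cockerham estimator.
#'
#' @inheritParams wc_site_components
#' @return a single number, or `NA` when no usable sites exist.
#' @export
hudson_fst <- function(geno, popA, popB) {
  ca <- pop_site_counts(geno, popA)
  cb <- pop_site_counts(geno, popB)
  ok <- ca$n >= 2 & cb$n >= 2
  pA <- ca$p
  pB <- cb$p
  num <- (pA - pB)^2 - pA * (1 - pA) / (ca$n - 1) - pB * (1 - pB) / (cb$n - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  use <- ok & !is.na(den) & den != 0
  if (!any(use)) return(NA_real_)
  sum(num[use]) / sum(den[use])
}
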