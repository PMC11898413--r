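#' Genotype matrix for a multi-population cohort
#'
#' The central data container: diploid alt-allele dosages (0, 1, 2 or `NA` for
#' missing) for samples x variants, with 1-based variant coordinates, optional
#' per-genotype sequencing depth, a population label per sample, and exactly
#' one population flagged as the reference (the zero-pressure baseline used by
#' the ROD scan).
#'
#' Variants are stored sorted by (chromosome, position); chromosomes keep
#' their order of first appearance.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns; values in \{0, 1, 2\} or `NA`.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based positions, one per variant.
#' @param pops named character vector mapping sample id to population name;
#'   must cover every row of `dosage`.
#' @param ref_pop name of the reference population.
#' @param depth optional integer matrix of per-genotype read depths, same
#'   shape as `dosage`.
#' @param chrom_len optional named numeric vector of chromosome lengths (bp);
#'   when absent, window grids fall back to the last observed position.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, pops, ref_pop,
                            depth = NULL, chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    stop("dosage must have sample ids as rownames")
  }
  samples <- rownames(dosage)
  n_var <- ncol(dosage)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != n_var || length(pos) != n_var) {
    stop("chrom and pos must have one entry per variant (column of dosage)")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (n_var > 0 && nrow(dosage) > 0 &&
      (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))) {
    stop("dosage values must lie in {0, 1, 2} or be NA")
  }
  if (!all(samples %in% names(pops))) {
    missing_s <- setdiff(samples, names(pops))
    stop("samples without a population label: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  }
  pops <- pops[samples]
  if (!ref_pop %in% pops) {
    stop("reference population '", ref_pop, "' has no samples")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(dosage))) stop("depth must match dosage shape")
    rownames(depth) <- samples
  }
  chrom_f <- factor(chrom, levels = unique(chrom))
  o <- order(chrom_f, pos)
  dosage <- dosage[, o, drop = FALSE]
  if (!is.null(depth)) depth <- depth[, o, drop = FALSE]
  structure(
    list(dosage = dosage, depth = depth,
         chrom = chrom[o], pos = pos[o],
         samples = samples, pops = pops, ref_pop = ref_pop,
         chrom_len = chrom_len),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      length(x$pos), "variants\n")
  tab <- table(x$pops)
  cat("populations:",
      paste(sprintf("%s(%d)%s", names(tab), tab,
                    ifelse(names(tab) == x$ref_pop, "*", "")),
            collapse = " "),
      "  (* = reference)\n")
  cat("chromosomes:", paste(unique(x$chrom), collapse = " "), "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_variants <- function(x) length(x$pos)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname genotype_matrix
#' @export
populations <- function(x) unique(unname(x$pops))

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param variants integer or logical index over variants.
#' @param samples character vector of sample ids, or index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_geno <- function(x, variants = NULL, samples = NULL) {
  dosage <- x$dosage
  depth <- x$depth
  chrom <- x$chrom
  pos <- x$pos
  if (!is.null(variants)) {
    dosage <- dosage[, variants, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, variants, drop = FALSE]
    chrom <- chrom[variants]
    pos <- pos[variants]
  }
  if (!is.null(samples)) {
    dosage <- dosage[samples, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[samples, , drop = FALSE]
  }
  genotype_matrix(dosage, chrom, pos, x$pops[rownames(dosage)], x$ref_pop,
                  depth = depth, chrom_len = x$chrom_len)
}

#' Effective chromosome lengths of a genotype matrix
#'
#' Returns the declared chromosome lengths when the matrix carries them
#' (simulated cohorts do), otherwise the last observed position per
#' chromosome; this is the grid [make_windows()] tiles.
#'
#' @param x a `genotype_matrix`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(x) {
  if (!is.null(x$chrom_len)) {
    return(x$chrom_len[unique(x$chrom)])
  }
  out <- tapply(x$pos, factor(x$chrom, levels = unique(x$chrom)), max)
  stats::setNames(as.numeric(out), names(out))
}

as_dosage <- function(x) {
  if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
}

# Per-site allele bookkeeping for one population:
# n  = non-missing allele copies, ac = alt-allele copies, p = alt frequency,
# n_ind = non-missing diploid individuals, het = observed heterozygote
# fraction among non-missing individuals.
pop_site_counts <- function(x, pop) {
  rows <- which(x$pops == pop)
  if (length(rows) == 0) stop("population '", pop, "' not present")
  d <- x$dosage[rows, , drop = FALSE]
  n_ind <- colSums(!is.na(d))
  ac <- colSums(d, na.rm = TRUE)
  n <- 2L * n_ind
  p <- ifelse(n > 0, ac / n, NA_real_)
  het <- ifelse(n_ind > 0, colSums(d == 1L, na.rm = TRUE) / n_ind, NA_real_)
  list(n = n, ac = ac, p = p, n_ind = n_ind, het = het)
}

# Unbiased per-site heterozygosity 2*p*q*n/(n-1); NA where fewer than 2
# allele copies are observed.
site_pi <- function(n, ac) {
  p <- ac / n
  h <- 2 * p * (1 - p) * n / (n - 1)
  h[n < 2] <- NA_real_
  h
}
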