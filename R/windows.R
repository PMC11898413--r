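#' Sliding-window specification
#'
#' @param window_size window span in bp (default 100 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(window_size = 100000, step = 10000) {
  if (window_size <= 0 || step <= 0) stop("window_size and step must be > 0")
  if (step > window_size) stop("step must not exceed window_size")
  structure(list(window_size = as.numeric(window_size),
                 step = as.numeric(step)), class = "window_spec")
}

#' Build the sliding-window grid for a set of chromosomes
#'
#' Windows are half-open `[start, end)` in 1-based coordinates, starting at
#' 1, 1 + step, 1 + 2*step, ...; trailing windows clipped by the chromosome
#' end are retained and flagged `partial`.
#'
#' @param chrom_len named numeric vector of chromosome lengths.
#' @param spec a [window_spec()].
#' @return data.frame with columns `chrom`, `start`, `end`, `partial`.
#' @export
make_windows <- function(chrom_len, spec = window_spec()) {
  out <- lapply(names(chrom_len), function(cn) {
    len <- chrom_len[[cn]]
    starts <- seq(1, len, by = spec$step)
    ends <- pmin(starts + spec$window_size, len + 1)
    data.frame(chrom = cn, start = starts, end = ends,
               partial = (ends - starts) < spec$window_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sum per-site value columns over each window via cumulative sums.
# `pos` must be sorted ascending within the chromosome; vals is an L x m
# matrix (NA treated as 0 by the caller).
win_agg <- function(pos, vals, starts, ends) {
  vals <- as.matrix(vals)
  cs <- apply(vals, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- findInterval(starts - 1, pos)
  hi <- findInterval(ends - 1, pos)
  cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]
}

# Apply win_agg chromosome by chromosome over a window grid.
window_apply <- function(geno, windows, vals) {
  vals <- as.matrix(vals)
  out <- matrix(0, nrow = nrow(windows), ncol = ncol(vals),
                dimnames = list(NULL, colnames(vals)))
  for (cn in unique(windows$chrom)) {
    wi <- windows$chrom == cn
    si <- geno$chrom == cn
    if (!any(si)) next
    out[wi, ] <- win_agg(geno$pos[si], vals[si, , drop = FALSE],
                         windows$start[wi], windows$end[wi])
  }
  out
}

#' Windowed nucleotide diversity for one population
#'
#' Per-site diversity is the unbiased heterozygosity `2*p*q*n/(n-1)` with `n`
#' the non-missing allele copies in the population at that site; window pi is
#' the sum of per-site values divided by the window span (the VCFtools
#' windowed-pi convention: monomorphic and unobserved positions contribute 0
#' to the numerator and full length to the denominator). Sites with fewer
#' than 2 observed copies are unusable and skipped.
#'
#' @param geno a filtered [genotype_matrix()].
#' @param pop population name.
#' @param spec a [window_spec()].
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `pi`, `partial`.
#' @export
windowed_pi <- function(geno, pop, spec = window_spec()) {
  if (!pop %in% geno$pops) stop("population '", pop, "' not present")
  cnt <- pop_site_counts(geno, pop)
  h <- site_pi(cnt$n, cnt$ac)
  usable <- !is.na(h)
  windows <- make_windows(chrom_lengths(geno), spec)
  agg <- window_apply(geno, windows,
                      cbind(h = ifelse(usable, h, 0),
                            n = as.numeric(usable)))
  windows$n_sites <- as.integer(agg[, "n"])
  windows$pi <- agg[, "h"] / (windows$end - windows$start)
  windows[c("chrom", "start", "end", "n_sites", "pi", "partial")]
}

#' Genome-wide per-site nucleotide diversity for one population
#'
#' Sum of per-site unbiased heterozygosity divided by total genome length
#' (the genome-wide reduction of the windowed statistic).
#'
#' @inheritParams windowed_pi
#' @return a single number.
#' @export
genome_pi <- function(geno, pop) {
  cnt <- pop_site_counts(geno, pop)
  h <- site_pi(cnt$n, cnt$ac)
  sum(h, na.rm = TRUE) / sum(chrom_lengths(geno))
}

# ---- Tajima's D ------------------------------------------------------------

# The canonical constants (Tajima 1989) for a sample of n allele copies.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D for one population
#'
#' `D = (pi_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))` per window, where `pi_hat`
#' is the mean-pairwise-difference estimate (sum over sites of unbiased
#' heterozygosity, on the count scale) and `S` the number of segregating
#' sites among non-missing genotypes. Windows with `S = 0` get `NA`. With
#' missing data the constants use the rounded mean copy count over the
#' window's segregating sites.
#'
#' @inheritParams windowed_pi
#' @return data.frame: `chrom`, `start`, `end`, `n_sites` (segregating
#'   sites), `tajima_d`, `partial`.
#' @export
windowed_tajima_d <- function(geno, pop, spec = window_spec()) {
  if (!pop %in% geno$pops) stop("population '", pop, "' not present")
  cnt <- pop_site_counts(geno, pop)
  if (2 * sum(geno$pops == pop) < 4) {
    stop("Tajima's D needs at least 4 allele copies in population '",
         pop, "'")
  }
  seg <- cnt$n >= 4 & cnt$ac > 0 & cnt$ac < cnt$n
  h <- site_pi(cnt$n, cnt$ac)
  windows <- make_windows(chrom_lengths(geno), spec)
  agg <- window_apply(geno, windows,
                      cbind(pi = ifelse(seg, h, 0),
                            S = as.numeric(seg),
                            ncop = ifelse(seg, cnt$n, 0)))
  S <- agg[, "S"]
  pihat <- agg[, "pi"]
  nbar <- ifelse(S > 0, round(agg[, "ncop"] / S), NA_real_)
  d <- rep(NA_real_, nrow(windows))
  ok <- which(S > 0 & !is.na(nbar) & nbar >= 4)
  for (nv in unique(nbar[ok])) {
    k <- tajima_constants(nv)
    sel <- ok[nbar[ok] == nv]
    vr <- k$e1 * S[sel] + k$e2 * S[sel] * (S[sel] - 1)
    d[sel] <- (pihat[sel] - S[sel] / k$a1) / sqrt(vr)
  }
  windows$n_sites <- as.integer(S)
  windows$tajima_d <- d
  windows[c("chrom", "start", "end", "n_sites", "tajima_d", "partial")]
}
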