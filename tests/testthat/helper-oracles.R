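# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (loops, allele-copy expansion) so they share no code
# path with the package implementations they check.

# Build a genotype_matrix from a samples x variants dosage matrix with
# minimal ceremony. `pops` maps each sample to a population; default is a
# single population "A" with "A" as reference.
toy_geno <- function(dosage, pops = NULL, ref_pop = NULL, chrom = NULL,
                     pos = NULL, depth = NULL, chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  }
  if (is.null(pops)) {
    pops <- setNames(rep("A", nrow(dosage)), rownames(dosage))
  }
  ref_pop <- ref_pop %||% pops[[1]]
  chrom <- chrom %||% rep("chr1", ncol(dosage))
  pos <- pos %||% seq_len(ncol(dosage))
  rodscan:::genotype_matrix(dosage, chrom, pos, pops, ref_pop,
                            depth = depth, chrom_len = chrom_len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand one population's dosages at one site into allele copies (0/1).
allele_copies <- function(dos) {
  dos <- dos[!is.na(dos)]
  unlist(lapply(dos, function(g) c(rep(1L, g), rep(0L, 2L - g))))
}

# Oracle per-site pi: proportion of differing pairs among allele copies.
oracle_site_pi <- function(dos) {
  cp <- allele_copies(dos)
  n <- length(cp)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diffs <- diffs + (cp[i] != cp[j])
  }
  unname(diffs / choose(n, 2))
}

# Oracle window pi for one population over [start, end).
oracle_window_pi <- function(dosage_pop, pos, start, end) {
  idx <- which(pos >= start & pos < end)
  tot <- 0
  for (l in idx) {
    v <- oracle_site_pi(dosage_pop[, l])
    if (!is.na(v)) tot <- tot + v
  }
  tot / (end - start)
}

# Oracle Weir & Cockerham (1984) per-site components for two populations,
# written scalar-by-scalar from the published formulas.
oracle_wc_site <- function(dosA, dosB) {
  dosA <- dosA[!is.na(dosA)]
  dosB <- dosB[!is.na(dosB)]
  if (length(dosA) < 2 || length(dosB) < 2) return(c(a = NA, d = NA))
  r <- 2
  ns <- c(length(dosA), length(dosB))
  ps <- c(sum(dosA) / (2 * length(dosA)), sum(dosB) / (2 * length(dosB)))
  hs <- c(mean(dosA == 1), mean(dosB == 1))
  n_bar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  p_bar <- sum(ns * ps) / sum(ns)
  s2 <- sum(ns * (ps - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(ns * hs) / sum(ns)
  a <- (n_bar / nc) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, d = a + b + cc)
}

# Oracle ratio-of-sums Fst over a set of sites.
oracle_fst <- function(dosage_A, dosage_B) {
  A <- 0
  D <- 0
  for (l in seq_len(ncol(dosage_A))) {
    comp <- oracle_wc_site(dosage_A[, l], dosage_B[, l])
    if (!any(is.na(comp)) && comp["d"] != 0) {
      A <- A + comp["a"]
      D <- D + comp["d"]
    }
  }
  unname(A / D)
}

# Oracle Tajima's D from a complete (no-missing) dosage block.
oracle_tajima_d <- function(dosage_pop) {
  n <- 2 * nrow(dosage_pop)
  S <- 0
  pihat <- 0
  for (l in seq_len(ncol(dosage_pop))) {
    ac <- sum(dosage_pop[, l])
    if (ac > 0 && ac < n) {
      S <- S + 1
      pihat <- pihat + ac * (n - ac) / choose(n, 2)
    }
  }
  if (S == 0) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Random small genotype fixture (with optional missingness) for oracle tests.
random_fixture <- function(seed, n_per_pop = 6, n_sites = 25,
                           missing = 0.1, n_pops = 2) {
  set.seed(seed)
  n <- n_per_pop * n_pops
  p <- runif(n_sites, 0.1, 0.9)
  dos <- matrix(rbinom(n * n_sites, 2, rep(p, each = n)), nrow = n)
  if (missing > 0) dos[runif(length(dos)) < missing] <- NA
  rownames(dos) <- paste0("s", 1:n)
  pops <- setNames(rep(paste0("P", seq_len(n_pops)), each = n_per_pop),
                   rownames(dos))
  toy_geno(dos, pops = pops, ref_pop = "P1",
           pos = sort(sample.int(1e5, n_sites)),
           chrom_len = c(chr1 = 1e5))
}

# A window of diploid genotypes whose segregating sites follow the neutral
# sample SFS (derived-allele count i with probability proportional to 1/i),
# for checking the centering of Tajima's D.
neutral_sfs_window <- function(n_dip, S) {
  n <- 2 * n_dip
  probs <- (1 / seq_len(n - 1))
  counts <- sample(seq_len(n - 1), S, replace = TRUE, prob = probs)
  dos <- sapply(counts, function(ac) {
    copies <- sample(c(rep(1L, ac), rep(0L, n - ac)))
    copies[seq(1, n, by = 2)] + copies[seq(2, n, by = 2)]
  })
  matrix(dos, nrow = n_dip)
}
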