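#' Configuration for a simulated resequencing cohort
#'
#' Describes a seeded multi-population cohort under the Balding-Nichols
#' F-model: every variable site has an ancestral frequency drawn from
#' `maf_spectrum`, each population's site frequency is a Beta draw around it
#' with differentiation parameter `divergence_F`, and diploid genotypes are
#' binomial draws from the population frequency. Sweeps are implanted as
#' frequency pushes toward fixation inside declared intervals. Site density is
#' chosen so that expected genome-wide per-site nucleotide diversity matches
#' `target_pi`.
#'
#' @param seed integer; fully determines the cohort.
#' @param n_pops number of populations.
#' @param samples_per_pop diploid individuals per population.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (scalar or per-chromosome
#'   vector).
#' @param target_pi expected genome-wide per-site nucleotide diversity
#'   (dimensionless; default 3.1e-3, the scale observed in coastal marine
#'   fish cohorts).
#' @param divergence_F Balding-Nichols F per population (scalar recycled, or
#'   one value per population), each in \[0, 1).
#' @param sweep_intervals `NULL` or a data.frame with columns `chrom`,
#'   `start`, `end`, `pops` (comma-separated population names), `reduction`
#'   (fraction of diversity removed, in (0, 1\]).
#' @param admixture_spec `NULL`, or `list(K =, alpha =)`: individuals then
#'   draw ancestry proportions from Dirichlet(`alpha`) over `K` ancestral
#'   sources whose site frequencies are independent Balding-Nichols draws.
#' @param depth_model `NULL` (no depth simulated) or `c(mean =, size =)` for a
#'   negative-binomial per-genotype read depth.
#' @param missing_rate independent per-genotype missingness probability in
#'   \[0, 1).
#' @param maf_spectrum `c(lo, hi)` bounds of the uniform ancestral-frequency
#'   spectrum.
#' @param pop_names optional population names (default `pop1`, `pop2`, ...).
#' @param ref_pop name of the reference population (default the first).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_pops = 6L,
                              samples_per_pop = 10L,
                              n_chroms = 2L,
                              chrom_length = 1e6,
                              target_pi = 3.1e-3,
                              divergence_F = 0.001,
                              sweep_intervals = NULL,
                              admixture_spec = NULL,
                              depth_model = c(mean = 12.6, size = 5),
                              missing_rate = 0.02,
                              maf_spectrum = c(0.05, 0.95),
                              pop_names = NULL,
                              ref_pop = NULL) {
  if (n_pops < 1 || samples_per_pop < 1) {
    stop("need at least one population with at least one sample")
  }
  if (n_chroms < 1) stop("need at least one chromosome")
  chrom_length <- rep_len(as.numeric(chrom_length), n_chroms)
  if (any(chrom_length < 1)) stop("chromosome lengths must be positive")
  if (target_pi <= 0) stop("target_pi must be positive")
  divergence_F <- rep_len(divergence_F, n_pops)
  if (any(divergence_F < 0 | divergence_F >= 1)) {
    stop("divergence_F must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (length(maf_spectrum) != 2 || maf_spectrum[1] <= 0 ||
      maf_spectrum[2] >= 1 || maf_spectrum[1] >= maf_spectrum[2]) {
    stop("maf_spectrum must be c(lo, hi) with 0 < lo < hi < 1")
  }
  pop_names <- pop_names %||% paste0("pop", seq_len(n_pops))
  if (length(pop_names) != n_pops) stop("pop_names must have length n_pops")
  ref_pop <- ref_pop %||% pop_names[1]
  if (!ref_pop %in% pop_names) stop("ref_pop must be one of pop_names")
  chrom_names <- paste0("chr", seq_len(n_chroms))
  if (!is.null(sweep_intervals)) {
    sweep_intervals <- as.data.frame(sweep_intervals)
    need <- c("chrom", "start", "end", "pops", "reduction")
    if (!all(need %in% names(sweep_intervals))) {
      stop("sweep_intervals needs columns ", paste(need, collapse = ", "))
    }
    if (!all(sweep_intervals$chrom %in% chrom_names)) {
      stop("sweep interval on unknown chromosome")
    }
    len <- chrom_length[match(sweep_intervals$chrom, chrom_names)]
    if (any(sweep_intervals$start < 1 | sweep_intervals$end > len |
            sweep_intervals$start >= sweep_intervals$end)) {
      stop("sweep intervals must lie within chromosome bounds")
    }
    if (any(sweep_intervals$reduction <= 0 | sweep_intervals$reduction > 1)) {
      stop("diversity reduction must lie in (0, 1]")
    }
    sw_pops <- unlist(strsplit(sweep_intervals$pops, ","))
    if (!all(trimws(sw_pops) %in% pop_names)) {
      stop("sweep interval names an unknown population")
    }
  }
  if (!is.null(admixture_spec)) {
    if (is.null(admixture_spec$K) || admixture_spec$K < 1) {
      stop("admixture_spec$K must be >= 1")
    }
    admixture_spec$alpha <- rep_len(admixture_spec$alpha %||% 1,
                                    admixture_spec$K)
  }
  if (!is.null(depth_model)) {
    if (is.null(names(depth_model))) names(depth_model) <- c("mean", "size")
    if (depth_model[["mean"]] <= 0 || depth_model[["size"]] <= 0) {
      stop("depth_model mean and size must be positive")
    }
  }
  structure(
    list(seed = as.integer(seed), n_pops = as.integer(n_pops),
         samples_per_pop = as.integer(samples_per_pop),
         n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
         chrom_names = chrom_names, target_pi = target_pi,
         divergence_F = divergence_F, sweep_intervals = sweep_intervals,
         admixture_spec = admixture_spec, depth_model = depth_model,
         missing_rate = missing_rate, maf_spectrum = maf_spectrum,
         pop_names = pop_names, ref_pop = ref_pop),
    class = "simulation_config"
  )
}

# Expected 2*p*(1-p) under a Uniform(lo, hi) ancestral spectrum (closed form).
spectrum_het <- function(lo, hi) {
  ep <- (lo + hi) / 2
  ep2 <- (lo^2 + lo * hi + hi^2) / 3
  2 * (ep - ep2)
}

balding_nichols <- function(p, f) {
  out <- p
  pos <- f > 0
  if (any(pos)) {
    shape1 <- p[pos] * (1 - f[pos]) / f[pos]
    shape2 <- (1 - p[pos]) * (1 - f[pos]) / f[pos]
    out[pos] <- stats::rbeta(sum(pos), shape1, shape2)
  }
  out
}

#' Simulate a multi-population genotype cohort with known truth
#'
#' Draws a seeded cohort under the model described in
#' [simulation_config()] and returns both the genotype matrix and a truth
#' record (ancestral and per-population site frequencies, per-population F,
#' ancestry proportions when admixed, and the implanted sweep intervals) for
#' recovery testing.
#'
#' @param config a [simulation_config()].
#' @return `list(geno = genotype_matrix, truth = list(...))`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  genome_len <- sum(cfg$chrom_length)
  # Site density so that E[genome-wide per-site pi] ~ target_pi. Each variable
  # site contributes 2*p_pop*q_pop in expectation, i.e. 2*p*q*(1-F) averaged
  # over the spectrum.
  f_mean <- mean(cfg$divergence_F)
  e_het <- spectrum_het(cfg$maf_spectrum[1], cfg$maf_spectrum[2]) *
    (1 - f_mean)
  n_sites <- round(cfg$target_pi * genome_len / e_het)
  if (n_sites < 1) stop("configuration yields zero variable sites")
  per_chrom <- pmax(1, round(n_sites * cfg$chrom_length / genome_len))
  chrom <- rep(cfg$chrom_names, per_chrom)
  pos <- unlist(lapply(seq_len(cfg$n_chroms), function(i) {
    sort(sample.int(cfg$chrom_length[i], per_chrom[i]))
  }))
  L <- length(pos)
  p_anc <- stats::runif(L, cfg$maf_spectrum[1], cfg$maf_spectrum[2])

  n_pop <- cfg$n_pops
  k_per <- cfg$samples_per_pop
  n_ind <- n_pop * k_per
  pop_of_sample <- rep(cfg$pop_names, each = k_per)
  sample_ids <- paste0(pop_of_sample, "_", rep(seq_len(k_per), times = n_pop))

  # Per-population site frequencies (Balding-Nichols around the ancestral
  # frequency), then sweep pushes toward fixation.
  pop_freq <- matrix(NA_real_, nrow = n_pop, ncol = L,
                     dimnames = list(cfg$pop_names, NULL))
  for (j in seq_len(n_pop)) {
    pop_freq[j, ] <- balding_nichols(p_anc, rep(cfg$divergence_F[j], L))
  }
  if (!is.null(cfg$sweep_intervals)) {
    for (k in seq_len(nrow(cfg$sweep_intervals))) {
      iv <- cfg$sweep_intervals[k, ]
      in_iv <- chrom == iv$chrom & pos >= iv$start & pos < iv$end
      affected <- trimws(strsplit(iv$pops, ",")[[1]])
      for (pn in affected) {
        idx <- which(in_iv)
        hit <- idx[stats::runif(length(idx)) < iv$reduction]
        # Limiting Beta({0,1}) push: fix the allele with probability equal to
        # its current frequency; scales E[2pq] by exactly (1 - reduction).
        pop_freq[pn, hit] <- stats::rbinom(length(hit), 1L, pop_freq[pn, hit])
      }
    }
  }

  truth_q <- NULL
  if (!is.null(cfg$admixture_spec)) {
    K <- cfg$admixture_spec$K
    src_freq <- matrix(NA_real_, nrow = K, ncol = L)
    for (k in seq_len(K)) {
      src_freq[k, ] <- balding_nichols(p_anc, rep(f_mean, L))
    }
    truth_q <- rdirichlet(n_ind, cfg$admixture_spec$alpha)
    rownames(truth_q) <- sample_ids
    ind_freq <- truth_q %*% src_freq
    dosage <- matrix(stats::rbinom(n_ind * L, 2L, ind_freq),
                     nrow = n_ind, dimnames = list(sample_ids, NULL))
  } else {
    ind_freq <- pop_freq[pop_of_sample, , drop = FALSE]
    dosage <- matrix(stats::rbinom(n_ind * L, 2L, ind_freq),
                     nrow = n_ind, dimnames = list(sample_ids, NULL))
    src_freq <- NULL
  }

  depth <- NULL
  if (!is.null(cfg$depth_model)) {
    depth <- matrix(stats::rnbinom(n_ind * L, mu = cfg$depth_model[["mean"]],
                                   size = cfg$depth_model[["size"]]),
                    nrow = n_ind, dimnames = list(sample_ids, NULL))
  }
  if (cfg$missing_rate > 0) {
    dosage[stats::runif(n_ind * L) < cfg$missing_rate] <- NA_integer_
  }

  geno <- genotype_matrix(
    dosage, chrom, pos,
    pops = stats::setNames(pop_of_sample, sample_ids),
    ref_pop = cfg$ref_pop, depth = depth,
    chrom_len = stats::setNames(cfg$chrom_length, cfg$chrom_names)
  )
  truth <- list(
    F = stats::setNames(cfg$divergence_F, cfg$pop_names),
    p_anc = p_anc, pop_freq = pop_freq,
    src_freq = if (!is.null(cfg$admixture_spec)) src_freq else NULL,
    Q = truth_q,
    sweep_intervals = cfg$sweep_intervals,
    config = cfg
  )
  list(geno = geno, truth = truth)
}

#' Lay out non-overlapping synthetic gene models
#'
#' Convenience generator for GFF3 fixtures: evenly spaced gene spans per
#' chromosome, for exercising region-to-gene overlap.
#'
#' @param chrom_len named vector of chromosome lengths.
#' @param n_per_chrom genes per chromosome.
#' @param gene_length span of each gene in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
synthetic_genes <- function(chrom_len, n_per_chrom = 10, gene_length = 10000) {
  out <- lapply(names(chrom_len), function(cn) {
    len <- chrom_len[[cn]]
    starts <- round(seq(1, max(1, len - gene_length),
                        length.out = n_per_chrom))
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + gene_length - 1, len),
               gene_id = sprintf("%s_g%02d", cn, seq_len(n_per_chrom)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
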