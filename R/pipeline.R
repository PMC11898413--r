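#' Run the full scan pipeline from a configuration
#'
#' Wires the stages simulate (or load) -> filter -> windowed statistics ->
#' sweep scan -> population structure into one reproducible run. Every
#' stochastic stage receives an explicit seed derived from `config$seed`;
#' rerunning with an identical configuration reproduces byte-identical
#' outputs. A `manifest.json` recording stages, seeds, parameters and output
#' file checksums is written into the run directory.
#'
#' @param config a named list, or the path of a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{run directory (created if absent).}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{simulate}{optional list of [simulation_config()] arguments; when
#'       present the cohort is simulated and serialized (VCF + population
#'       table + GFF of synthetic gene models).}
#'     \item{input}{alternative to `simulate`: list with `vcf`, `pop_table`,
#'       `ref_pop`, and optionally `gff`.}
#'     \item{filter}{optional [filter_thresholds()] arguments.}
#'     \item{windows}{optional [window_spec()] arguments.}
#'     \item{sweep}{optional: `top_frac`, `min_sites`, `max_gap`, `mode`.}
#'     \item{nj}{logical; build the IBS neighbor-joining tree.}
#'     \item{admix}{optional: `K_range`, `repeats`, `folds`, `max_sites`.}
#'   }
#' @return invisibly, a list with the computed objects (`geno`, `windows`,
#'   `sweep`, `tree`, `cv_table`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package = "rodscan",
                   version = as.character(utils::packageVersion("rodscan")),
                   seed = seed, stages = list())
  outputs <- character()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- acquire genotypes ----------------------------------------------------
  genes <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_cohort(cfg)
    geno <- sim$geno
    genes <- synthetic_genes(chrom_lengths(geno))
    vcf_path <- file.path(out_dir, "cohort.vcf")
    write_vcf(geno, vcf_path)
    write_pop_table(geno, file.path(out_dir, "populations.tsv"))
    write_gff(genes, file.path(out_dir, "genes.gff3"))
    outputs <- c(outputs, vcf_path,
                 file.path(out_dir, c("populations.tsv", "genes.gff3")))
    note("simulate", seed = cfg$seed, n_pops = cfg$n_pops,
         samples_per_pop = cfg$samples_per_pop,
         n_variants = n_variants(geno))
  } else if (!is.null(config$input)) {
    inp <- config$input
    if (is.null(inp$vcf) || !file.exists(inp$vcf)) {
      stop("input VCF not found: ", inp$vcf %||% "<missing>")
    }
    geno <- read_vcf(inp$vcf, inp$pop_table, inp$ref_pop)
    if (!is.null(inp$gff)) genes <- read_gff_genes(inp$gff)
    note("input", vcf = inp$vcf, n_variants = n_variants(geno))
  } else {
    stop("config needs either a 'simulate' or an 'input' section")
  }

  # --- filter ---------------------------------------------------------------
  thr <- do.call(filter_thresholds, config$filter %||% list())
  geno <- filter_variants(geno, thr)
  frep <- filter_report(geno)
  write_tsv(frep$criteria, file.path(out_dir, "filter_report.tsv"))
  outputs <- c(outputs, file.path(out_dir, "filter_report.tsv"))
  note("filter", n_in = frep$n_in, n_retained = frep$n_retained)

  # --- windowed statistics --------------------------------------------------
  spec <- do.call(window_spec, config$windows %||% list())
  pops <- populations(geno)
  pi_tabs <- lapply(pops, function(p) {
    w <- windowed_pi(geno, p, spec)
    data.frame(CHROM = w$chrom, BIN_START = w$start, BIN_END = w$end - 1,
               N_VARIANTS = w$n_sites, PI = w$pi, POP = p)
  })
  write_tsv(do.call(rbind, pi_tabs), file.path(out_dir, "windowed_pi.tsv"))
  fst_mat <- pairwise_fst_matrix(geno)
  write_tsv(cbind(POP = rownames(fst_mat), as.data.frame(fst_mat)),
            file.path(out_dir, "global_fst_matrix.tsv"))
  pi_genome <- vapply(pops, function(p) genome_pi(geno, p), numeric(1))
  write_tsv(data.frame(POP = pops, PI = unname(pi_genome)),
            file.path(out_dir, "genome_pi.tsv"))
  outputs <- c(outputs, file.path(out_dir, c("windowed_pi.tsv",
                                             "global_fst_matrix.tsv",
                                             "genome_pi.tsv")))
  note("windows", window_size = spec$window_size, step = spec$step)

  # --- sweep scan -----------------------------------------------------------
  sw_cfg <- config$sweep %||% list()
  scan_pops <- setdiff(pops, geno$ref_pop)
  sweep_out <- list()
  all_regions <- list()
  for (p in scan_pops) {
    sc <- sweep_scan(geno, p, spec,
                     top_frac = sw_cfg$top_frac %||% 0.05,
                     min_sites = sw_cfg$min_sites %||% 10,
                     max_gap = sw_cfg$max_gap %||% 0,
                     genes = genes,
                     mode = sw_cfg$mode %||% "intersection")
    sweep_out[[p]] <- sc
    if (nrow(sc$regions) > 0) {
      all_regions[[p]] <- cbind(population = p, sc$regions)
    }
    fst_rod <- sc$windows
    fst_rod_tab <- data.frame(
      CHROM = fst_rod$chrom, BIN_START = fst_rod$start,
      BIN_END = fst_rod$end - 1, N_VARIANTS = fst_rod$n_sites,
      WEIR_AND_COCKERHAM_FST = fst_rod$fst, ROD = fst_rod$rod,
      OUTLIER = fst_rod$outlier)
    write_tsv(fst_rod_tab,
              file.path(out_dir, paste0("scan_", p, ".tsv")))
    outputs <- c(outputs, file.path(out_dir, paste0("scan_", p, ".tsv")))
  }
  region_tab <- if (length(all_regions) > 0) {
    do.call(rbind, all_regions)
  } else {
    data.frame(population = character(), chrom = character(),
               start = numeric(), end = numeric(), n_windows = integer(),
               peak_fst = numeric(), peak_rod = numeric(),
               gene_ids = character())
  }
  write_tsv(region_tab, file.path(out_dir, "sweep_regions.tsv"))
  if (nrow(region_tab) > 0) {
    write_regions_bed(region_tab, file.path(out_dir, "sweep_regions.bed"))
    outputs <- c(outputs, file.path(out_dir, "sweep_regions.bed"))
  }
  outputs <- c(outputs, file.path(out_dir, "sweep_regions.tsv"))
  note("sweep", n_regions = nrow(region_tab))

  # --- population structure -------------------------------------------------
  tree <- NULL
  if (isTRUE(config$nj %||% TRUE)) {
    tree <- nj_tree(ibs_distance(geno))
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
    outputs <- c(outputs, file.path(out_dir, "nj_tree.nwk"))
    note("nj", n_tips = length(tree$tip.label))
  }
  cv_table <- NULL
  if (!is.null(config$admix)) {
    ad <- config$admix
    G <- geno
    max_sites <- ad$max_sites %||% 2000
    if (n_variants(geno) > max_sites) {
      keep <- with_seed(derive_seed(seed, 777), {
        sort(sample.int(n_variants(geno), max_sites))
      })
      G <- subset_geno(geno, variants = keep)
    }
    cv_table <- scan_K(G, K_range = ad$K_range %||% 1:6,
                       repeats = ad$repeats %||% 20L,
                       folds = ad$folds %||% 5L,
                       seed = derive_seed(seed, 42))
    write_tsv(cv_table, file.path(out_dir, "cv_scan.tsv"))
    best_k <- cv_table$K[which.min(cv_table$cv_min)]
    fit <- admixture_fit(G, K = max(best_k, 1), seed = derive_seed(seed, 43),
                         n_restarts = ad$n_restarts %||% 2L)
    q_tab <- data.frame(sample = geno$samples,
                        population = unname(geno$pops[geno$samples]),
                        fit$Q, check.names = FALSE)
    names(q_tab)[-(1:2)] <- paste0("Q", seq_len(fit$K))
    write_tsv(q_tab, file.path(out_dir, "admixture_Q.tsv"))
    outputs <- c(outputs, file.path(out_dir, c("cv_scan.tsv",
                                               "admixture_Q.tsv")))
    note("admix", best_K = best_k)
  }

  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(outputs)), basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(geno = geno, sweep = sweep_out, regions = region_tab,
                 tree = tree, cv_table = cv_table, manifest = manifest))
}
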