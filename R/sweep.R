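#' Reduction of diversity (ROD) relative to a reference population
#'
#' `ROD = |1 - pi_pop / pi_ref|`; the signed value `1 - pi_pop / pi_ref`
#' (positive when the population has lost diversity relative to the
#' reference) is returned alongside. Where `pi_ref` is 0 the statistic is
#' undefined (`NA`).
#'
#' @param pi_pop per-site diversity of the scanned population (vectorized).
#' @param pi_ref per-site diversity of the reference population.
#' @return data.frame with columns `rod` and `signed_rod`.
#' @export
rod <- function(pi_pop, pi_ref) {
  signed <- ifelse(!is.na(pi_ref) & pi_ref > 0, 1 - pi_pop / pi_ref,
                   NA_real_)
  data.frame(rod = abs(signed), signed_rod = signed)
}

#' Windowed ROD for one population against the reference
#'
#' Joins the population's and the reference's windowed diversity on the
#' common window grid and computes [rod()] per window. Windows where either
#' population has fewer than `min_sites` usable sites, or where the
#' reference diversity is 0, are undefined and excluded from ranking.
#'
#' @param geno a filtered [genotype_matrix()].
#' @param pop scanned population (must differ from the reference for a
#'   meaningful scan; scanning the reference itself yields all zeros).
#' @param spec a [window_spec()].
#' @param min_sites minimum usable sites per window (default 10).
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `pi_pop`,
#'   `pi_ref`, `rod`, `signed_rod`, `partial`.
#' @export
rod_windows <- function(geno, pop, spec = window_spec(), min_sites = 10) {
  wp <- windowed_pi(geno, pop, spec)
  wr <- windowed_pi(geno, geno$ref_pop, spec)
  stopifnot(identical(wp[c("chrom", "start")], wr[c("chrom", "start")]))
  out <- wp[c("chrom", "start", "end", "partial")]
  out$n_sites <- pmin(wp$n_sites, wr$n_sites)
  out$pi_pop <- wp$pi
  out$pi_ref <- wr$pi
  rv <- rod(wp$pi, wr$pi)
  low <- out$n_sites < min_sites
  rv$rod[low] <- NA_real_
  rv$signed_rod[low] <- NA_real_
  out$rod <- rv$rod
  out$signed_rod <- rv$signed_rod
  out[c("chrom", "start", "end", "n_sites", "pi_pop", "pi_ref",
        "rod", "signed_rod", "partial")]
}

#' Call outlier windows by the joint top-quantile Fst/ROD rule
#'
#' Computes the genome-wide `1 - top_frac` quantile of windowed Fst and of
#' ROD separately (undefined windows excluded) and flags windows at or above
#' each threshold. The called set is, by default, the intersection of the two
#' single-statistic outlier sets; `mode = "union"` is available. Ties at a
#' threshold are included.
#'
#' @param fst_win output of [windowed_fst()] (population vs reference).
#' @param rod_win output of [rod_windows()] for the same population and grid.
#' @param top_frac outlier fraction (default 0.05).
#' @param mode `"intersection"` (default) or `"union"`.
#' @param one_sided if `TRUE`, rank the signed ROD (diversity loss only)
#'   instead of the printed absolute value.
#' @return data.frame of the window grid with columns `fst`, `rod`,
#'   `fst_outlier`, `rod_outlier`, `outlier`, plus attributes
#'   `fst_threshold` and `rod_threshold`.
#' @export
call_outlier_windows <- function(fst_win, rod_win, top_frac = 0.05,
                                 mode = c("intersection", "union"),
                                 one_sided = FALSE) {
  mode <- match.arg(mode)
  stopifnot(identical(fst_win[c("chrom", "start")],
                      rod_win[c("chrom", "start")]))
  out <- rod_win[c("chrom", "start", "end", "n_sites", "partial")]
  out$fst <- fst_win$fst
  out$rod <- if (one_sided) rod_win$signed_rod else rod_win$rod
  ranked <- !is.na(out$fst) & !is.na(out$rod)
  n_ranked <- sum(ranked)
  if (n_ranked < 20) {
    warning("only ", n_ranked,
            " ranked windows; top-quantile thresholds are unstable")
  }
  fst_thr <- stats::quantile(out$fst[ranked], 1 - top_frac, na.rm = TRUE,
                             names = FALSE)
  rod_thr <- stats::quantile(out$rod[ranked], 1 - top_frac, na.rm = TRUE,
                             names = FALSE)
  out$fst_outlier <- ranked & out$fst >= fst_thr
  out$rod_outlier <- ranked & out$rod >= rod_thr
  out$outlier <- if (mode == "intersection") {
    out$fst_outlier & out$rod_outlier
  } else {
    out$fst_outlier | out$rod_outlier
  }
  expected <- ceiling(top_frac * n_ranked)
  if (n_ranked > 0 &&
      (sum(out$fst_outlier) > 2 * expected ||
       sum(out$rod_outlier) > 2 * expected)) {
    warning("ties at the outlier threshold inflate the outlier set")
  }
  attr(out, "fst_threshold") <- fst_thr
  attr(out, "rod_threshold") <- rod_thr
  out
}

#' Merge outlier windows into sweep regions
#'
#' Outlier windows on one chromosome that overlap, abut, or are separated by
#' at most `max_gap` bp are merged; region bounds are the minimum start and
#' maximum end, and peak window statistics are recorded.
#'
#' @param outliers data.frame of called windows (rows with `outlier = TRUE`
#'   of [call_outlier_windows()] output, or any window data.frame with
#'   `chrom`, `start`, `end` and optionally `fst`, `rod`).
#' @param max_gap maximum separation in bp between merged windows
#'   (default 0: only overlapping or adjacent windows merge).
#' @return data.frame: `chrom`, `start`, `end`, `n_windows`, `peak_fst`,
#'   `peak_rod`.
#' @export
merge_regions <- function(outliers, max_gap = 0) {
  if ("outlier" %in% names(outliers)) {
    outliers <- outliers[outliers$outlier, , drop = FALSE]
  }
  if (nrow(outliers) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      peak_fst = numeric(), peak_rod = numeric()))
  }
  outliers <- outliers[order(factor(outliers$chrom,
                                    levels = unique(outliers$chrom)),
                             outliers$start), , drop = FALSE]
  res <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = cur$n, peak_fst = cur$fst, peak_rod = cur$rod)
  }
  for (i in seq_len(nrow(outliers))) {
    w <- outliers[i, ]
    w_fst <- if ("fst" %in% names(w)) w$fst else NA_real_
    w_rod <- if ("rod" %in% names(w)) w$rod else NA_real_
    if (!is.null(cur) && w$chrom == cur$chrom &&
        (w$start - cur$end) <= max_gap) {
      cur$end <- max(cur$end, w$end)
      cur$n <- cur$n + 1L
      cur$fst <- max(cur$fst, w_fst, na.rm = TRUE)
      cur$rod <- max(cur$rod, w_rod, na.rm = TRUE)
    } else {
      if (!is.null(cur)) res[[length(res) + 1]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L,
                  fst = w_fst, rod = w_rod)
    }
  }
  res[[length(res) + 1]] <- flush(cur)
  do.call(rbind, res)
}

#' Attach overlapping genes to sweep regions
#'
#' A gene is attached to a region iff its span overlaps the region by at
#' least 1 bp (strand ignored). Regions use the package's half-open 1-based
#' convention; GFF gene coordinates are 1-based inclusive.
#'
#' @param regions output of [merge_regions()].
#' @param genes a GFF3 file path, or a data.frame with columns `chrom`,
#'   `start`, `end`, `gene_id` (1-based inclusive).
#' @return `regions` with an added character column `gene_ids`
#'   (comma-separated, `""` when empty).
#' @export
annotate_genes <- function(regions, genes) {
  if (is.character(genes)) genes <- read_gff_genes(genes)
  regions$gene_ids <- rep("", nrow(regions))
  if (nrow(regions) == 0 || nrow(genes) == 0) return(regions)
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start, end = regions$end - 1)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
  if (length(hits) > 0) {
    ids <- tapply(genes$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(g) paste(unique(g), collapse = ","))
    regions$gene_ids[as.integer(names(ids))] <- unname(ids)
  }
  regions
}

#' Read gene features from a GFF3 file
#'
#' Imports via rtracklayer and keeps `gene`-type features; the gene
#' identifier is taken from the `ID` attribute, falling back to `Name`.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- as.character(gr$ID)
  if (all(is.na(id)) && !is.null(gr$Name)) id <- as.character(gr$Name)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = id, stringsAsFactors = FALSE)
}

#' Full sweep scan of one population against the reference
#'
#' Convenience wrapper chaining [windowed_fst()], [rod_windows()],
#' [call_outlier_windows()], [merge_regions()] and, when gene models are
#' supplied, [annotate_genes()].
#'
#' @param geno a filtered [genotype_matrix()].
#' @param pop scanned population.
#' @param spec a [window_spec()].
#' @param top_frac outlier fraction (default 0.05).
#' @param min_sites minimum usable sites per ranked window.
#' @param max_gap merge gap in bp.
#' @param genes optional GFF3 path or gene data.frame.
#' @param mode `"intersection"` or `"union"` outlier rule.
#' @return list with elements `windows` (the called window grid) and
#'   `regions` (merged, optionally gene-annotated sweep regions).
#' @export
sweep_scan <- function(geno, pop, spec = window_spec(), top_frac = 0.05,
                       min_sites = 10, max_gap = 0, genes = NULL,
                       mode = "intersection") {
  if (pop == geno$ref_pop) {
    stop("scanned population must differ from the reference population")
  }
  fst_win <- windowed_fst(geno, pop, geno$ref_pop, spec)
  rod_win <- rod_windows(geno, pop, spec, min_sites = min_sites)
  called <- call_outlier_windows(fst_win, rod_win, top_frac = top_frac,
                                 mode = mode)
  regions <- merge_regions(called, max_gap = max_gap)
  if (!is.null(genes)) regions <- annotate_genes(regions, genes)
  list(windows = called, regions = regions)
}

#' Write sweep regions as a BED file
#'
#' Converts the package's 1-based half-open regions to BED's 0-based
#' half-open convention.
#'
#' @param regions output of [merge_regions()] / [sweep_scan()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d", regions$chrom,
                   as.integer(regions$start - 1), as.integer(regions$end - 1))
  writeLines(lines, path)
  invisible(path)
}
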