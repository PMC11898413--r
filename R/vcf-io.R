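#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with per-genotype GT (and optionally DP) fields into a
#' [genotype_matrix()]. Only biallelic SNP records are kept; multi-allelic
#' sites and indels are skipped with a reported count. GT fields are decoded
#' to alt-allele dosage regardless of phasing (`0/1` and `1|0` both give 1);
#' `./.` becomes missing.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param pop_table data.frame with columns `sample` and `population`, or the
#'   path of a 2-column TSV; must cover every sample in the VCF.
#' @param ref_pop name of the reference population.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_table, ref_pop) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  pop_table <- read_pop_table(pop_table)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip,
            " non-biallelic-SNP record(s)")
  }
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, pop_table$sample)
  if (length(unknown) > 0) {
    stop("VCF samples missing from population table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  gt_map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L,
              "1/0" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage <- matrix(gt_map[gt], nrow = nrow(gt))
  bad <- !is.na(gt) & !gt %in% c(names(gt_map), "./.", ".|.", ".")
  if (any(bad)) {
    message("read_vcf: ", sum(bad),
            " unparseable GT field(s) set to missing")
  }
  depth <- NULL
  fmt <- v@gt[snp, 1]
  if (any(grepl("DP", fmt))) {
    depth <- t(vcfR::extract.gt(v, element = "DP",
                                as.numeric = TRUE)[snp, , drop = FALSE])
    storage.mode(depth) <- "integer"
  }
  dosage <- t(dosage)
  rownames(dosage) <- vcf_samples
  genotype_matrix(
    dosage,
    chrom = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]),
    pops = stats::setNames(pop_table$population, pop_table$sample),
    ref_pop = ref_pop,
    depth = depth
  )
}

#' Read a sample-to-population assignment table
#'
#' @param x a data.frame with columns `sample` and `population`, or the path
#'   of a headerless or headered 2-column TSV.
#' @return a data.frame with columns `sample` and `population`.
#' @export
read_pop_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample", "population") %in% names(x)))
    return(x[c("sample", "population")])
  }
  df <- utils::read.table(x, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (all(tolower(unlist(df[1, ])) == c("sample", "population"))) {
    df <- df[-1, , drop = FALSE]
  }
  stats::setNames(df[, 1:2], c("sample", "population"))
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits a sorted plain-text VCF with GT (and DP when present) FORMAT fields.
#' Alleles are written as placeholder REF=A / ALT=T; dosage information
#' round-trips bit-identically through [read_vcf()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path) {
  if (n_variants(geno) == 0 || n_samples(geno) == 0) {
    stop("cannot write an empty genotype matrix")
  }
  has_dp <- !is.null(geno$depth)
  lens <- chrom_lengths(geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rodscan",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) {
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">"
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  cells <- matrix("./.", nrow = n_samples(geno), ncol = n_variants(geno))
  obs <- !is.na(geno$dosage)
  cells[obs] <- gt_code[geno$dosage[obs] + 1L]
  if (has_dp) {
    dp <- ifelse(is.na(geno$depth), ".", as.character(geno$depth))
    cells <- matrix(paste0(cells, ":", dp), nrow = nrow(cells))
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- paste(geno$chrom, geno$pos, ".", "A", "T", ".", "PASS", ".", fmt,
                apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a population-assignment TSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pop_table <- function(geno, path) {
  write_tsv(data.frame(sample = geno$samples,
                       population = unname(geno$pops[geno$samples])), path)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive coordinates, GFF convention).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff <- function(genes, path) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  lines <- c(
    "##gff-version 3",
    sprintf("%s\trodscan\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
            genes$chrom, as.integer(genes$start), as.integer(genes$end),
            genes$gene_id, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}
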