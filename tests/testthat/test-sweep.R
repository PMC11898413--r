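test_that("ROD obeys its defining identities", {
  expect_equal(rod(3e-3, 3e-3)$rod, 0)
  expect_equal(rod(0, 3e-3)$rod, 1)
  expect_equal(rod(2.4e-3, 3.0e-3)$rod, 0.2, tolerance = 1e-12)
  expect_equal(rod(2.4e-3, 3.0e-3)$signed_rod, 0.2, tolerance = 1e-12)
  # diversity gain scores too, with the sign preserved in signed_rod
  expect_equal(rod(4.5e-3, 3.0e-3)$rod, 0.5, tolerance = 1e-12)
  expect_equal(rod(4.5e-3, 3.0e-3)$signed_rod, -0.5, tolerance = 1e-12)
  # undefined when the reference has no diversity
  expect_true(is.na(rod(1e-3, 0)$rod))
  # scale invariance
  pi_p <- c(1e-3, 2e-3, 3e-3)
  pi_r <- c(3e-3, 3e-3, 2e-3)
  expect_equal(rod(10 * pi_p, 10 * pi_r)$rod, rod(pi_p, pi_r)$rod,
               tolerance = 1e-12)
})

test_that("reference-vs-self ROD is identically zero across all windows", {
  cfg <- simulation_config(seed = 8, n_pops = 2, samples_per_pop = 8,
                           n_chroms = 1, chrom_length = 5e5,
                           missing_rate = 0, depth_model = NULL)
  g <- simulate_cohort(cfg)$geno
  rw <- rod_windows(g, g$ref_pop)
  defined <- !is.na(rw$rod)
  expect_true(any(defined))
  expect_true(all(rw$rod[defined] == 0))
  # low-coverage windows are excluded from ranking
  rw2 <- rod_windows(g, "pop2", min_sites = 1e6)
  expect_true(all(is.na(rw2$rod)))
})

test_that("outlier calling takes the intersection of the two top-5% sets", {
  grid <- data.frame(chrom = "chr1",
                     start = seq(1, by = 1e4, length.out = 100))
  grid$end <- grid$start + 1e5
  grid$n_sites <- 50L
  grid$partial <- FALSE
  set.seed(6)
  fst_win <- grid
  fst_win$fst <- runif(100, 0, 0.01)
  rod_win <- grid
  rod_win$rod <- runif(100, 0, 0.2)
  rod_win$signed_rod <- rod_win$rod
  rod_win$pi_pop <- 1e-3
  rod_win$pi_ref <- 1e-3
  # plant 5 windows sharing the maxima of both statistics
  top <- 11:15
  fst_win$fst[top] <- 0.5
  rod_win$rod[top] <- 0.9
  called <- call_outlier_windows(fst_win, rod_win)
  expect_equal(which(called$outlier), top)
  expect_true(all(which(called$outlier) %in% which(called$fst_outlier)))
  expect_true(sum(called$fst_outlier) <= ceiling(0.05 * 100) + 1)
  # union mode is a superset of the intersection
  called_u <- call_outlier_windows(fst_win, rod_win, mode = "union")
  expect_true(all(called$outlier <= called_u$outlier))
})

test_that("degenerate all-tied statistics return every window with a warning", {
  grid <- data.frame(chrom = "chr1",
                     start = seq(1, by = 1e4, length.out = 30))
  grid$end <- grid$start + 1e5
  grid$n_sites <- 50L
  grid$partial <- FALSE
  fst_win <- grid
  fst_win$fst <- 0.01
  rod_win <- grid
  rod_win$rod <- 0.1
  rod_win$signed_rod <- 0.1
  expect_warning(called <- call_outlier_windows(fst_win, rod_win), "tie")
  expect_true(all(called$outlier))
  # too few ranked windows is flagged (the all-tied warning also fires here)
  expect_warning(
    expect_warning(call_outlier_windows(fst_win[1:5, ], rod_win[1:5, ]),
                   "unstable"),
    "tie")
})

test_that("regions merge across overlaps and gaps per the max_gap rule", {
  w <- data.frame(chrom = "chr1", start = c(1, 10001),
                  end = c(100001, 110001), fst = c(0.2, 0.3),
                  rod = c(0.5, 0.4))
  m <- merge_regions(w)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$end, 110001)
  expect_equal(m$n_windows, 2L)
  expect_equal(m$peak_fst, 0.3)
  expect_equal(m$peak_rod, 0.5)
  # different chromosomes never merge
  w2 <- data.frame(chrom = c("chr1", "chr2"), start = c(1, 1),
                   end = c(100001, 100001), fst = 0.1, rod = 0.1)
  expect_equal(nrow(merge_regions(w2)), 2)
  # 200 kb separation with max_gap = 0 stays split, a large max_gap bridges
  w3 <- data.frame(chrom = "chr1", start = c(1, 300001, 600001),
                   end = c(100001, 400001, 700001), fst = 0.1, rod = 0.1)
  expect_equal(nrow(merge_regions(w3, max_gap = 0)), 3)
  expect_equal(nrow(merge_regions(w3, max_gap = 2e5)), 1)
})

test_that("genes attach iff they overlap a region by at least 1 bp", {
  regions <- data.frame(chrom = "chr1", start = 100000, end = 200000,
                        n_windows = 1L, peak_fst = 0.1, peak_rod = 0.1)
  genes <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(150000, 200000, 50000, 150000),
                      end = c(160000, 210000, 99999, 160000),
                      gene_id = c("inside", "abutting_end", "before",
                                  "wrong_chrom"))
  ann <- annotate_genes(regions, genes)
  expect_equal(ann$gene_ids, "inside")
  # half-open region [1, 100000): a gene starting at 100000 is excluded
  reg2 <- data.frame(chrom = "chr1", start = 1, end = 100000,
                     n_windows = 1L, peak_fst = 0.1, peak_rod = 0.1)
  gene2 <- data.frame(chrom = "chr1", start = 100000, end = 110000,
                      gene_id = "at_boundary")
  expect_equal(annotate_genes(reg2, gene2)$gene_ids, "")
})

test_that("GFF3 gene models round-trip through write_gff and read_gff_genes", {
  genes <- synthetic_genes(c(chr1 = 1e6), n_per_chrom = 5)
  path <- tempfile(fileext = ".gff3")
  write_gff(genes, path)
  back <- read_gff_genes(path)
  expect_equal(back$chrom, genes$chrom)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("an implanted sweep is recovered end-to-end with its marker gene", {
  sw <- data.frame(chrom = "chr1", start = 900001, end = 1100000,
                   pops = "BH", reduction = 0.8)
  cfg <- simulation_config(seed = 101, n_pops = 2, samples_per_pop = 10,
                           n_chroms = 2, chrom_length = 2e6,
                           sweep_intervals = sw, depth_model = NULL,
                           pop_names = c("XM", "BH"), ref_pop = "XM")
  g <- simulate_cohort(cfg)$geno
  genes <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                      start = rep(seq(1e5, 1.7e6, length.out = 5), 2),
                      end = rep(seq(1e5, 1.7e6, length.out = 5), 2) + 2e4,
                      gene_id = paste0("g", 1:10))
  genes$gene_id[3] <- "sweep_gene"  # chr1 gene at 900k-920k, inside the sweep
  sc <- sweep_scan(g, "BH", genes = genes)
  hit <- sc$regions$chrom == "chr1" & sc$regions$start < 1100000 &
    sc$regions$end > 900001
  expect_true(any(hit))
  expect_true(any(grepl("sweep_gene", sc$regions$gene_ids[hit])))
  # scanning the reference against itself is refused
  expect_error(sweep_scan(g, "XM"), "differ from the reference")
})

test_that("sweep regions serialize to 0-based half-open BED", {
  regions <- data.frame(chrom = "chr1", start = 10001, end = 110001,
                        n_windows = 2L, peak_fst = 0.1, peak_rod = 0.2)
  path <- tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  expect_equal(readLines(path), "chr1\t10000\t110000")
})
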