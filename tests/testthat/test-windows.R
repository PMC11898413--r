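test_that("the window grid tiles chromosomes and bounds variant coverage", {
  spec <- window_spec(window_size = 1e5, step = 1e4)
  w <- make_windows(c(chr1 = 1e6, chr2 = 2.5e5), spec)
  expect_true(all(w$end - w$start <= 1e5))
  expect_true(all(diff(w$start[w$chrom == "chr1"]) == 1e4))
  # every position is covered by at most ceiling(window/step) windows
  pos <- c(1, 9999, 10000, 123456, 999999)
  cover <- sapply(pos, function(p) {
    sum(w$chrom == "chr1" & w$start <= p & p < w$end)
  })
  expect_true(all(cover >= 1 & cover <= 10))
  expect_true(any(w$partial))
  expect_error(window_spec(step = 2e5), "step")
})

test_that("windowed pi matches the hand-computed single-site example", {
  # one site, 10 diploids, alt count 10/20:
  # per-site 2*0.5*0.5*(20/19), window pi = that / 1e5
  dos <- matrix(c(rep(2L, 5), rep(0L, 5)), ncol = 1,
                dimnames = list(paste0("s", 1:10), NULL))
  g <- toy_geno(dos, pos = 5000, chrom_len = c(chr1 = 1e5))
  w <- windowed_pi(g, "A", window_spec(1e5, 1e5))
  expect_equal(nrow(w), 1)
  expect_equal(w$n_sites, 1L)
  expect_equal(w$pi, 2 * 0.5 * 0.5 * (20 / 19) / 1e5, tolerance = 1e-12)
  # a window with no variants has pi = 0
  g2 <- toy_geno(dos, pos = 5000, chrom_len = c(chr1 = 3e5))
  w2 <- windowed_pi(g2, "A", window_spec(1e5, 1e5))
  expect_equal(w2$pi[w2$start == 200001], 0)
  expect_equal(w2$n_sites[w2$start == 200001], 0L)
})

test_that("windowed pi equals the brute-force pair-counting oracle", {
  for (seed in 1:5) {
    g <- random_fixture(seed, n_per_pop = 5, n_sites = 30, missing = 0.15)
    spec <- window_spec(4e4, 2e4)
    w <- windowed_pi(g, "P1", spec)
    rows <- which(g$pops == "P1")
    for (k in seq_len(nrow(w))) {
      expect_equal(
        w$pi[k],
        oracle_window_pi(g$dosage[rows, , drop = FALSE], g$pos,
                         w$start[k], w$end[k]),
        tolerance = 1e-10)
    }
  }
})

test_that("pi is invariant to sample order and allele label swap", {
  g <- random_fixture(3, n_per_pop = 6, n_sites = 20, missing = 0.1,
                      n_pops = 1)
  w <- windowed_pi(g, "P1")
  # permute samples
  perm <- sample(g$samples)
  gp <- subset_geno(g, samples = perm)
  expect_equal(windowed_pi(gp, "P1")$pi, w$pi, tolerance = 1e-14)
  # swap REF/ALT labels: dosage -> 2 - dosage
  swapped <- 2L - g$dosage
  gs <- toy_geno(swapped, pops = g$pops, pos = g$pos,
                 chrom_len = c(chr1 = 1e5))
  expect_equal(windowed_pi(gs, "P1")$pi, w$pi, tolerance = 1e-14)
})

test_that("Weir-Cockerham Fst matches the site-by-site oracle", {
  for (seed in 1:5) {
    g <- random_fixture(seed + 10, n_per_pop = 3, n_sites = 20,
                        missing = 0.1)
    rows1 <- which(g$pops == "P1")
    rows2 <- which(g$pops == "P2")
    expect_equal(global_fst(g, "P1", "P2"),
                 oracle_fst(g$dosage[rows1, , drop = FALSE],
                            g$dosage[rows2, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("Fst is symmetric, bounded and correct in degenerate cases", {
  g <- random_fixture(99, n_per_pop = 6, n_sites = 25, missing = 0.05)
  expect_identical(global_fst(g, "P1", "P2"), global_fst(g, "P2", "P1"))
  # identical genotype vectors in both populations -> estimate <= 0
  set.seed(4)
  block <- matrix(rbinom(8 * 15, 2, 0.3), 8, 15)
  dos <- rbind(block, block)
  rownames(dos) <- paste0("s", 1:16)
  pops <- setNames(rep(c("P1", "P2"), each = 8), rownames(dos))
  gid <- toy_geno(dos, pops = pops)
  expect_lte(global_fst(gid, "P1", "P2"), 0)
  # fixed REF vs fixed ALT -> estimate = 1
  dosf <- rbind(matrix(0L, 6, 10), matrix(2L, 6, 10))
  rownames(dosf) <- paste0("s", 1:12)
  popsf <- setNames(rep(c("P1", "P2"), each = 6), rownames(dosf))
  gf <- toy_geno(dosf, pops = popsf)
  expect_equal(global_fst(gf, "P1", "P2"), 1, tolerance = 1e-12)
})

test_that("increasing between-population divergence never lowers the estimate", {
  # pop1 fixed at p = 0.5 (homozygote mixture), pop2 swept from p = 0.5 to 1
  n <- 10
  base1 <- c(rep(2L, n / 2), rep(0L, n / 2))
  ests <- sapply(5:10, function(k) {
    dos <- rbind(matrix(base1, n, 2),
                 matrix(c(rep(2L, k), rep(0L, n - k)), n, 2))
    rownames(dos) <- paste0("s", 1:(2 * n))
    pops <- setNames(rep(c("P1", "P2"), each = n), rownames(dos))
    global_fst(toy_geno(dos, pops = pops), "P1", "P2")
  })
  expect_true(all(diff(ests) >= -1e-12))
})

test_that("windowed Fst aggregates by ratio of sums over the window grid", {
  g <- random_fixture(21, n_per_pop = 5, n_sites = 30, missing = 0.1)
  spec <- window_spec(5e4, 5e4)
  w <- windowed_fst(g, "P1", "P2", spec)
  rows1 <- which(g$pops == "P1")
  rows2 <- which(g$pops == "P2")
  for (k in which(w$n_sites > 0)) {
    idx <- which(g$pos >= w$start[k] & g$pos < w$end[k])
    expect_equal(w$fst[k],
                 oracle_fst(g$dosage[rows1, idx, drop = FALSE],
                            g$dosage[rows2, idx, drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("Tajima's D matches the longhand-constants oracle", {
  set.seed(31)
  for (rep_i in 1:5) {
    dos <- matrix(rbinom(5 * 12, 2, runif(12, 0.1, 0.9)[col(matrix(0, 5, 12))]),
                  5, 12, dimnames = list(paste0("s", 1:5), NULL))
    g <- toy_geno(dos, pos = sort(sample.int(9e4, 12)),
                  chrom_len = c(chr1 = 1e5))
    w <- windowed_tajima_d(g, "A", window_spec(1e5, 1e5))
    expect_equal(w$tajima_d, oracle_tajima_d(dos), tolerance = 1e-10)
  }
  # S = 0 gives the undefined sentinel
  dos0 <- matrix(0L, 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  dos0[, 1] <- 2L
  g0 <- toy_geno(dos0, chrom_len = c(chr1 = 1e5))
  expect_true(is.na(windowed_tajima_d(g0, "A",
                                      window_spec(1e5, 1e5))$tajima_d))
  # fewer than 4 allele copies is a labelled error
  dos1 <- matrix(c(0L, 1L, 2L), 1, 3, dimnames = list("s1", NULL))
  expect_error(windowed_tajima_d(toy_geno(dos1), "A"), "4 allele copies")
})

test_that("Tajima's D is centered near 0 under the neutral site-frequency spectrum", {
  set.seed(41)
  d <- replicate(300, {
    dos <- neutral_sfs_window(n_dip = 10, S = 40)
    rownames(dos) <- paste0("s", 1:10)
    g <- toy_geno(dos, chrom_len = c(chr1 = 1e5))
    windowed_tajima_d(g, "A", window_spec(1e5, 1e5))$tajima_d
  })
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se + 0.05)
})
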