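#' Identity-by-state distance matrix between samples
#'
#' `d(i, j)` is the mean, over sites where both samples are genotyped, of
#' `|dosage_i - dosage_j| / 2`; it lies in \[0, 1\], with 0 for identical
#' genotypes and 1 for opposite homozygotes at every shared site.
#'
#' @param geno a [genotype_matrix()].
#' @return symmetric numeric matrix with sample ids as dimnames and zero
#'   diagonal.
#' @export
ibs_distance <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  out <- matrix(0, n, n, dimnames = list(geno$samples, geno$samples))
  for (i in seq_len(n - 1)) {
    di <- d[i, ]
    for (j in seq(i + 1, n)) {
      shared <- !is.na(di) & !is.na(d[j, ])
      if (!any(shared)) {
        stop("samples ", geno$samples[i], " and ", geno$samples[j],
             " share no co-genotyped sites")
      }
      out[i, j] <- out[j, i] <- mean(abs(di[shared] - d[j, shared])) / 2
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair minimizing the
#' Q-criterion `(n-2)*d(i,j) - r_i - r_j`, assign branch lengths by the
#' standard formulas, and reduce the matrix; the last three nodes are joined
#' at an unrooted trifurcating root. Exact Q-ties are broken by the lowest
#' (row, column) index pair. Negative branch lengths are clamped to 0 (the
#' PHYLIP convention) with a message reporting the pre-clamp value.
#'
#' @param d symmetric distance matrix with labels as dimnames (3 or more
#'   taxa), e.g. from [ibs_distance()].
#' @return an [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  frag <- rownames(d)

  fmt <- function(x) sprintf("%.12g", x)
  clamp_len <- function(x) {
    if (x < 0) {
      message("nj_tree: negative branch length ", signif(x, 6),
              " clamped to 0")
      0
    } else {
      x
    }
  }

  while (n > 3) {
    r <- rowSums(d)
    qm <- (n - 2) * d - outer(r, r, "+")
    diag(qm) <- Inf
    m <- min(qm)
    cand <- which(qm == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- clamp_len(li)
    lj <- clamp_len(lj)
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- frag
    d <- d2
    n <- n - 1
  }
  l1 <- clamp_len((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp_len((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp_len((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                   ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = newick)
}
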