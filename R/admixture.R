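#' Fit the K-ancestral-population admixture model by EM
#'
#' The standard admixture likelihood: each dosage `g_il` is
#' Binomial(2, x_il) with `x_il = sum_k q_ik p_kl`, where `Q` holds per-
#' individual ancestry proportions and `P` per-source alt-allele
#' frequencies. Maximized by plain EM from random Dirichlet (Q) / Uniform
#' (P) starts; the best of `n_restarts` runs by log-likelihood is returned.
#' Missing genotypes are dropped from the likelihood. `K = 1` has its EM
#' fixed point at the pooled allele frequencies, reached after one
#' iteration. The log-likelihood is non-decreasing over iterations; `P` is
#' kept in `[eps, 1 - eps]`.
#'
#' @param x a [genotype_matrix()] or a samples x variants dosage matrix.
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random starts (default 1).
#' @param max_iter maximum EM iterations (default 2000).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param eps bound keeping `P` away from 0 and 1 (default 1e-6).
#' @return object of class `admixture_fit`: `K`, `Q`, `P`, `loglik`,
#'   `n_iter`, `converged`, `n_restarts`, `cv_error` (`NA` here; see
#'   [cv_error()]).
#' @export
admixture_fit <- function(x, K, seed = 1L, n_restarts = 1L,
                          max_iter = 2000L, tol = 1e-8, eps = 1e-6) {
  G <- as_dosage(x)
  if (K < 1) stop("K must be >= 1")
  if (nrow(G) == 0 || ncol(G) == 0) stop("empty genotype matrix")
  best <- NULL
  for (rep_i in seq_len(max(1L, n_restarts))) {
    fit <- with_seed(derive_seed(seed, rep_i),
                     admixture_em(G, K, max_iter, tol, eps))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (K == 1) break  # closed-form fixed point; restarts are redundant
  }
  best$n_restarts <- if (K == 1) 1L else max(1L, n_restarts)
  best$samples <- rownames(G)
  if (!is.null(rownames(G))) rownames(best$Q) <- rownames(G)
  class(best) <- "admixture_fit"
  best
}

admixture_em <- function(G, K, max_iter, tol, eps) {
  I <- nrow(G)
  L <- ncol(G)
  miss <- is.na(G)
  G0 <- G
  G0[miss] <- 0L
  G2 <- 2L - G
  G2[miss] <- 0L
  storage.mode(G0) <- "double"
  storage.mode(G2) <- "double"
  Li <- rowSums(!miss)
  if (any(Li == 0)) stop("sample(s) with no observed genotypes")
  Q <- rdirichlet(I, rep(1, K))
  P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  if (K == 1) {
    Q <- matrix(1, I, 1)
    P <- matrix(clamp(colMeans(G, na.rm = TRUE) / 2, eps, 1 - eps), 1, L)
  }
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  trace <- numeric()
  repeat {
    X <- Q %*% P
    ll <- sum(G0 * log(X)) + sum(G2 * log1p(-X))
    trace[iter + 1L] <- ll
    if (ll < ll_prev - 1e-8 * abs(ll_prev) - 1e-10) {
      warning("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
    }
    if (iter > 0 && (ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    U <- G0 / X
    V <- G2 / (1 - X)
    tu <- crossprod(Q, U)      # K x L
    tv <- crossprod(Q, V)
    num_alt <- P * tu
    num_ref <- (1 - P) * tv
    Qn <- Q * (U %*% t(P) + V %*% t(1 - P)) / (2 * Li)
    Qn <- Qn / rowSums(Qn)
    P <- clamp(num_alt / (num_alt + num_ref), eps, 1 - eps)
    Q <- Qn
    ll_prev <- ll
    iter <- iter + 1L
  }
  list(K = as.integer(K), Q = Q, P = P, loglik = ll, n_iter = iter,
       converged = converged, loglik_trace = trace, cv_error = NA_real_)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, " loglik =", format(x$loglik),
      " iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Closed-form log-likelihood of the K = 1 admixture model
#'
#' With a single ancestral population the model collapses to independent
#' binomials at the pooled allele frequencies; used to validate the EM path.
#'
#' @inheritParams admixture_fit
#' @return the log-likelihood value.
#' @export
admixture_loglik_k1 <- function(x, eps = 1e-6) {
  G <- as_dosage(x)
  p <- clamp(colMeans(G, na.rm = TRUE) / 2, eps, 1 - eps)
  ll <- sweep(G, 2, log(p), "*") + sweep(2 - G, 2, log1p(-p), "*")
  sum(ll, na.rm = TRUE)
}

#' Cross-validation error of the admixture model for one K
#'
#' Masks a random fold of the non-missing genotype entries, fits the model
#' on the remainder, predicts the masked dosages as `2 * Q %*% P`, and
#' reports the root-mean-squared deviation over masked entries, averaged
#' across folds (ADMIXTURE-style entry masking).
#'
#' @inheritParams admixture_fit
#' @param folds number of folds (>= 2, default 5).
#' @param max_iter,tol EM settings for the fold fits.
#' @return the CV error (a single number).
#' @export
cv_error <- function(x, K, folds = 5L, seed = 1L, n_restarts = 1L,
                     max_iter = 500L, tol = 1e-6) {
  G <- as_dosage(x)
  if (folds < 2) stop("folds must be >= 2")
  obs <- which(!is.na(G))
  if (length(obs) < folds) stop("not enough observed genotypes to fold")
  fold_of <- with_seed(derive_seed(seed, 999), {
    sample(rep_len(seq_len(folds), length(obs)))
  })
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    idx <- obs[fold_of == f]
    if (length(idx) == 0) stop("fold ", f, " has no masked entries")
    Gm <- G
    Gm[idx] <- NA_integer_
    fit <- admixture_fit(Gm, K, seed = derive_seed(seed, f),
                         n_restarts = n_restarts, max_iter = max_iter,
                         tol = tol)
    pred <- 2 * fit$Q %*% fit$P
    errs[f] <- sqrt(mean((pred[idx] - G[idx])^2))
  }
  mean(errs)
}

#' Scan K with repeated cross-validation
#'
#' Repeats [cv_error()] for every K in `K_range` with `repeats` distinct
#' seeds and reports the minimum (and mean) CV error per K — the protocol of
#' repeating each K and keeping the best run.
#'
#' @inheritParams cv_error
#' @param K_range integer vector of K values (default 1:6).
#' @param repeats repetitions per K (default 20).
#' @return data.frame with columns `K`, `cv_min`, `cv_mean`.
#' @export
scan_K <- function(x, K_range = 1:6, repeats = 20L, folds = 5L, seed = 1L,
                   n_restarts = 1L, max_iter = 500L, tol = 1e-6) {
  G <- as_dosage(x)
  rows <- lapply(K_range, function(K) {
    cvs <- vapply(seq_len(repeats), function(r) {
      cv_error(G, K, folds = folds, seed = derive_seed(seed, K * 1000 + r),
               n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    }, numeric(1))
    data.frame(K = K, cv_min = min(cvs), cv_mean = mean(cvs))
  })
  do.call(rbind, rows)
}

#' Align mixture labels of an estimated Q to a reference Q
#'
#' Admixture components are identifiable only up to label permutation;
#' this picks the column permutation of `Q` minimizing the mean absolute
#' error against `Q_ref` (exhaustive over K! permutations, K small).
#'
#' @param Q estimated ancestry matrix (samples x K).
#' @param Q_ref reference ancestry matrix of the same shape.
#' @return `Q` with permuted columns.
#' @export
align_Q <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  perms <- all_permutations(K)
  maes <- vapply(perms, function(p) mean(abs(Q[, p, drop = FALSE] - Q_ref)),
                 numeric(1))
  Q[, perms[[which.min(maes)]], drop = FALSE]
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}
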