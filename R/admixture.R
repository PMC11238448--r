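# Shared EM engine for the binomial admixture likelihood
#   loglik = sum_ij w_ij [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ],
#   p = Q F',  Q rows on the simplex, F in [eps, 1 - eps].
# FRAPPE-style multiplicative updates; monotone in the log-likelihood.
.admix_em <- function(G, W, Q, F, update_F, eps, tol, max_iter) {
  G[is.na(G)] <- 0
  G <- G * W
  G2 <- (2 - G) * W          # NB: (2 - g) masked; G already masked
  G2[W == 0] <- 0
  two_m <- 2 * rowSums(W)
  ll <- function(P) sum(G * log(P) + G2 * log1p(-P))
  P <- Q %*% t(F)
  trace <- numeric(0)
  cur <- ll(P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    R1 <- G / P
    R0 <- G2 / (1 - P)
    if (update_F) {
      N1 <- crossprod(R1, Q) * F          # m x K
      N0 <- crossprod(R0, Q) * (1 - F)
      F <- N1 / (N1 + N0)
      F[!is.finite(F)] <- 0.5
      F <- pmin(pmax(F, eps), 1 - eps)
    }
    Q <- Q * (R1 %*% F + R0 %*% (1 - F)) / two_m
    Q <- Q / rowSums(Q)
    P <- Q %*% t(F)
    new <- ll(P)
    trace <- c(trace, new)
    if (is.finite(new) && new - cur < tol && it > 1) { converged <- TRUE; cur <- new; break }
    cur <- new
  }
  list(Q = Q, F = F, loglik = cur, trace = trace, converged = converged,
       iterations = length(trace))
}

.new_admix_fit <- function(Q, F, loglik, mode, K, extra = list()) {
  structure(c(list(Q = Q, F = F, loglik = loglik, mode = mode, K = K), extra),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admixture fit (%s, K = %d): %d individuals, %d SNPs\n",
              x$mode, x$K, nrow(x$Q), nrow(x$F)))
  cat(sprintf("log-likelihood %.2f (%s after %d iterations)\n", x$loglik,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$iterations %||% NA_integer_))
  cat("mean ancestry: ", paste(sprintf("%s %.3f", colnames(x$Q), colMeans(x$Q)),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Supervised admixture estimation
#'
#' Fixes the ancestral allele frequencies to the observed frequencies of
#' labelled reference panels (clamped to `[eps, 1 - eps]`) and, for each
#' target individual, maximises the independent-SNP binomial
#' log-likelihood over the ancestry simplex by EM.
#'
#' @param dataset A [geno_dataset()].
#' @param reference_labels Population labels defining the K ancestral
#'   panels (each needs >= 2 reference individuals).
#' @param target_ids Ids of the individuals whose ancestry is estimated;
#'   must be disjoint from the reference individuals.
#' @param eps Frequency clamp keeping the likelihood finite (1e-6).
#' @param tol Convergence tolerance in log-likelihood units (1e-4).
#' @param max_iter Maximum EM iterations (2000); non-convergence
#'   produces a warning with the last iterate.
#' @return An `admix_fit` with `Q` (targets x K), `F`, `loglik`, and the
#'   per-run log-likelihood `trace`.
#' @export
admix_supervised <- function(dataset, reference_labels, target_ids,
                             eps = 1e-6, tol = 1e-4, max_iter = 2000) {
  stopifnot(inherits(dataset, "geno_dataset"))
  pops <- sort(unique(reference_labels))
  ref_rows <- which(dataset$populations %in% pops)
  if (any(dataset$ids[ref_rows] %in% target_ids)) {
    stop("target_ids must be disjoint from the reference individuals")
  }
  ti <- match(target_ids, dataset$ids)
  if (anyNA(ti)) stop("unknown target ids: ",
                      paste(target_ids[is.na(ti)], collapse = ", "))
  K <- length(pops)
  m <- nrow(dataset$map)
  F <- matrix(NA_real_, m, K, dimnames = list(dataset$map$id, pops))
  for (k in seq_len(K)) {
    rows <- which(dataset$populations == pops[k])
    if (length(rows) < 2) stop("reference population '", pops[k],
                               "' has fewer than 2 individuals")
    gk <- dataset$genotypes[rows, , drop = FALSE]
    pk <- colSums(gk, na.rm = TRUE) / (2 * colSums(!is.na(gk)))
    if (all(pk %in% c(0, 1) | is.na(pk))) {
      stop("reference population '", pops[k], "' is monomorphic at every SNP")
    }
    pk[is.na(pk)] <- 0.5
    F[, k] <- pmin(pmax(pk, eps), 1 - eps)
  }
  G <- dataset$genotypes[ti, , drop = FALSE]
  W <- (!is.na(G)) * 1
  if (K == 1) {
    Q <- matrix(1, length(ti), 1, dimnames = list(target_ids, pops))
    G0 <- G; G0[is.na(G0)] <- 0
    ll <- sum(W * (G0 * log(F[, 1])[col(G0)] +
                   (2 - G0) * log(1 - F[, 1])[col(G0)]))
    return(.new_admix_fit(Q, F, ll, "supervised", 1L,
                          list(converged = TRUE, iterations = 0L)))
  }
  Q0 <- matrix(1 / K, length(ti), K)
  fit <- .admix_em(G, W, Q0, F, update_F = FALSE, eps = eps,
                   tol = tol, max_iter = max_iter)
  if (!fit$converged) warning("supervised EM did not converge in ",
                              max_iter, " iterations; returning last iterate")
  dimnames(fit$Q) <- list(target_ids, pops)
  .new_admix_fit(fit$Q, F, fit$loglik, "supervised", K,
                 list(converged = fit$converged, iterations = fit$iterations,
                      trace = fit$trace))
}

#' Unsupervised admixture estimation
#'
#' Joint EM estimation of ancestry fractions Q and ancestral allele
#' frequencies F from a seeded random start; the log-likelihood is
#' monotone non-decreasing over iterations and the best of `n_restarts`
#' runs is returned.  Cluster labels are arbitrary; use
#' [align_q_columns()] to match runs.
#'
#' @param dataset A [geno_dataset()].
#' @param K Number of ancestral clusters (1 <= K <= n).
#' @param seed Integer seed.
#' @param tol,max_iter,eps As in [admix_supervised()].
#' @param n_restarts Independent restarts (default 3).
#' @return An `admix_fit` with the per-iteration log-likelihood `trace`
#'   of the winning run.
#' @export
admix_unsupervised <- function(dataset, K, seed = 1L, tol = 1e-4,
                               max_iter = 2000, eps = 1e-6, n_restarts = 3) {
  stopifnot(inherits(dataset, "geno_dataset"))
  n <- length(dataset$ids)
  if (K < 1 || K > n) stop("K must be between 1 and the number of individuals")
  G <- dataset$genotypes
  W <- (!is.na(G)) * 1
  fit <- .admix_unsupervised_masked(G, W, K, seed, tol, max_iter, eps, n_restarts)
  dimnames(fit$Q) <- list(dataset$ids, paste0("cluster", seq_len(K)))
  dimnames(fit$F) <- list(dataset$map$id, paste0("cluster", seq_len(K)))
  .new_admix_fit(fit$Q, fit$F, fit$loglik, "unsupervised", as.integer(K),
                 list(converged = fit$converged, iterations = fit$iterations,
                      trace = fit$trace))
}

# Core unsupervised fit on an explicit observation-weight matrix W
# (0 = missing or masked); shared with the cross-validation routine.
.admix_unsupervised_masked <- function(G, W, K, seed, tol, max_iter, eps,
                                       n_restarts) {
  n <- nrow(G); m <- ncol(G)
  if (K == 1) {
    G0 <- G; G0[is.na(G0)] <- 0
    p <- colSums(G0 * W) / pmax(2 * colSums(W), 1)
    F <- matrix(pmin(pmax(p, eps), 1 - eps), m, 1)
    Q <- matrix(1, n, 1)
    ll <- sum(W * (G0 * log(F[, 1])[col(G0)] +
                   (2 - G0) * log(1 - F[, 1])[col(G0)]))
    return(list(Q = Q, F = F, loglik = ll, converged = TRUE, iterations = 0L,
                trace = numeric(0)))
  }
  set.seed(seed)
  G0 <- G; G0[is.na(G0)] <- 0
  p_obs <- colSums(G0 * W) / pmax(2 * colSums(W), 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    Q0 <- matrix(stats::rgamma(n * K, 1), n, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(p_obs, m, K) + matrix(stats::runif(m * K, -0.1, 0.1), m, K)
    F0 <- pmin(pmax(F0, eps), 1 - eps)
    fit <- .admix_em(G, W, Q0, F0, update_F = TRUE, eps = eps,
                     tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Align the columns of one ancestry matrix to another
#'
#' Greedy best-permutation matching on column correlations, for
#' comparing runs or matching estimates to truth despite label
#' switching.
#'
#' @param Q Ancestry matrix to permute.
#' @param Q_ref Reference matrix with the same dimensions.
#' @return `Q` with columns permuted to best match `Q_ref`.
#' @export
align_q_columns <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K)
  cc <- suppressWarnings(stats::cor(Q_ref, Q))
  cc[!is.finite(cc)] <- -1
  perm <- integer(K)
  avail <- seq_len(K)
  for (k in order(apply(cc, 1, max), decreasing = TRUE)) {
    j <- avail[which.max(cc[k, avail])]
    perm[k] <- j
    avail <- setdiff(avail, j)
  }
  out <- Q[, perm, drop = FALSE]
  colnames(out) <- colnames(Q_ref)
  out
}

#' Masking-based cross-validation error for choosing K
#'
#' Partitions the observed genotype entries into `n_folds` random
#' disjoint masks; each fold is hidden in turn, the unsupervised model
#' is fitted on the remaining entries, and the hidden entries are
#' scored by their mean binomial deviance under the fitted dosage
#' expectation 2 Q F'.
#'
#' @param dataset A [geno_dataset()].
#' @param K Number of clusters.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param ... Passed to the unsupervised fitter (`tol`, `max_iter`,
#'   `eps`, `n_restarts`).
#' @return List with `mean` and `sd` of the per-fold masked deviance
#'   and the per-fold values `folds`.
#' @export
admix_cv_error <- function(dataset, K, n_folds = 5, seed = 1L, ...) {
  stopifnot(inherits(dataset, "geno_dataset"))
  G <- dataset$genotypes
  obs <- which(!is.na(G))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), length(obs)))
  args <- list(...)
  tol <- args$tol %||% 1e-4; max_iter <- args$max_iter %||% 2000
  eps <- args$eps %||% 1e-6; n_restarts <- args$n_restarts %||% 1
  dev_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    W <- (!is.na(G)) * 1
    masked <- obs[fold_of == f]
    W[masked] <- 0
    fit <- .admix_unsupervised_masked(G, W, K, seed + f, tol, max_iter, eps,
                                      n_restarts)
    P <- pmin(pmax(fit$Q %*% t(fit$F), 1e-9), 1 - 1e-9)
    g <- G[masked]; p <- P[masked]
    t1 <- ifelse(g > 0, g * log(g / (2 * p)), 0)
    t0 <- ifelse(g < 2, (2 - g) * log((2 - g) / (2 * (1 - p))), 0)
    dev_fold[f] <- 2 * mean(t1 + t0)
  }
  list(mean = mean(dev_fold), sd = stats::sd(dev_fold), folds = dev_fold)
}

#' Genomic admixture percentage relative to a reference population
#'
#' A_GEN = 100 x (1 - q_reference): the percentage of an individual's
#' ancestry not assigned to the home/reference population of a
#' supervised fit.
#'
#' @param fit A supervised `admix_fit`.
#' @param reference_population Column name of the reference ancestry.
#' @return Named numeric vector of A_GEN percentages in `[0, 100]`.
#' @export
agen <- function(fit, reference_population) {
  stopifnot(inherits(fit, "admix_fit"))
  if (!reference_population %in% colnames(fit$Q)) {
    stop("unknown reference population '", reference_population, "'; fit has: ",
         paste(colnames(fit$Q), collapse = ", "))
  }
  100 * (1 - fit$Q[, reference_population])
}
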