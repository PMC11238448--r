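#' Identity-by-state relationship matrix
#'
#' Entry (i, j) is the mean per-SNP IBS score over markers where both
#' individuals have non-missing calls: identical genotypes score 1, one
#' shared allele 0.5, opposite homozygotes 0.  Computed with indicator
#' cross-products, so missing data are handled pairwise-complete.
#'
#' @param dataset A [geno_dataset()].
#' @return Symmetric n x n matrix of similarities in `[0, 1]`, ids as
#'   dimnames.
#' @export
ibs_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "geno_dataset"))
  g <- dataset$genotypes
  M <- (!is.na(g)) * 1
  A0 <- (!is.na(g) & g == 0L) * 1
  A2 <- (!is.na(g) & g == 2L) * 1
  shared <- tcrossprod(M)
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("no shared non-missing markers for pair(s): ",
         paste(apply(bad, 1, function(r)
           paste(dataset$ids[r], collapse = "/")), collapse = ", "))
  }
  A1 <- M - A0 - A2
  # sum over shared markers of |g_i - g_j|
  absdiff <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
             tcrossprod(A1, A2) + tcrossprod(A2, A1) +
             2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  G <- 1 - absdiff / (2 * shared)
  dimnames(G) <- list(dataset$ids, dataset$ids)
  G
}

#' Genetic distance matrix from IBS similarities
#'
#' @param G Relationship matrix from [ibs_matrix()].
#' @return D = 1 - G elementwise, diagonal forced to 0.
#' @export
distance_matrix <- function(G) {
  D <- 1 - G
  diag(D) <- 0
  D
}

#' PCA of a relationship matrix
#'
#' Double-centers the similarity matrix and eigendecomposes it.
#' Components are ordered by decreasing eigenvalue; each eigenvector is
#' sign-fixed so its largest-magnitude loading is positive; the variance
#' fraction divides by the sum of positive eigenvalues.
#'
#' @param G Symmetric relationship matrix.
#' @param center Double-center before decomposition (default `TRUE`).
#' @return Object of class `grm_pca`: `eigenvalues`, `vectors`
#'   (orthonormal columns), `variance_fraction`, `scores` (vectors
#'   scaled by sqrt of positive eigenvalues).
#' @export
pca_grm <- function(G, center = TRUE) {
  if (any(!is.finite(G))) stop("relationship matrix has non-finite entries")
  if (max(abs(G - t(G))) > 1e-8) stop("relationship matrix must be symmetric")
  n <- nrow(G)
  C <- if (center) {
    J <- diag(n) - matrix(1 / n, n, n)
    J %*% G %*% J
  } else G
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  pos <- pmax(e$values, 0)
  vf <- if (sum(pos) > 0) pos / sum(pos) else pos
  scores <- vec %*% diag(sqrt(pos), n, n)
  rownames(vec) <- rownames(scores) <- rownames(G)
  colnames(vec) <- colnames(scores) <- paste0("PC", seq_len(n))
  structure(list(eigenvalues = e$values, vectors = vec,
                 variance_fraction = vf, scores = scores),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("PCA of relationship matrix\n")
  cat(sprintf("  PC%d: eigenvalue %.4g (%.1f%% of variance)\n",
              seq_len(k), x$eigenvalues[seq_len(k)],
              100 * x$variance_fraction[seq_len(k)]), sep = "")
  invisible(x)
}

# Weir-Cockerham (1984) variance components for one pair of populations,
# returned as per-SNP numerator (a) and denominator (a + b + c).
.wc_components <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  ok <- n1 > 0 & n2 > 0
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a[ok], d = (a + b + c_)[ok])
}

# Hudson estimator (Bhatia et al. 2013 formulation) per-SNP components.
.hudson_components <- function(g1, g2) {
  n1 <- 2 * colSums(!is.na(g1)); n2 <- 2 * colSums(!is.na(g2))
  ok <- n1 > 1 & n2 > 1
  p1 <- colSums(g1, na.rm = TRUE) / n1
  p2 <- colSums(g2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(a = num[ok], d = den[ok])
}

#' Pairwise F_ST between populations
#'
#' Estimates F_ST for every pair of population labels as a
#' ratio-of-sums across SNPs of per-SNP variance components.  The
#' default estimator is Weir-Cockerham (1984), the method behind the
#' "Wright's F_ST" option of PLINK 1.9; a Hudson-type estimator is
#' available as an alternative.  Negative per-SNP components are kept in
#' the sums; the final estimate is floored at 0.
#'
#' @param dataset A [geno_dataset()].
#' @param labels Population labels; default the dataset's labels.
#' @param method "wc" (default) or "hudson".
#' @return Symmetric matrix of F_ST estimates with zero diagonal.
#' @export
pairwise_fst <- function(dataset, labels = NULL, method = c("wc", "hudson")) {
  stopifnot(inherits(dataset, "geno_dataset"))
  method <- match.arg(method)
  if (is.null(labels)) labels <- dataset$populations
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least two populations")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("populations need >= 2 individuals: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  comp <- switch(method, wc = .wc_components, hudson = .hudson_components)
  K <- length(pops)
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) {
    gi <- dataset$genotypes[labels == pops[i], , drop = FALSE]
    for (j in (i + 1):K) {
      gj <- dataset$genotypes[labels == pops[j], , drop = FALSE]
      if (all(colSums(!is.na(gi)) == 0) || all(colSums(!is.na(gj)) == 0)) {
        stop("population with all-missing genotypes")
      }
      cc <- comp(gi, gj)
      fin <- is.finite(cc$a) & is.finite(cc$d)
      est <- sum(cc$a[fin]) / sum(cc$d[fin])
      out[i, j] <- out[j, i] <- max(0, est)
    }
  }
  out
}

#' Export a distance matrix as a NEXUS file
#'
#' Writes TAXA and DISTANCES blocks (lower-triangular, with diagonal)
#' readable by SplitsTree-class network software.  Labels containing
#' whitespace or quotes are quoted per NEXUS rules.
#'
#' @param D Symmetric matrix with labels as dimnames (e.g. an F_ST
#'   matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_nexus_distances <- function(D, path) {
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("taxon", seq_len(nrow(D)))
  quote_label <- function(x) {
    ifelse(grepl("[][ \t()\"']", x),
           paste0("'", gsub("'", "''", x), "'"), x)
  }
  ql <- quote_label(labels)
  n <- nrow(D)
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("  DIMENSIONS NTAX=%d;", n),
             "  TAXLABELS",
             paste0("    ", ql),
             "  ;",
             "END;", "",
             "BEGIN DISTANCES;",
             sprintf("  DIMENSIONS NTAX=%d;", n),
             "  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;",
             "  MATRIX")
  for (i in seq_len(n)) {
    lines <- c(lines, paste0("    ", ql[i], " ",
                             paste(format(D[i, seq_len(i)], digits = 10),
                                   collapse = " ")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
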