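#' Horn's parallel analysis for a relationship matrix
#'
#' Determines how many leading principal components of the (double-
#' centered) relationship matrix exceed chance expectation.  In
#' "genotype" mode each null replicate permutes every marker's genotype
#' column independently (preserving the allele-frequency spectrum while
#' destroying individual-level structure), recomputes the IBS matrix
#' and its eigenvalues; in "matrix" mode the off-diagonal entries of G
#' are permuted into a random symmetric matrix instead (fast fallback
#' when genotypes are unavailable).  The number of significant PCs is
#' the count of leading observed eigenvalues exceeding the (1 - P)
#' null quantile of the same rank, stopping at the first failure.
#'
#' @param G Symmetric relationship matrix.
#' @param dataset Optional [geno_dataset()]; required for mode
#'   "genotype".
#' @param P Significance level (default 0.01).
#' @param iterations Monte-Carlo replicates (default 1000; < 100 raises
#'   a warning because the quantile is unstable).
#' @param seed Integer seed.
#' @param mode "genotype" (default when `dataset` given) or "matrix".
#' @param center Double-center before the eigendecomposition (default
#'   `TRUE`).
#' @return Object of class `parallel_analysis`: `k_significant`,
#'   `observed_eigenvalues`, `null_quantiles`, `P`, `iterations`,
#'   `seed`.
#' @export
parallel_analysis <- function(G, dataset = NULL, P = 0.01, iterations = 1000,
                              seed = 1L, mode = c("genotype", "matrix"),
                              center = TRUE) {
  mode <- if (missing(mode) && is.null(dataset)) "matrix" else match.arg(mode)
  if (mode == "genotype" && is.null(dataset)) {
    stop("mode 'genotype' needs the genotype dataset")
  }
  if (iterations < 100) warning("fewer than 100 iterations: null quantiles unstable")
  if (max(abs(G - t(G))) > 1e-8) stop("G must be symmetric")
  n <- nrow(G)
  eig <- function(M) {
    if (center) {
      J <- diag(n) - matrix(1 / n, n, n)
      M <- J %*% M %*% J
    }
    eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  observed <- eig(G)
  set.seed(seed)
  null_eig <- matrix(0, iterations, n)
  if (mode == "genotype") {
    g <- dataset$genotypes
    for (it in seq_len(iterations)) {
      gp <- apply(g, 2, sample)
      ds <- dataset
      ds$genotypes <- gp
      null_eig[it, ] <- eig(ibs_matrix(ds))
    }
  } else {
    off <- G[upper.tri(G)]
    dg <- diag(G)
    for (it in seq_len(iterations)) {
      Gn <- matrix(0, n, n)
      Gn[upper.tri(Gn)] <- sample(off)
      Gn <- Gn + t(Gn)
      diag(Gn) <- dg
      null_eig[it, ] <- eig(Gn)
    }
  }
  qs <- apply(null_eig, 2, stats::quantile, probs = 1 - P, names = FALSE)
  exceed <- observed > qs
  k <- if (exceed[1]) {
    r <- rle(exceed)
    r$lengths[1]
  } else 0L
  structure(list(k_significant = as.integer(k),
                 observed_eigenvalues = observed,
                 null_quantiles = qs, P = P,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), mode = mode),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("Horn's parallel analysis (%s null, %d iterations, P = %g)\n",
              x$mode, x$iterations, x$P))
  cat(sprintf("significant PCs: %d\n", x$k_significant))
  k <- min(5L, length(x$observed_eigenvalues))
  cat(sprintf("  PC%d: observed %.4g vs null %.4g\n", seq_len(k),
              x$observed_eigenvalues[seq_len(k)], x$null_quantiles[seq_len(k)]),
      sep = "")
  invisible(x)
}

#' Genetic contribution scores from an SVD of G
#'
#' Scores each individual's influence on the population structure:
#' gc_j = sum over the first k components of w_i |cor(G[, j], u_i)|,
#' where u_i are the left singular vectors of G and the weights
#' w_i = lambda_i / sum(lambda_1..k) are the normalised singular
#' values.  Individuals whose relationship column has zero variance
#' (correlation undefined) score 0, with a warning.
#'
#' @param G Symmetric relationship matrix with ids as dimnames.
#' @param k Number of leading components to use (1 <= k <= n), e.g.
#'   from [parallel_analysis()].
#' @return Data frame `id`, `score`, `rank` (dense ranking, ties share
#'   a rank), ordered as the input.
#' @export
contribution_scores <- function(G, k) {
  n <- nrow(G)
  if (k < 1 || k > n) stop("k must be between 1 and n")
  sv <- svd(G, nu = k, nv = 0)
  lambda <- sv$d[seq_len(k)]
  w <- lambda / sum(lambda)
  Gc <- sweep(G, 2, colMeans(G))
  sds <- sqrt(colSums(Gc^2))
  zero_var <- sds < .Machine$double.eps^0.5
  if (any(zero_var)) {
    warning("zero-variance relationship column(s) scored 0: ",
            paste(colnames(G)[zero_var], collapse = ", "))
  }
  U <- sv$u
  Uc <- sweep(U, 2, colMeans(U))
  usd <- sqrt(colSums(Uc^2))
  # |cor(G[,j], u_i)| for all j, i at once
  cors <- abs(t(crossprod(Gc, Uc)) / outer(usd, sds))
  cors[, zero_var] <- 0
  cors[!is.finite(cors)] <- 0
  score <- drop(w %*% cors)
  rank <- match(-score, sort(unique(-score)))
  data.frame(id = colnames(G) %||% as.character(seq_len(n)),
             score = score, rank = rank,
             stringsAsFactors = FALSE, row.names = NULL)
}
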