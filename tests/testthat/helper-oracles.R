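# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately use naive loops and direct
# definitions, not the vectorised code paths under test.

# Per-pair IBS tally by looping over markers.
oracle_ibs <- function(dataset) {
  g <- dataset$genotypes
  n <- nrow(g)
  out <- matrix(NA_real_, n, n, dimnames = list(dataset$ids, dataset$ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sc <- 0; cnt <- 0
      for (s in seq_len(ncol(g))) {
        a <- g[i, s]; b <- g[j, s]
        if (is.na(a) || is.na(b)) next
        cnt <- cnt + 1
        sc <- sc + if (a == b) 1 else if (abs(a - b) == 1) 0.5 else 0
      }
      out[i, j] <- sc / cnt
    }
  }
  out
}

# Brute-force ROH caller for one individual on one chromosome:
# enumerates every candidate (start, end) SNP pair, filters by the full
# constraint set, removes contained candidates, and selects greedily by
# smallest start (ties: largest end), dropping overlaps.
oracle_roh <- function(g, pos, params) {
  m <- length(g)
  het <- !is.na(g) & g == 1L
  miss <- is.na(g)
  hom <- !miss & !het
  W <- params$window_snps
  if (m < W) {
    pass1 <- sum(het) <= params$window_max_het &&
             sum(miss) <= params$window_max_missing
    elig <- rep((if (pass1) 1 else 0) > params$window_threshold, m)
  } else {
    nw <- m - W + 1L
    pass <- logical(nw)
    for (w in seq_len(nw)) {
      win <- w:(w + W - 1L)
      pass[w] <- sum(het[win]) <= params$window_max_het &&
                 sum(miss[win]) <= params$window_max_missing
    }
    elig <- logical(m)
    for (i in seq_len(m)) {
      wins <- max(1L, i - W + 1L):min(i, nw)
      elig[i] <- mean(pass[wins]) > params$window_threshold
    }
  }
  min_snps_eff <- params$min_snps + if (isTRUE(params$strict_min_snps)) 1L else 0L
  # precompute, for every start, the furthest end not blocked by an
  # ineligible SNP, an oversized gap, or the heterozygote budget
  run_end <- integer(m)
  r <- rle(elig); ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)]) + 1L
  for (k in seq_along(r$values)) run_end[starts[k]:ends[k]] <- if (r$values[k]) ends[k] else 0L
  big_gap_after <- c(diff(pos) > params$max_gap_bp, FALSE)
  hpos <- which(het)
  cands <- list()
  for (s in seq_len(m)) {
    if (!elig[s] || !hom[s]) next
    stop_e <- run_end[s]
    bg <- which(big_gap_after[s:stop_e])
    if (length(bg)) stop_e <- s + bg[1L] - 1L
    hs <- hpos[hpos >= s & hpos <= stop_e]
    if (length(hs) > params$max_het_per_segment) {
      stop_e <- hs[params$max_het_per_segment + 1L] - 1L
    }
    if (stop_e < s) next
    # test every candidate end in range against the full constraint set
    es <- s:stop_e
    len <- pos[es] - pos[s] + 1
    ok <- hom[es] & (es - s + 1L >= min_snps_eff) &
          (len >= params$min_length_bp) &
          (len / (es - s + 1L) <= params$min_density_bp_per_snp)
    if (any(ok)) {
      # only the furthest passing end can be maximal for this start
      cands[[length(cands) + 1L]] <- c(s, max(es[ok]))
    }
  }
  if (!length(cands)) return(matrix(integer(0), 0, 2))
  # leftmost-maximal greedy selection: repeatedly take the candidate
  # with the smallest start (ties: largest end) beyond the previous
  # segment, so segments never overlap
  C <- do.call(rbind, cands)
  C <- C[order(C[, 1], -C[, 2]), , drop = FALSE]
  out <- list()
  prev_end <- 0L
  for (i in seq_len(nrow(C))) {
    if (C[i, 1] > prev_end) {
      out[[length(out) + 1L]] <- C[i, ]
      prev_end <- C[i, 2]
    }
  }
  do.call(rbind, out)
}

# Wright's path-counting inbreeding coefficients.  All upward paths
# from each parent are enumerated; a common ancestor contributes
# (1/2)^(n1+n2+1) (1 + F_A) for every pair of paths sharing only the
# ancestor itself.
oracle_inbreeding_paths <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  paths_up <- function(i) {
    out <- list(c(i))
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
    }
    out
  }
  Fv <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) || is.na(d)) { Fv[i] <- 0; next }
    ps <- paths_up(s); pd <- paths_up(d)
    acc <- 0
    for (p1 in ps) {
      for (p2 in pd) {
        a <- p1[length(p1)]
        if (a != p2[length(p2)]) next
        if (length(intersect(setdiff(p1, a), setdiff(p2, a)))) next
        acc <- acc + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + Fv[a])
      }
    }
    Fv[i] <- acc
  }
  setNames(Fv, ped$id)
}

# Exhaustive two-ancestry likelihood grid for one target genotype
# vector under fixed panel frequencies F (m x 2).
oracle_grid_q <- function(g, F, grid = seq(0, 1, by = 0.01)) {
  ok <- !is.na(g)
  g <- g[ok]; F <- F[ok, , drop = FALSE]
  ll <- vapply(grid, function(q) {
    p <- q * F[, 1] + (1 - q) * F[, 2]
    sum(g * log(p) + (2 - g) * log(1 - p))
  }, 0)
  grid[which.max(ll)]
}

# Contribution scores by an explicit per-column correlation loop.
oracle_gc <- function(G, k) {
  sv <- svd(G)
  lambda <- sv$d[seq_len(k)]
  w <- lambda / sum(lambda)
  n <- ncol(G)
  score <- numeric(n)
  for (j in seq_len(n)) {
    if (stats::sd(G[, j]) == 0) { score[j] <- 0; next }
    cc <- 0
    for (i in seq_len(k)) {
      cc <- cc + w[i] * abs(stats::cor(G[, j], sv$u[, i]))
    }
    score[j] <- cc
  }
  score
}

# Minimal NEXUS DISTANCES re-parser (lower-triangular with diagonal).
oracle_parse_nexus <- function(path) {
  lines <- readLines(path)
  i0 <- grep("MATRIX", lines)[1]
  i1 <- which(trimws(lines) == ";" & seq_along(lines) > i0)[1]
  rows <- trimws(lines[(i0 + 1):(i1 - 1)])
  labs <- character(0); vals <- list()
  for (r in rows) {
    if (startsWith(r, "'")) {
      m <- regmatches(r, regexec("^'([^']*)'\\s+(.*)$", r))[[1]]
      labs <- c(labs, m[2])
      vals[[length(vals) + 1L]] <- as.numeric(strsplit(m[3], "[ \t]+")[[1]])
    } else {
      tok <- strsplit(r, "[ \t]+")[[1]]
      labs <- c(labs, tok[1])
      vals[[length(vals) + 1L]] <- as.numeric(tok[-1])
    }
  }
  n <- length(labs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    D[i, seq_len(i)] <- vals[[i]]
    D[seq_len(i), i] <- vals[[i]]
  }
  D
}
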