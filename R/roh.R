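#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow the PLINK \code{--homozyg} scanning-window approach
#' as commonly applied to equine array data: minimum SNP density of one
#' SNP per 50 kb, maximum gap of 100 kb between consecutive SNPs,
#' minimum segment length 500 kb containing at least 80 SNPs, at most
#' one heterozygous call per segment, and 50-SNP windows allowing one
#' heterozygous and five missing calls with a 0.05 hit-rate threshold.
#'
#' @param min_density_bp_per_snp Maximum average bp per SNP in a segment.
#' @param max_gap_bp Maximum gap between consecutive segment SNPs.
#' @param min_length_bp Minimum segment length (inclusive, 1-based).
#' @param min_snps Minimum number of SNPs per segment (inclusive bound;
#'   set `strict_min_snps = TRUE` for a strictly-greater rule).
#' @param max_het_per_segment Heterozygous calls allowed per segment.
#' @param window_snps Scanning window size in SNPs.
#' @param window_threshold A SNP is ROH-eligible when its proportion of
#'   passing windows is strictly greater than this.
#' @param window_max_het,window_max_missing Heterozygous/missing calls
#'   allowed per window.
#' @param strict_min_snps Require strictly more than `min_snps` SNPs.
#' @return List of class `roh_params`.
#' @export
roh_params <- function(min_density_bp_per_snp = 50000, max_gap_bp = 100000,
                       min_length_bp = 500000, min_snps = 80,
                       max_het_per_segment = 1, window_snps = 50,
                       window_threshold = 0.05, window_max_het = 1,
                       window_max_missing = 5, strict_min_snps = FALSE) {
  p <- list(min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp, min_length_bp = min_length_bp,
            min_snps = min_snps, max_het_per_segment = max_het_per_segment,
            window_snps = window_snps, window_threshold = window_threshold,
            window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            strict_min_snps = isTRUE(strict_min_snps))
  num <- unlist(p[1:9])
  if (any(num < 0) || p$min_length_bp < 1) stop("roh parameters must be positive")
  class(p) <- "roh_params"
  p
}

# Window-based ROH eligibility of every SNP on one chromosome.
# Returns a logical vector; chromosomes shorter than the window are
# treated as a single window spanning all their SNPs.
.roh_eligible <- function(het, miss, params) {
  m <- length(het)
  W <- params$window_snps
  if (m < W) {
    pass <- sum(het) <= params$window_max_het &&
            sum(miss) <= params$window_max_missing
    return(rep((if (pass) 1 else 0) > params$window_threshold, m))
  }
  ch <- cumsum(het); cm <- cumsum(miss)
  nw <- m - W + 1L
  w_het <- ch[W:m] - c(0, ch)[1:nw]
  w_mis <- cm[W:m] - c(0, cm)[1:nw]
  pass <- w_het <= params$window_max_het & w_mis <= params$window_max_missing
  cp <- c(0, cumsum(pass))
  i <- seq_len(m)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, nw)
  total <- hi - lo + 1L
  hits <- cp[hi + 1L] - cp[lo]
  hits / total > params$window_threshold
}

# Greedy leftmost-maximal segment calling inside one run of eligible
# SNPs (already free of gaps > max_gap).  pos/het/hom are vectors for
# the run; returns a matrix of (start_idx, end_idx) pairs local to the
# run.
.roh_call_segments <- function(pos, het, hom, params) {
  n <- length(pos)
  min_snps_eff <- params$min_snps + if (params$strict_min_snps) 1L else 0L
  H <- c(0L, cumsum(het))
  out <- list()
  s <- 1L
  while (s <= n - min_snps_eff + 1L) {
    if (!hom[s]) { s <- s + 1L; next }
    # furthest end under the per-segment heterozygote budget
    lim <- H[s] + params$max_het_per_segment
    e_het <- if (H[n + 1L] <= lim) n else which(H[-1L] > lim)[1L] - 1L
    # smallest end meeting the SNP-count and length floors
    e_lo <- max(s + min_snps_eff - 1L,
                s - 1L + which(pos[s:n] >= pos[s] + params$min_length_bp - 1)[1L] - 0L)
    if (is.na(e_lo) || e_lo > e_het) { s <- s + 1L; next }
    found <- NA_integer_
    for (e in seq(e_het, e_lo)) {
      if (!hom[e]) next
      len <- pos[e] - pos[s] + 1
      if (len / (e - s + 1L) <= params$min_density_bp_per_snp) { found <- e; break }
    }
    if (is.na(found)) { s <- s + 1L; next }
    out[[length(out) + 1L]] <- c(s, found)
    s <- found + 1L
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Detect runs of homozygosity
#'
#' PLINK-style overlapping-window semantics: a window of
#' `window_snps` SNPs passes when it contains at most `window_max_het`
#' heterozygous and `window_max_missing` missing calls; a SNP is
#' ROH-eligible when the proportion of passing windows covering it
#' exceeds `window_threshold`.  Maximal runs of eligible SNPs are split
#' at gaps larger than `max_gap_bp` and trimmed into segments
#' satisfying the per-segment constraints (heterozygote budget, SNP
#' count, length and density floors); segments start and end on
#' homozygous non-missing SNPs, and when a run admits several
#' candidates the leftmost-maximal one is emitted first, greedily.
#'
#' @param dataset A [geno_dataset()] (markers sorted by chromosome and
#'   position; enforced by the container).
#' @param params A [roh_params()].
#' @return Data frame `id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_het`, `length_bp` with one row per segment.
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  stopifnot(inherits(dataset, "geno_dataset"), inherits(params, "roh_params"))
  map <- dataset$map
  chroms <- unique(map$chrom)
  res <- list()
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    pos <- map$bp[idx]
    gap_split <- c(0L, which(diff(pos) > params$max_gap_bp), length(idx))
    for (i in seq_along(dataset$ids)) {
      g <- dataset$genotypes[i, idx]
      het <- !is.na(g) & g == 1L
      miss <- is.na(g)
      hom <- !miss & !het
      elig <- .roh_eligible(het, miss, params)
      # maximal runs of eligible SNPs, further split at large gaps
      r <- rle(elig)
      ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)]) + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        cuts <- gap_split[gap_split >= a & gap_split < b]
        bounds <- unique(c(a - 1L, cuts, b))
        for (t in seq_len(length(bounds) - 1L)) {
          lo <- bounds[t] + 1L; hi <- bounds[t + 1L]
          segs <- .roh_call_segments(pos[lo:hi], het[lo:hi], hom[lo:hi], params)
          if (nrow(segs)) {
            s_idx <- lo + segs[, 1L] - 1L
            e_idx <- lo + segs[, 2L] - 1L
            res[[length(res) + 1L]] <- data.frame(
              id = dataset$ids[i], chrom = ch,
              start_bp = pos[s_idx], end_bp = pos[e_idx],
              n_snps = e_idx - s_idx + 1L,
              n_het = vapply(seq_along(s_idx), function(q)
                sum(het[s_idx[q]:e_idx[q]]), 0L),
              length_bp = pos[e_idx] - pos[s_idx] + 1,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      length_bp = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$id, dataset$ids), match(out$chrom, chroms),
                   out$start_bp), ]
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding percentage from total ROH length
#'
#' F_ROH = 100 x S_ROH / L_AUTO: the percentage of the autosomal genome
#' covered by runs of homozygosity.
#'
#' @param s_roh_mb Total ROH length in Mb.
#' @param l_auto_mb Autosomal genome length in Mb (default 2280.92, the
#'   equine autosome).
#' @return F_ROH in percent.
#' @export
froh_percent <- function(s_roh_mb, l_auto_mb = 2280.92) {
  100 * s_roh_mb / l_auto_mb
}

#' Per-individual and per-population ROH summaries
#'
#' Computes N_ROH (segment count), S_ROH (total length, Mb), L_ROH
#' (mean length, Mb; `NA` when there are no segments) and F_ROH
#' (percent of the autosome, via [froh_percent()]) per individual, and
#' aggregates (mean, sd, median, min, max) per population.
#'
#' @param segments Segment table from [detect_roh()].
#' @param dataset The [geno_dataset()] the segments came from (supplies
#'   the full individual list, so ROH-free individuals appear with
#'   N_ROH = 0).
#' @param l_auto_mb Autosomal genome length in Mb (default 2280.92).
#' @return List of class `roh_summary` with data frames `individuals`
#'   and `populations`, and the constant `l_auto_mb`.
#' @export
summarize_roh <- function(segments, dataset, l_auto_mb = 2280.92) {
  stopifnot(inherits(dataset, "geno_dataset"))
  ids <- dataset$ids
  s_mb <- n_seg <- numeric(length(ids))
  if (nrow(segments)) {
    agg_s <- tapply(segments$length_bp, segments$id, sum) / 1e6
    agg_n <- tapply(segments$length_bp, segments$id, length)
    i <- match(names(agg_s), ids)
    s_mb[i] <- agg_s
    n_seg[i] <- agg_n
  }
  ind <- data.frame(id = ids, population = dataset$populations,
                    n_roh = as.integer(n_seg), s_roh_mb = s_mb,
                    l_roh_mb = ifelse(n_seg > 0, s_mb / n_seg, NA_real_),
                    f_roh = froh_percent(s_mb, l_auto_mb),
                    stringsAsFactors = FALSE)
  agg <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
                       median = stats::median(x, na.rm = TRUE),
                       min = suppressWarnings(min(x, na.rm = TRUE)),
                       max = suppressWarnings(max(x, na.rm = TRUE)))
  pops <- split(ind, ind$population)
  pop_tab <- do.call(rbind, lapply(names(pops), function(p) {
    d <- pops[[p]]
    stats_ <- rbind(n_roh = agg(d$n_roh), s_roh_mb = agg(d$s_roh_mb),
                    l_roh_mb = agg(d$l_roh_mb), f_roh = agg(d$f_roh))
    data.frame(population = p, n = nrow(d),
               statistic = rownames(stats_), stats_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(individuals = ind, populations = pop_tab,
                 l_auto_mb = l_auto_mb),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat(sprintf("ROH summary: %d individuals, L_AUTO = %.2f Mb\n",
              nrow(x$individuals), x$l_auto_mb))
  means <- x$populations[x$populations$statistic == "f_roh", c("population", "n", "mean")]
  cat("mean F_ROH (%) per population:\n")
  print.data.frame(means, digits = 4, row.names = FALSE)
  invisible(x)
}

#' ROH length-class profile per population
#'
#' Fractions of segments falling in the length classes 0.5-1, >1-2,
#' >2-4, >4-6, >6-8, >8-10 and >10 Mb (lower-exclusive, upper-inclusive
#' except the first class, which includes 0.5 Mb).  Fractions sum to 1
#' per population.
#'
#' @param segments Segment table from [detect_roh()].
#' @param populations Named character vector mapping individual id to
#'   population label.
#' @return Data frame: population, one column per class, `n_segments`.
#' @export
roh_length_classes <- function(segments, populations) {
  if (!nrow(segments)) stop("no segments to classify")
  mb <- segments$length_bp / 1e6
  if (any(mb < 0.5)) stop("segment shorter than 0.5 Mb violates the minimum-length invariant")
  breaks <- c(0.5 - 1e-9, 1, 2, 4, 6, 8, 10, Inf)
  lab <- c("0.5-1", ">1-2", ">2-4", ">4-6", ">6-8", ">8-10", ">10")
  cls <- cut(mb, breaks, labels = lab)
  pop <- populations[segments$id]
  tab <- table(pop, cls)
  frac <- tab / rowSums(tab)
  out <- data.frame(population = rownames(tab),
                    as.data.frame.matrix(frac),
                    n_segments = as.integer(rowSums(tab)),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}
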