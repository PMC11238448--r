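#' Per-SNP ROH incidence within a population
#'
#' For every marker, the fraction of a population's individuals whose
#' runs of homozygosity cover it (a marker is covered when its position
#' lies within a segment, bounds inclusive).
#'
#' @param segments Segment table from [detect_roh()] (any individuals;
#'   only the population's are used).
#' @param dataset The [geno_dataset()] providing the marker map and
#'   population labels.
#' @param population Population label.
#' @return Numeric vector of length m (aligned to the map) in `[0, 1]`.
#' @export
snp_incidence <- function(segments, dataset, population) {
  stopifnot(inherits(dataset, "geno_dataset"))
  members <- dataset$ids[dataset$populations == population]
  if (!length(members)) stop("population '", population, "' has no individuals")
  map <- dataset$map
  cover <- numeric(nrow(map))
  segs <- segments[segments$id %in% members, , drop = FALSE]
  for (ind in unique(segs$id)) {
    si <- segs[segs$id == ind, , drop = FALSE]
    covered <- logical(nrow(map))
    for (r in seq_len(nrow(si))) {
      covered <- covered | (map$chrom == si$chrom[r] &
                            map$bp >= si$start_bp[r] & map$bp <= si$end_bp[r])
    }
    cover <- cover + covered
  }
  cover / length(members)
}

#' Detect ROH islands from per-SNP incidence
#'
#' Islands are maximal runs of consecutive markers (within a
#' chromosome) whose incidence is strictly greater than the threshold;
#' a marker at exactly the threshold breaks a run.  Island bp bounds
#' are the first and last member marker positions.
#'
#' @param incidence Vector from [snp_incidence()], aligned to the map.
#' @param dataset The [geno_dataset()] providing the map.
#' @param threshold Support threshold (default 0.5, strict).
#' @param population Optional label recorded in the output.
#' @return Data frame `population`, `chrom`, `start_bp`, `end_bp`,
#'   `idx_start`, `idx_end` (row indices into the map), `n_snps`,
#'   `support` (maximum incidence), `length_mb`.
#' @export
detect_islands <- function(incidence, dataset, threshold = 0.5,
                           population = NA_character_) {
  stopifnot(inherits(dataset, "geno_dataset"))
  map <- dataset$map
  if (length(incidence) != nrow(map)) stop("incidence not aligned to the marker map")
  hot <- incidence > threshold
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r <- rle(hot[idx])
    ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)]) + 1L
    for (k in which(r$values)) {
      gi <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        population = population, chrom = ch,
        start_bp = map$bp[gi[1]], end_bp = map$bp[gi[length(gi)]],
        idx_start = gi[1], idx_end = gi[length(gi)],
        n_snps = length(gi), support = max(incidence[gi]),
        length_mb = (map$bp[gi[length(gi)]] - map$bp[gi[1]] + 1) / 1e6,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(population = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      idx_start = integer(0), idx_end = integer(0),
                      n_snps = integer(0), support = numeric(0),
                      length_mb = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Find ROH islands for every population of a dataset
#'
#' @param segments Segment table from [detect_roh()].
#' @param dataset The [geno_dataset()].
#' @param threshold Support threshold (strict; default 0.5).
#' @return Named list of island tables, one per population.
#' @export
islands_by_population <- function(segments, dataset, threshold = 0.5) {
  pops <- sort(unique(dataset$populations))
  stats::setNames(lapply(pops, function(p) {
    detect_islands(snp_incidence(segments, dataset, p), dataset,
                   threshold = threshold, population = p)
  }), pops)
}

#' Classify ROH islands as private or shared across populations
#'
#' Two islands overlap when they share at least `min_shared_snps`
#' common markers (marker indices on the common map, not bp
#' intersection alone); an island is private when it overlaps no island
#' of any other population.  Multi-population overlaps are reported per
#' contiguous run of markers covered by the same set of two or more
#' populations.
#'
#' @param islands Named list of island tables from
#'   [islands_by_population()] (computed on one common marker map).
#' @param dataset The common [geno_dataset()].
#' @param min_shared_snps Minimum shared markers (default 2).
#' @return List with `islands` (the input rows plus a `private` flag),
#'   `overlaps` (data frame `chrom`, `start_bp`, `end_bp`, `length_mb`,
#'   `n_shared_snps`, `populations`), and `summary` (per population:
#'   total, private and shared island counts).
#' @export
classify_islands <- function(islands, dataset, min_shared_snps = 2) {
  stopifnot(inherits(dataset, "geno_dataset"))
  m <- nrow(dataset$map)
  pops <- names(islands)
  for (p in pops) {
    isl <- islands[[p]]
    if (nrow(isl) && (max(isl$idx_end) > m ||
        any(dataset$map$chrom[isl$idx_start] != isl$chrom))) {
      stop("island table for '", p, "' does not match the dataset's marker map")
    }
  }
  # marker-level coverage per population
  cov <- sapply(pops, function(p) {
    v <- logical(m)
    isl <- islands[[p]]
    for (r in seq_len(nrow(isl))) v[isl$idx_start[r]:isl$idx_end[r]] <- TRUE
    v
  })
  cov <- matrix(cov, nrow = m, dimnames = list(NULL, pops))

  shared_count <- function(p, q, i1, i2, j1, j2) {
    lo <- max(i1, j1); hi <- min(i2, j2)
    if (hi < lo) 0L else hi - lo + 1L
  }
  flagged <- lapply(pops, function(p) {
    isl <- islands[[p]]
    if (!nrow(isl)) { isl$private <- logical(0); return(isl) }
    isl$private <- vapply(seq_len(nrow(isl)), function(r) {
      for (q in setdiff(pops, p)) {
        other <- islands[[q]]
        for (r2 in seq_len(nrow(other))) {
          if (other$chrom[r2] != isl$chrom[r]) next
          if (shared_count(p, q, isl$idx_start[r], isl$idx_end[r],
                           other$idx_start[r2], other$idx_end[r2]) >= min_shared_snps) {
            return(FALSE)
          }
        }
      }
      TRUE
    }, TRUE)
    isl
  })
  names(flagged) <- pops

  # contiguous runs of markers shared by the same set of >= 2 populations
  overlaps <- list()
  key <- apply(cov, 1, function(v) paste(pops[v], collapse = ","))
  npop <- rowSums(cov)
  for (ch in unique(dataset$map$chrom)) {
    idx <- which(dataset$map$chrom == ch)
    r <- rle(key[idx])
    ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)]) + 1L
    for (k in seq_along(r$values)) {
      gi <- idx[starts[k]:ends[k]]
      if (npop[gi[1]] < 2 || length(gi) < min_shared_snps) next
      overlaps[[length(overlaps) + 1L]] <- data.frame(
        chrom = ch, start_bp = dataset$map$bp[gi[1]],
        end_bp = dataset$map$bp[gi[length(gi)]],
        length_mb = (dataset$map$bp[gi[length(gi)]] - dataset$map$bp[gi[1]] + 1) / 1e6,
        n_shared_snps = length(gi), populations = r$values[k],
        stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame(chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
               length_mb = numeric(0), n_shared_snps = integer(0),
               populations = character(0), stringsAsFactors = FALSE)
  summary_tab <- do.call(rbind, lapply(pops, function(p) {
    isl <- flagged[[p]]
    data.frame(population = p, n_islands = nrow(isl),
               n_private = sum(isl$private), n_shared = sum(!isl$private),
               total_length_mb = sum(isl$length_mb),
               stringsAsFactors = FALSE)
  }))
  list(islands = flagged, overlaps = overlaps, summary = summary_tab)
}

#' Export islands as a BED file
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' 1-based inclusive island bounds is `start - 1`, `end`.
#'
#' @param islands Island table from [detect_islands()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_islands_bed <- function(islands, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open; converted from 1-based inclusive island bounds", con)
  if (nrow(islands)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", islands$chrom,
                       as.integer(islands$start_bp) - 1L,
                       as.integer(islands$end_bp),
                       ifelse(is.na(islands$population), ".", islands$population)),
               con)
  }
  invisible(path)
}
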