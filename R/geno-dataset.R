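#' SNP genotype dataset
#'
#' Container for diploid autosomal SNP genotypes: a set of individuals with
#' population labels, a marker map sorted by chromosome and base-pair
#' position, and an n x m dosage matrix counting copies of the B allele
#' (0, 1, 2, or `NA` for missing calls).
#'
#' @param ids Character vector of individual ids (unique).
#' @param populations Character vector of population labels, one per id.
#' @param map Data frame with columns `chrom`, `id`, `bp`, `allele_a`,
#'   `allele_b`; rows must be sorted by chromosome then position, with
#'   strictly increasing positions within each chromosome.
#' @param genotypes Integer matrix (individuals x markers) of B-allele
#'   dosages in \{0, 1, 2\}; `NA` marks missing calls.
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(ids, populations, map, genotypes) {
  ids <- as.character(ids)
  populations <- as.character(populations)
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  if (length(populations) != length(ids)) {
    stop("'populations' must have one label per individual")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("chrom", "id", "bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) stop("map lacks columns: ", paste(missing_cols, collapse = ", "))
  map$chrom <- as.character(map$chrom)
  map$id <- as.character(map$id)
  map$bp <- as.numeric(map$bp)
  if (anyDuplicated(map$id)) {
    stop("duplicate marker ids: ", paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(ids) || ncol(genotypes) != nrow(map)) {
    stop(sprintf("genotype matrix is %d x %d but there are %d individuals and %d markers",
                 nrow(genotypes), ncol(genotypes), length(ids), nrow(map)))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(map$chrom)) {
    pos <- map$bp[map$chrom == ch]
    if (any(diff(pos) <= 0)) {
      i <- which(diff(pos) <= 0)[1]
      stop(sprintf("positions not strictly increasing on chromosome %s (marker index %d)", ch, i + 1L))
    }
  }
  rownames(genotypes) <- ids
  colnames(genotypes) <- map$id
  structure(list(ids = ids, populations = populations, map = map,
                 genotypes = genotypes),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf("geno_dataset: %d individuals, %d markers, %d chromosomes\n",
              length(x$ids), nrow(x$map), length(unique(x$map$chrom))))
  tab <- table(x$populations)
  cat("populations: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.geno_dataset <- function(object, ...) {
  p <- b_allele_freq(object)
  maf <- pmin(p, 1 - p)
  out <- list(n = length(object$ids), m = nrow(object$map),
              populations = table(object$populations),
              maf = summary(maf), missing = mean(is.na(object$genotypes)))
  class(out) <- "summary.geno_dataset"
  out
}

#' @export
print.summary.geno_dataset <- function(x, ...) {
  cat(sprintf("%d individuals x %d markers\n", x$n, x$m))
  print(x$populations)
  cat("MAF distribution:\n"); print(x$maf)
  cat(sprintf("missing: %.2f%%\n", 100 * x$missing))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param dataset A [geno_dataset()].
#' @param individuals Optional character vector of ids (or logical/integer
#'   index) to keep.
#' @param markers Optional marker ids (or logical/integer index) to keep,
#'   in map order.
#' @return A `geno_dataset`.
#' @export
subset_dataset <- function(dataset, individuals = NULL, markers = NULL) {
  stopifnot(inherits(dataset, "geno_dataset"))
  ri <- seq_along(dataset$ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, dataset$ids) else ri[individuals]
    if (anyNA(ri)) stop("unknown individual ids: ",
                        paste(individuals[is.na(match(individuals, dataset$ids))], collapse = ", "))
  }
  ci <- seq_len(nrow(dataset$map))
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, dataset$map$id) else ci[markers]
    if (anyNA(ci)) stop("unknown marker ids")
    ci <- sort(ci)
  }
  geno_dataset(dataset$ids[ri], dataset$populations[ri],
               dataset$map[ci, , drop = FALSE],
               dataset$genotypes[ri, ci, drop = FALSE])
}

# Pooled B-allele frequency over observed calls, one value per marker.
b_allele_freq <- function(dataset) {
  g <- dataset$genotypes
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}
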