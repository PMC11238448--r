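#' Filter markers by minor allele frequency
#'
#' Computes the minor allele frequency of every marker over non-missing
#' calls across the pooled sample and drops markers with MAF strictly
#' below `threshold`; markers at exactly the threshold are retained.
#' Marker order is preserved and the filter is idempotent.
#'
#' @param dataset A [geno_dataset()].
#' @param threshold MAF exclusion threshold in `[0, 0.5]`; default 0.05.
#' @return A `geno_dataset` with the retained markers.
#' @export
maf_filter <- function(dataset, threshold = 0.05) {
  stopifnot(inherits(dataset, "geno_dataset"))
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  p <- b_allele_freq(dataset)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) stop("MAF filter removed every marker (empty panel)")
  subset_dataset(dataset, markers = which(keep))
}

#' Allele and genotype frequencies at selected markers
#'
#' Tabulates genotype counts and frequencies (AA, AB, BB) and the
#' B-allele frequency at the requested markers, over non-missing calls,
#' either pooled or per population.
#'
#' @param dataset A [geno_dataset()].
#' @param marker_ids Character vector of marker ids; default all markers.
#' @param by_population Split by population label (default `TRUE`).
#' @return Data frame with one row per marker (x population) holding
#'   counts `n_AA`, `n_AB`, `n_BB`, frequencies `f_AA`, `f_AB`, `f_BB`
#'   (summing to 1 per row) and `freq_b`.
#' @export
allele_freq <- function(dataset, marker_ids = NULL, by_population = TRUE) {
  stopifnot(inherits(dataset, "geno_dataset"))
  if (is.null(marker_ids)) marker_ids <- dataset$map$id
  idx <- match(marker_ids, dataset$map$id)
  if (anyNA(idx)) {
    stop("unknown marker id(s): ", paste(marker_ids[is.na(idx)], collapse = ", "))
  }
  groups <- if (by_population) split(seq_along(dataset$ids), dataset$populations)
            else list(all = seq_along(dataset$ids))
  out <- do.call(rbind, lapply(names(groups), function(pop) {
    g <- dataset$genotypes[groups[[pop]], idx, drop = FALSE]
    n0 <- colSums(g == 0L, na.rm = TRUE)
    n1 <- colSums(g == 1L, na.rm = TRUE)
    n2 <- colSums(g == 2L, na.rm = TRUE)
    n <- n0 + n1 + n2
    data.frame(marker = marker_ids, population = pop,
               chrom = dataset$map$chrom[idx], bp = dataset$map$bp[idx],
               n_AA = n0, n_AB = n1, n_BB = n2,
               f_AA = n0 / n, f_AB = n1 / n, f_BB = n2 / n,
               freq_b = (n1 + 2 * n2) / (2 * n),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}
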