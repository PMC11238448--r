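# Gene dropping: founder haplotypes are labelled mosaics; each meiosis
# places crossovers as a Poisson process at 1 per 100 cM (no
# interference) with a uniform position in cM, mapped linearly to bp.
# A haplotype mosaic on one chromosome is a pair of vectors (end, src):
# segment i covers (end[i-1], end[i]] in bp and descends from founder
# haplotype src[i].

# Source haplotype id at position(s) x (vectorised).
.mosaic_src_at <- function(hap, x) {
  hap$src[findInterval(x, hap$end, left.open = TRUE) + 1L]
}

# Recombine a parent's two chromosome mosaics into one gamete mosaic.
.make_gamete <- function(hap1, hap2, length_bp, length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  xo <- if (k > 0L) sort(stats::runif(k, 0, length_bp)) else numeric(0)
  phase <- sample.int(2L, 1L)
  bounds <- c(0, xo, length_bp)
  ends <- numeric(0); src <- integer(0)
  haps <- list(hap1, hap2)
  for (t in seq_len(k + 1L)) {
    lo <- bounds[t]; hi <- bounds[t + 1L]
    if (hi <= lo) next
    use <- haps[[if (t %% 2L == 1L) phase else 3L - phase]]
    idx <- which(use$end > lo & use$end < hi)
    ends <- c(ends, use$end[idx], hi)
    src <- c(src, use$src[idx], .mosaic_src_at(use, hi))
  }
  n <- length(ends)
  if (n > 1L) {
    keep <- c(src[-n] != src[-1L], TRUE)
    ends <- ends[keep]; src <- src[keep]
  }
  list(end = ends, src = src)
}

#' Gene-drop founder haplotypes down a pedigree
#'
#' Founders receive two haplotypes whose SNP alleles are drawn
#' independently per SNP from their breed's allele frequencies (no
#' background LD).  Descendants inherit recombinant parental gametes
#' with crossovers placed as a Poisson process at 1 crossover per 100 cM
#' and a linear bp-cM map per chromosome.  SNP positions are assigned
#' uniformly along each chromosome (marker count proportional to bp
#' length).  The returned truth tracks the founder-haplotype origin of
#' every genome segment: `true_q` is the genome fraction of founder
#' origin per breed, and `true_autozygosity` the fraction of the
#' autosome where both haplotypes descend from the same founder
#' haplotype (tracts of any length).
#'
#' @param ped A [pedigree()]; founders (both parents unknown) must carry
#'   a breed label matching a column of `founder_freqs`.  Individuals
#'   with exactly one known parent are not supported.
#' @param founder_freqs m x B matrix of B-allele frequencies from
#'   [simulate_founder_frequencies()].
#' @param chromosomes Data frame `name`, `length_bp`, `length_cM`.
#' @param seed Integer seed (byte-identical outputs for equal seeds).
#' @return List with `dataset` (a [geno_dataset()], population labels
#'   from the pedigree `breed` column) and `truth`: `true_q` (n x B,
#'   rows summing to 1), `true_autozygosity` (in `[0,1]`), `ibd_tracts`
#'   (per-individual data frames `chrom`, `start_bp`, `end_bp`).
#' @export
gene_drop <- function(ped, founder_freqs, chromosomes, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  founder_freqs <- as.matrix(founder_freqs)
  breeds <- colnames(founder_freqs)
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  m <- nrow(founder_freqs)
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent)) {
    stop("individuals with exactly one known parent cannot be gene-dropped: ",
         paste(ped$id[one_parent], collapse = ", "))
  }
  is_founder <- is.na(ped$sire)
  if (any(is_founder & !(ped$breed %in% breeds))) {
    stop("every founder needs a breed label matching a founder_freqs column")
  }
  set.seed(seed)

  # marker map: counts proportional to bp length, positions uniform
  n_chr <- nrow(chromosomes)
  w <- chromosomes$length_bp / sum(chromosomes$length_bp)
  m_per <- floor(m * w)
  rem <- m - sum(m_per)
  if (rem > 0) m_per[seq_len(rem)] <- m_per[seq_len(rem)] + 1L
  map_list <- lapply(seq_len(n_chr), function(c) {
    pos <- sort(sample.int(chromosomes$length_bp[c], m_per[c]))
    data.frame(chrom = chromosomes$name[c],
               id = sprintf("%s_snp%06d", chromosomes$name[c], seq_along(pos)),
               bp = pos, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, map_list)
  snp_chrom <- split(seq_len(nrow(map)), factor(map$chrom, levels = chromosomes$name))

  n <- nrow(ped)
  founder_idx <- integer(n)          # founder number (0 for non-founders)
  founder_idx[is_founder] <- seq_len(sum(is_founder))
  n_f <- sum(is_founder)
  hap_breed <- rep(ped$breed[is_founder], each = 2L)

  # founder haplotype alleles: (2 n_f) x m 0/1 matrix
  H <- matrix(0L, 2L * n_f, nrow(map))
  for (h in seq_len(2L * n_f)) {
    H[h, ] <- stats::rbinom(nrow(map), 1L, founder_freqs[, hap_breed[h]])
  }

  # drop mosaics in pedigree (topological) order
  mosaics <- vector("list", n)
  names(mosaics) <- ped$id
  row_of <- match(ped$id, ped$id)
  for (i in seq_len(n)) {
    if (is_founder[i]) {
      f <- founder_idx[i]
      mosaics[[i]] <- lapply(seq_len(n_chr), function(c) {
        L <- chromosomes$length_bp[c]
        list(h1 = list(end = L, src = 2L * f - 1L),
             h2 = list(end = L, src = 2L * f))
      })
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      mosaics[[i]] <- lapply(seq_len(n_chr), function(c) {
        L <- chromosomes$length_bp[c]; cM <- chromosomes$length_cM[c]
        list(h1 = .make_gamete(mosaics[[si]][[c]]$h1, mosaics[[si]][[c]]$h2, L, cM),
             h2 = .make_gamete(mosaics[[di]][[c]]$h1, mosaics[[di]][[c]]$h2, L, cM))
      })
    }
  }

  hap_breed_idx <- match(hap_breed, breeds)
  total_bp <- sum(chromosomes$length_bp)
  geno <- matrix(NA_integer_, n, nrow(map))
  true_q <- matrix(0, n, length(breeds), dimnames = list(ped$id, breeds))
  true_auto <- numeric(n)
  ibd_tracts <- vector("list", n)
  names(ibd_tracts) <- ped$id

  for (i in seq_len(n)) {
    tracts <- list()
    for (c in seq_len(n_chr)) {
      mz <- mosaics[[i]][[c]]
      pos <- map$bp[snp_chrom[[c]]]
      s1 <- .mosaic_src_at(mz$h1, pos)
      s2 <- .mosaic_src_at(mz$h2, pos)
      geno[i, snp_chrom[[c]]] <- H[cbind(s1, snp_chrom[[c]])] +
                                 H[cbind(s2, snp_chrom[[c]])]
      # breed-of-origin fractions from segment lengths on both haplotypes
      for (hp in c("h1", "h2")) {
        hap <- mz[[hp]]
        seg_len <- diff(c(0, hap$end))
        bidx <- hap_breed_idx[hap$src]
        for (u in unique(bidx)) {
          true_q[i, u] <- true_q[i, u] + sum(seg_len[bidx == u])
        }
      }
      # autozygous tracts: identical founder haplotype on both chromosomes
      ends_u <- sort(unique(c(mz$h1$end, mz$h2$end)))
      starts_u <- c(0, ends_u[-length(ends_u)])
      mid <- (starts_u + ends_u) / 2
      auto <- .mosaic_src_at(mz$h1, mid) == .mosaic_src_at(mz$h2, mid)
      if (any(auto)) {
        r <- rle(auto)
        hi <- cumsum(r$lengths); lo <- c(0L, hi[-length(hi)]) + 1L
        for (k in which(r$values)) {
          tracts[[length(tracts) + 1L]] <- data.frame(
            chrom = chromosomes$name[c],
            start_bp = starts_u[lo[k]], end_bp = ends_u[hi[k]])
        }
      }
    }
    tr <- if (length(tracts)) do.call(rbind, tracts) else
      data.frame(chrom = character(0), start_bp = numeric(0), end_bp = numeric(0))
    ibd_tracts[[i]] <- tr
    true_auto[i] <- sum(tr$end_bp - tr$start_bp) / total_bp
  }
  true_q <- true_q / (2 * total_bp)

  ds <- geno_dataset(ped$id, ped$breed, map, geno)
  list(dataset = ds,
       truth = list(true_q = true_q,
                    true_autozygosity = stats::setNames(true_auto, ped$id),
                    ibd_tracts = ibd_tracts))
}
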