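#' Simulation configuration for multi-breed gene dropping
#'
#' Bundles the parameters of the synthetic study design: several breeds
#' diverged from a common ancestral gene pool at known Balding-Nichols
#' divergence, bred forward for a number of discrete generations with an
#' optional fraction of close-relative matings, plus cross-breeding
#' events producing admixed individuals.
#'
#' @param n_breeds Number of breeds.
#' @param n_founders_per_breed Founders per breed (generation 0).
#' @param n_generations Number of bred generations (>= 1).
#' @param m_snps Total SNP count across the genome.
#' @param chromosomes Data frame with columns `name`, `length_bp`,
#'   `length_cM`.  Default: five 50 Mb / 50 cM autosomes.
#' @param fst_per_breed Balding-Nichols divergence in (0,1), recycled to
#'   `n_breeds`.
#' @param crossbreeding_events Data frame with columns `generation`,
#'   `sire_breed`, `dam_breed`, `n_offspring` (may be empty).
#' @param inbred_mating_fraction Proportion of matings drawn between
#'   full/half sibs (where available), in `[0, 1)`.
#' @param ancestral_freq_range Range the ancestral allele frequencies are
#'   drawn from, inside (0, 1).
#' @param seed Master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 4, n_founders_per_breed = 30,
                       n_generations = 6, m_snps = 20000,
                       chromosomes = data.frame(
                         name = paste0("chr", 1:5),
                         length_bp = rep(50e6, 5),
                         length_cM = rep(50, 5)),
                       fst_per_breed = 0.1,
                       crossbreeding_events = data.frame(
                         generation = 4L, sire_breed = "breed1",
                         dam_breed = "breed2", n_offspring = 10L),
                       inbred_mating_fraction = 0.2,
                       ancestral_freq_range = c(0.1, 0.9),
                       seed = 1L) {
  fst_per_breed <- rep_len(fst_per_breed, n_breeds)
  if (any(fst_per_breed <= 0 | fst_per_breed >= 1)) {
    stop("fst_per_breed values must lie strictly in (0, 1)")
  }
  if (n_generations < 1) stop("n_generations must be >= 1")
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (inbred_mating_fraction < 0 || inbred_mating_fraction >= 1) {
    stop("inbred_mating_fraction must be in [0, 1)")
  }
  if (length(ancestral_freq_range) != 2 || ancestral_freq_range[1] <= 0 ||
      ancestral_freq_range[2] >= 1 || ancestral_freq_range[1] > ancestral_freq_range[2]) {
    stop("ancestral_freq_range must lie inside (0, 1)")
  }
  breeds <- paste0("breed", seq_len(n_breeds))
  names(fst_per_breed) <- breeds
  if (!is.null(crossbreeding_events) && nrow(crossbreeding_events)) {
    bad <- setdiff(c(crossbreeding_events$sire_breed, crossbreeding_events$dam_breed), breeds)
    if (length(bad)) stop("crossbreeding event names unknown breed(s): ",
                          paste(bad, collapse = ", "))
    if (any(crossbreeding_events$generation < 1 |
            crossbreeding_events$generation > n_generations)) {
      stop("crossbreeding event generation out of range")
    }
  }
  structure(list(n_breeds = n_breeds, breeds = breeds,
                 n_founders_per_breed = n_founders_per_breed,
                 n_generations = n_generations, m_snps = m_snps,
                 chromosomes = chromosomes, fst_per_breed = fst_per_breed,
                 crossbreeding_events = crossbreeding_events,
                 inbred_mating_fraction = inbred_mating_fraction,
                 ancestral_freq_range = ancestral_freq_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d breeds x %d founders, %d generations, %d SNPs on %d chromosomes\n",
              x$n_breeds, x$n_founders_per_breed, x$n_generations, x$m_snps,
              nrow(x$chromosomes)))
  cat("divergence: ", paste(sprintf("%s=%.3g", names(x$fst_per_breed), x$fst_per_breed),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Balding-Nichols founder allele frequencies
#'
#' Draws ancestral frequencies uniformly inside `ancestral_freq_range`
#' and, for each breed with divergence F, per-SNP breed frequencies from
#' a Beta distribution with mean equal to the ancestral frequency p and
#' variance p(1-p)F (shape parameters p(1-F)/F and (1-p)(1-F)/F).
#'
#' @param m_snps Number of SNPs.
#' @param ancestral_freq_range Length-2 range inside (0, 1).
#' @param fst_per_breed Named (or unnamed) vector of divergences in (0,1).
#' @param seed Integer seed.
#' @return `m_snps` x `n_breeds` matrix of B-allele frequencies with the
#'   ancestral frequencies attached as attribute `"ancestral"`.
#' @export
simulate_founder_frequencies <- function(m_snps, ancestral_freq_range = c(0.1, 0.9),
                                         fst_per_breed, seed = 1L) {
  if (any(fst_per_breed <= 0 | fst_per_breed >= 1)) {
    stop("fst values must lie strictly in (0, 1)")
  }
  if (is.null(names(fst_per_breed))) {
    names(fst_per_breed) <- paste0("breed", seq_along(fst_per_breed))
  }
  set.seed(seed)
  p <- stats::runif(m_snps, ancestral_freq_range[1], ancestral_freq_range[2])
  out <- sapply(fst_per_breed, function(F) {
    stats::rbeta(m_snps, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  })
  out <- matrix(out, nrow = m_snps, dimnames = list(NULL, names(fst_per_breed)))
  attr(out, "ancestral") <- p
  out
}

#' Sample Hardy-Weinberg genotypes from breed allele frequencies
#'
#' Draws `n_per_pop` unrelated individuals per breed with independent
#' binomial(2, p) dosages, placing markers evenly along one synthetic
#' chromosome.  Convenience generator for estimator calibration where no
#' pedigree structure is needed.
#'
#' @param freqs m x B matrix of B-allele frequencies (columns = breeds).
#' @param n_per_pop Individuals per breed (recycled).
#' @param seed Integer seed.
#' @param spacing_bp Distance between adjacent markers (default 10 kb).
#' @return A [geno_dataset()].
#' @export
sample_breed_genotypes <- function(freqs, n_per_pop, seed = 1L, spacing_bp = 1e4) {
  freqs <- as.matrix(freqs)
  breeds <- colnames(freqs)
  if (is.null(breeds)) breeds <- paste0("breed", seq_len(ncol(freqs)))
  n_per_pop <- rep_len(n_per_pop, ncol(freqs))
  m <- nrow(freqs)
  set.seed(seed)
  geno <- do.call(rbind, lapply(seq_along(breeds), function(b) {
    matrix(stats::rbinom(n_per_pop[b] * m, 2L, rep(freqs[, b], each = n_per_pop[b])),
           nrow = n_per_pop[b])
  }))
  ids <- unlist(lapply(seq_along(breeds), function(b)
    sprintf("%s_i%03d", breeds[b], seq_len(n_per_pop[b]))))
  pops <- rep(breeds, n_per_pop)
  map <- data.frame(chrom = "1", id = sprintf("snp%06d", seq_len(m)),
                    bp = spacing_bp * seq_len(m),
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  geno_dataset(ids, pops, map, geno)
}

#' Generate a multi-breed pedigree with crosses and inbred matings
#'
#' Builds an acyclic pedigree: generation 0 founders carry pure breed
#' labels; each later generation contains `n_founders_per_breed`
#' offspring per breed from matings within the previous generation, a
#' configurable fraction of which are between full or half sibs.
#' Cross-breeding events insert offspring whose sire and dam come from
#' different breeds (population label "admixed").  Birth years are
#' assigned per generation starting at 2000.
#'
#' @param config A [sim_config()].
#' @return A [pedigree()] with columns `id`, `sire`, `dam`, `birth_year`,
#'   `breed`, `generation`.
#' @export
generate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  breeds <- config$breeds
  recs <- list()
  founders <- do.call(rbind, lapply(breeds, function(b) {
    data.frame(id = sprintf("%s_g0_%03d", b, seq_len(config$n_founders_per_breed)),
               sire = NA_character_, dam = NA_character_,
               birth_year = 2000L, breed = b, generation = 0L,
               stringsAsFactors = FALSE)
  }))
  recs[[1]] <- founders
  prev <- founders
  for (g in seq_len(config$n_generations)) {
    rows <- list()
    for (b in breeds) {
      pool <- prev[prev$breed == b, , drop = FALSE]
      if (nrow(pool) < 2) next
      n_off <- config$n_founders_per_breed
      for (i in seq_len(n_off)) {
        pair <- NULL
        if (stats::runif(1) < config$inbred_mating_fraction && g >= 2) {
          x <- pool[sample.int(nrow(pool), 1L), ]
          sibs <- pool$id[pool$id != x$id &
                          ((!is.na(pool$sire) & pool$sire == x$sire) |
                           (!is.na(pool$dam) & pool$dam == x$dam))]
          if (length(sibs)) pair <- c(x$id, sample(sibs, 1L))
        }
        if (is.null(pair)) pair <- sample(pool$id, 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_g%d_%03d", b, g, i),
          sire = pair[1], dam = pair[2], birth_year = 2000L + 10L * g,
          breed = b, generation = g, stringsAsFactors = FALSE)
      }
    }
    ev <- config$crossbreeding_events
    if (!is.null(ev) && nrow(ev)) {
      for (e in which(ev$generation == g)) {
        sires <- prev$id[prev$breed == ev$sire_breed[e]]
        dams <- prev$id[prev$breed == ev$dam_breed[e]]
        s <- sample(sires, 1L); d <- sample(dams, 1L)
        for (i in seq_len(ev$n_offspring[e])) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("adm_g%d_e%d_%03d", g, e, i),
            sire = s, dam = d, birth_year = 2000L + 10L * g,
            breed = "admixed", generation = g, stringsAsFactors = FALSE)
        }
      }
    }
    gen <- do.call(rbind, rows)
    recs[[g + 1L]] <- gen
    prev <- gen
  }
  pedigree(do.call(rbind, recs))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: draws founder frequencies, generates the
#' pedigree, and gene-drops founder haplotypes to produce a genotype
#' dataset with ancestry/autozygosity ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` ([geno_dataset()]), `truth` (see
#'   [gene_drop()]), `pedigree`, and `founder_freqs`.
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- simulate_founder_frequencies(config$m_snps, config$ancestral_freq_range,
                                        config$fst_per_breed, seed = config$seed)
  ped <- generate_pedigree(config)
  gd <- gene_drop(ped, freqs, config$chromosomes, seed = config$seed + 2L)
  list(dataset = gd$dataset, truth = gd$truth, pedigree = ped,
       founder_freqs = freqs)
}

#' Write simulation ground truth as TSV
#'
#' @param truth Truth list from [gene_drop()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  df <- data.frame(id = rownames(truth$true_q), truth$true_q,
                   true_autozygosity = truth$true_autozygosity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
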