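# Programmatic fixtures shared across test files.

# Tiny dataset built by hand: n individuals, m markers, one chromosome.
tiny_dataset <- function(geno, pops = NULL, spacing = 1e5) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pops)) pops <- rep("p1", n)
  map <- data.frame(chrom = "1", id = sprintf("s%03d", seq_len(m)),
                    bp = spacing * seq_len(m),
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  geno_dataset(sprintf("i%02d", seq_len(n)), pops, map, geno)
}

# Random single-chromosome genotype for ROH stress tests: mostly
# homozygous background with planted homozygous stretches, isolated
# heterozygotes, missing calls, and occasional large gaps.
rand_roh_instance <- function(seed, m = 1000) {
  set.seed(seed)
  gaps <- sample(5e3:6e4, m, replace = TRUE)
  big <- sample.int(m, size = sample(0:4, 1))
  gaps[big] <- sample(9e4:2.5e5, length(big), replace = TRUE)
  pos <- cumsum(gaps)
  het_rate <- runif(1, 0.01, 0.15)
  g <- ifelse(runif(m) < het_rate, 1L, sample(c(0L, 2L), m, replace = TRUE))
  n_stretch <- sample(1:3, 1)
  for (k in seq_len(n_stretch)) {
    len <- sample(60:400, 1)
    a <- sample.int(m - len, 1)
    g[a:(a + len - 1L)] <- sample(c(0L, 2L), len, replace = TRUE)
    for (h in seq_len(sample(0:3, 1))) {
      g[sample(a:(a + len - 1L), 1)] <- 1L
    }
  }
  g[runif(m) < 0.01] <- NA_integer_
  list(g = g, pos = pos)
}

roh_instance_dataset <- function(inst) {
  map <- data.frame(chrom = "1", id = sprintf("s%04d", seq_along(inst$pos)),
                    bp = inst$pos, allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  geno_dataset("ind", "pop", map, matrix(inst$g, 1))
}

# Random multi-generation pedigree; some unknown parents in later
# generations keep the path-counting oracle honest about the
# unrelated-founder convention.
rand_pedigree <- function(seed, generations = 5, per_gen = 6) {
  set.seed(seed)
  recs <- data.frame(id = paste0("g0_", seq_len(per_gen)),
                     sire = NA_character_, dam = NA_character_,
                     stringsAsFactors = FALSE)
  prev <- recs$id
  for (g in seq_len(generations - 1)) {
    ids <- paste0("g", g, "_", seq_len(per_gen))
    sire <- sample(prev, per_gen, replace = TRUE)
    dam <- vapply(sire, function(s) sample(setdiff(prev, s), 1), "")
    drop_parent <- runif(per_gen) < 0.1
    sire[drop_parent] <- NA
    dam[drop_parent] <- NA
    recs <- rbind(recs, data.frame(id = ids, sire = sire, dam = dam,
                                   stringsAsFactors = FALSE))
    prev <- ids
  }
  pedigree(recs)
}

# Two-breed gene-dropped dataset with F1 and backcross targets and
# known true ancestry, used by the admixture recovery tests.
cross_sim <- function(seed, m_snps = 10000, fst = 0.15, n_ref = 25,
                      n_f1 = 8, n_bc = 8) {
  freqs <- simulate_founder_frequencies(m_snps, c(0.1, 0.9),
                                        c(breed1 = fst, breed2 = fst),
                                        seed = seed)
  ids <- c(sprintf("r1_%d", seq_len(n_ref)), sprintf("r2_%d", seq_len(n_ref)),
           sprintf("f1_%d", seq_len(n_f1)), sprintf("bc_%d", seq_len(n_bc)))
  recs <- data.frame(
    id = ids,
    sire = c(rep(NA, 2 * n_ref), rep("r1_1", n_f1), rep("r1_2", n_bc)),
    dam = c(rep(NA, 2 * n_ref), rep("r2_1", n_f1), rep("f1_1", n_bc)),
    breed = c(rep("breed1", n_ref), rep("breed2", n_ref),
              rep("admixed", n_f1 + n_bc)),
    stringsAsFactors = FALSE)
  ped <- pedigree(recs)
  chroms <- data.frame(name = paste0("c", 1:5), length_bp = rep(5e7, 5),
                       length_cM = rep(50, 5))
  gd <- gene_drop(ped, freqs, chroms, seed = seed + 1L)
  list(dataset = gd$dataset, truth = gd$truth, ped = ped, freqs = freqs)
}
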