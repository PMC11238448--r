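test_that("Balding-Nichols founder frequencies have the stated moments", {
  # degenerate limit: divergence near 0 pins breed frequencies to the ancestral
  f0 <- simulate_founder_frequencies(2000, c(0.2, 0.8), c(a = 1e-4, b = 1e-4),
                                     seed = 11)
  anc <- attr(f0, "ancestral")
  expect_lt(max(abs(f0[, "a"] - anc)), 0.05)

  # fixed ancestral frequency 0.5, F = 0.5: mean 0.5, variance p(1-p)F = 0.125
  f5 <- simulate_founder_frequencies(20000, c(0.5, 0.5), c(a = 0.5), seed = 12)
  expect_equal(mean(f5[, "a"]), 0.5, tolerance = 0.01)
  expect_equal(var(f5[, "a"]), 0.125, tolerance = 0.01)

  expect_error(simulate_founder_frequencies(10, c(0.1, 0.9), c(a = 0)), "strictly")
  expect_error(simulate_founder_frequencies(10, c(0.1, 0.9), c(a = 1)), "strictly")
})

test_that("generated pedigrees are well-formed and honour cross-breeding events", {
  cfg <- sim_config(n_breeds = 3, n_founders_per_breed = 8, n_generations = 4,
                    m_snps = 100,
                    crossbreeding_events = data.frame(
                      generation = 2L, sire_breed = "breed1",
                      dam_breed = "breed3", n_offspring = 4L),
                    seed = 5)
  ped <- generate_pedigree(cfg)
  founders <- is.na(ped$sire) & is.na(ped$dam)
  expect_equal(sum(founders), 24)
  expect_true(all(ped$generation[founders] == 0))
  # parents exist and precede offspring in the (topological) record order
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  nf <- which(!founders)
  expect_true(all(idx[ped$sire[nf]] < nf & idx[ped$dam[nf]] < nf))
  # the cross-breeding event produced offspring with parents of different breeds
  adm <- ped[ped$breed == "admixed", ]
  expect_equal(nrow(adm), 4)
  expect_equal(unique(ped$breed[match(adm$sire, ped$id)]), "breed1")
  expect_equal(unique(ped$breed[match(adm$dam, ped$id)]), "breed3")

  # 1 generation, no crosses: a pedigree of founders plus one bred generation
  cfg1 <- sim_config(n_breeds = 2, n_founders_per_breed = 5, n_generations = 1,
                     m_snps = 10, crossbreeding_events = NULL, seed = 1)
  ped1 <- generate_pedigree(cfg1)
  expect_true(all(is.na(ped1$sire[ped1$generation == 0])))
})

test_that("gene drop yields exact founder and F1 ground truth", {
  sc <- cross_sim(seed = 21, m_snps = 1500, n_ref = 5, n_f1 = 3, n_bc = 2)
  tq <- sc$truth$true_q
  # founders: unit ancestry vector, zero autozygosity
  expect_equal(unname(tq["r1_3", ]), c(1, 0))
  expect_equal(unname(sc$truth$true_autozygosity[["r1_3"]]), 0)
  # F1 of pure sire x pure dam: exactly half/half
  expect_equal(unname(tq["f1_2", ]), c(0.5, 0.5))
  # simplex and bounds hold everywhere
  expect_equal(unname(rowSums(tq)), rep(1, nrow(tq)), tolerance = 1e-9)
  expect_true(all(sc$truth$true_autozygosity >= 0 &
                  sc$truth$true_autozygosity <= 1))
  # genotypes complete and in range
  expect_true(all(sc$dataset$genotypes %in% 0:2))
})

test_that("ibd tract union equals true autozygosity and tracts do not overlap", {
  sc <- cross_sim(seed = 22, m_snps = 500, n_ref = 4, n_f1 = 2, n_bc = 6)
  total_bp <- 5 * 5e7
  for (id in names(sc$truth$ibd_tracts)) {
    tr <- sc$truth$ibd_tracts[[id]]
    expect_equal(sum(tr$end_bp - tr$start_bp) / total_bp,
                 unname(sc$truth$true_autozygosity[[id]]))
    for (ch in unique(tr$chrom)) {
      tc <- tr[tr$chrom == ch, ]
      tc <- tc[order(tc$start_bp), ]
      if (nrow(tc) > 1) {
        expect_true(all(tc$start_bp[-1] >= tc$end_bp[-nrow(tc)]))
      }
    }
  }
})

test_that("full-sib F1 x F1 offspring average 25% autozygosity", {
  # 100 independent families x 2 offspring, so the average runs over
  # parental meioses as well as offspring ones
  fam <- lapply(seq_len(100), function(f) {
    p <- sprintf("fam%03d_%s", f, c("S", "D", "f1a", "f1b", "o1", "o2"))
    data.frame(id = p,
               sire = c(NA, NA, p[1], p[1], p[3], p[3]),
               dam = c(NA, NA, p[2], p[2], p[4], p[4]),
               breed = c("breed1", "breed2", rep("admixed", 4)),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, fam)
  ped <- pedigree(recs)
  freqs <- simulate_founder_frequencies(200, c(0.2, 0.8),
                                        c(breed1 = 0.1, breed2 = 0.1), seed = 31)
  chroms <- data.frame(name = paste0("c", 1:5), length_bp = rep(5e7, 5),
                       length_cM = rep(50, 5))
  gd <- gene_drop(ped, freqs, chroms, seed = 32)
  off <- grep("_o[12]$", ped$id, value = TRUE)
  auto <- gd$truth$true_autozygosity[off]
  expect_lt(abs(mean(auto) - 0.25), 0.03)
})

test_that("identical seeds reproduce identical outputs", {
  cfg <- sim_config(n_breeds = 2, n_founders_per_breed = 6, n_generations = 2,
                    m_snps = 300, crossbreeding_events = NULL, seed = 77)
  s1 <- simulate_breeds(cfg)
  s2 <- simulate_breeds(cfg)
  expect_identical(s1$dataset$genotypes, s2$dataset$genotypes)
  expect_identical(s1$truth$true_q, s2$truth$true_q)
  expect_identical(s1$pedigree, s2$pedigree)
})

test_that("founder-breed allele frequencies converge to the generating values", {
  freqs <- simulate_founder_frequencies(400, c(0.2, 0.8), c(breed1 = 0.2),
                                        seed = 41)
  recs <- data.frame(id = sprintf("f%03d", 1:150), sire = NA, dam = NA,
                     breed = "breed1", stringsAsFactors = FALSE)
  gd <- gene_drop(pedigree(recs), freqs,
                  data.frame(name = "c1", length_bp = 5e7, length_cM = 50),
                  seed = 42)
  p_hat <- colMeans(gd$dataset$genotypes) / 2
  expect_equal(unname(p_hat), unname(freqs[, 1]), tolerance = 0.12)
  expect_gt(cor(p_hat, freqs[, 1]), 0.97)
})
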