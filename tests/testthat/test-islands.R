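# A dataset with a planted consensus homozygous region: `carriers` of
# the population carry one shared ROH segment spanning marker indices
# span[1]..span[2].
planted_island_data <- function(n = 10, m = 300, span = c(100, 220),
                                carriers = 6, seed = 101) {
  set.seed(seed)
  pos <- seq(2e4, by = 2e4, length.out = m)
  g <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m)
  for (i in seq_len(carriers)) {
    g[i, span[1]:span[2]] <- sample(c(0L, 2L), diff(span) + 1, replace = TRUE)
  }
  map <- data.frame(chrom = "1", id = sprintf("s%04d", 1:m), bp = pos,
                    allele_a = "A", allele_b = "B")
  ds <- geno_dataset(sprintf("i%02d", 1:n), rep("pop", n), map, g)
  segs <- data.frame(id = sprintf("i%02d", seq_len(carriers)), chrom = "1",
                     start_bp = pos[span[1]], end_bp = pos[span[2]],
                     n_snps = diff(span) + 1L, n_het = 0L,
                     length_bp = pos[span[2]] - pos[span[1]] + 1,
                     stringsAsFactors = FALSE)
  list(ds = ds, segs = segs, pos = pos)
}

test_that("snp incidence equals the brute-force membership tally", {
  pd <- planted_island_data()
  inc <- snp_incidence(pd$segs, pd$ds, "pop")
  expect_equal(inc[100:220], rep(0.6, 121))
  expect_equal(inc[1:99], rep(0, 99))
  # brute-force tally over random segment fixtures
  set.seed(102)
  segs <- do.call(rbind, lapply(sprintf("i%02d", 1:10), function(id) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    a <- sort(sample(pd$pos, k))
    data.frame(id = id, chrom = "1", start_bp = a,
               end_bp = pmin(a + 5e5, max(pd$pos)), n_snps = 2L, n_het = 0L,
               length_bp = 5e5, stringsAsFactors = FALSE)
  }))
  inc2 <- snp_incidence(segs, pd$ds, "pop")
  manual <- vapply(seq_along(pd$pos), function(j) {
    covered <- vapply(sprintf("i%02d", 1:10), function(id) {
      si <- segs[segs$id == id, , drop = FALSE]
      any(si$start_bp <= pd$pos[j] & si$end_bp >= pd$pos[j])
    }, TRUE)
    mean(covered)
  }, 0)
  expect_equal(unname(inc2), manual)
  expect_error(snp_incidence(pd$segs, pd$ds, "nosuch"), "no individuals")
})

test_that("island detection is strict at the support threshold", {
  pd <- planted_island_data()
  m <- nrow(pd$ds$map)
  inc <- rep(0, m)
  inc[50:60] <- 0.5       # exactly at threshold: excluded
  inc[100:110] <- 0.51
  inc[112:120] <- 0.7     # separated by one sub-threshold marker
  inc[111] <- 0.5
  isl <- detect_islands(inc, pd$ds, threshold = 0.5, population = "pop")
  expect_equal(nrow(isl), 2)
  expect_equal(isl$idx_start, c(100L, 112L))
  expect_equal(isl$idx_end, c(110L, 120L))
  expect_equal(isl$support, c(0.51, 0.7))
  expect_equal(nrow(detect_islands(rep(0, m), pd$ds)), 0)
})

test_that("a planted consensus region yields exactly one island at its coordinates", {
  pd <- planted_island_data()
  segs <- detect_roh(pd$ds)  # carriers' planted stretch is the only ROH
  inc <- snp_incidence(segs, pd$ds, "pop")
  isl <- detect_islands(inc, pd$ds, population = "pop")
  expect_equal(nrow(isl), 1)
  # recovered bounds sit within a few SNPs of the planted span: the
  # window hit-rate of a stretch's outermost SNPs falls below the
  # threshold (few covering windows pass), trimming the edges slightly
  expect_lte(abs(isl$idx_start - 100L), 4L)
  expect_lte(abs(isl$idx_end - 220L), 4L)
  expect_gt(isl$support, 0.5)
})

test_that("island classification honours the two-SNP overlap rule", {
  pd <- planted_island_data()
  mk <- function(pop, i1, i2) {
    data.frame(population = pop, chrom = "1",
               start_bp = pd$pos[i1], end_bp = pd$pos[i2],
               idx_start = i1, idx_end = i2, n_snps = i2 - i1 + 1L,
               support = 0.8, length_mb = (pd$pos[i2] - pd$pos[i1] + 1) / 1e6,
               stringsAsFactors = FALSE)
  }
  empty <- mk("x", 1, 2)[0, ]
  # identical islands in two populations: shared
  res <- classify_islands(list(a = mk("a", 10, 20), b = mk("b", 10, 20)),
                          pd$ds)
  expect_false(res$islands$a$private)
  expect_false(res$islands$b$private)
  expect_equal(res$overlaps$n_shared_snps, 11L)
  expect_equal(res$overlaps$populations, "a,b")

  # overlap of exactly one marker: both remain private
  res1 <- classify_islands(list(a = mk("a", 10, 20), b = mk("b", 20, 30)),
                           pd$ds)
  expect_true(res1$islands$a$private)
  expect_true(res1$islands$b$private)
  expect_equal(nrow(res1$overlaps), 0)

  # overlap of exactly two markers: shared
  res2 <- classify_islands(list(a = mk("a", 10, 20), b = mk("b", 19, 30)),
                           pd$ds)
  expect_false(res2$islands$a$private)
  expect_equal(res2$overlaps$n_shared_snps, 2L)

  # private + shared = total per population (three-way fixture)
  res3 <- classify_islands(list(a = rbind(mk("a", 10, 20), mk("a", 50, 60)),
                                b = mk("b", 15, 25), c = empty), pd$ds)
  s <- res3$summary
  expect_equal(s$n_private + s$n_shared, s$n_islands)
  expect_equal(s$n_islands[s$population == "a"], 2)
  expect_equal(s$n_private[s$population == "a"], 1)
})

test_that("classification matches a brute-force interval-intersection oracle", {
  pd <- planted_island_data()
  set.seed(103)
  rand_islands <- function(pop, k) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      a <- sample(1:280, 1); b <- min(a + sample(3:30, 1), 300)
      data.frame(population = pop, chrom = "1", start_bp = pd$pos[a],
                 end_bp = pd$pos[b], idx_start = a, idx_end = b,
                 n_snps = b - a + 1L, support = 0.9,
                 length_mb = (pd$pos[b] - pd$pos[a] + 1) / 1e6,
                 stringsAsFactors = FALSE)
    }))
  }
  isl <- list(a = rand_islands("a", 4), b = rand_islands("b", 4),
              c = rand_islands("c", 3))
  res <- classify_islands(isl, pd$ds)
  for (p in names(isl)) {
    for (r in seq_len(nrow(isl[[p]]))) {
      shared <- FALSE
      for (q in setdiff(names(isl), p)) {
        for (r2 in seq_len(nrow(isl[[q]]))) {
          ov <- length(intersect(isl[[p]]$idx_start[r]:isl[[p]]$idx_end[r],
                                 isl[[q]]$idx_start[r2]:isl[[q]]$idx_end[r2]))
          if (ov >= 2) shared <- TRUE
        }
      }
      expect_equal(res$islands[[p]]$private[r], !shared)
    }
  }
})
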