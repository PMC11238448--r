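test_that("hand-written .ped/.map fixture parses to the expected dosages", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1\tsnpA\t0\t1000",
               "1\tsnpB\t0\t2000",
               "2\tsnpC\t0\t500"), map_path)
  # individual 1: A/A C/T G/G ; individual 2: A/C T/T C/G
  writeLines(c("fam1 ind1 0 0 1 -9 A A C T G G",
               "fam1 ind2 0 0 2 -9 A C T T C G"), ped_path)
  ds <- read_plink_text(ped_path, map_path)
  expect_equal(ds$ids, c("ind1", "ind2"))
  # B allele is the lexicographically larger of the observed alleles
  expect_equal(ds$map$allele_b, c("C", "T", "G"))
  expect_equal(unname(ds$genotypes["ind1", c("snpA", "snpB", "snpC")]),
               c(0L, 1L, 2L))
  expect_equal(unname(ds$genotypes["ind2", c("snpA", "snpB", "snpC")]),
               c(1L, 2L, 1L))
})

test_that("markers with unknown position are excluded on read", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1\tok1\t0\t1000", "1\tbad\t0\t0", "1\tok2\t0\t3000"), map_path)
  writeLines("f i 0 0 0 -9 A A G G C C", ped_path)
  expect_message(ds <- read_plink_text(ped_path, map_path), "unknown chromosomal position")
  expect_equal(ds$map$id, c("ok1", "ok2"))
  expect_equal(unname(ds$genotypes[1, ]), c(0L, 0L))
})

test_that("ragged and malformed files raise format errors naming the line", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200"), map_path)
  writeLines(c("f i1 0 0 0 -9 A A G G",
               "f i2 0 0 0 -9 A A G"), ped_path)
  expect_error(read_plink_text(ped_path, map_path), "line 2")
  writeLines(c("1\ts1\t0\t100", "1\ts1\t0\t200"), map_path)
  writeLines("f i1 0 0 0 -9 A A G G", ped_path)
  expect_error(read_plink_text(ped_path, map_path), "duplicate marker id")
})

test_that("PLINK text and VCF round-trips preserve the dosage matrix", {
  sc <- cross_sim(seed = 51, m_snps = 400, n_ref = 4, n_f1 = 2, n_bc = 2)
  ds <- sc$dataset
  ds$genotypes[1, 5] <- NA  # include a missing call
  ped_path <- withr::local_tempfile(fileext = ".ped")
  map_path <- withr::local_tempfile(fileext = ".map")
  write_plink_text(ds, ped_path, map_path)
  back <- read_plink_text(ped_path, map_path)
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
  expect_equal(back$map$bp, ds$map$bp)

  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ds, vcf_path)
  back2 <- read_vcf(vcf_path)
  expect_identical(unname(back2$genotypes), unname(ds$genotypes))
  expect_equal(back2$map$chrom, ds$map$chrom)
})

test_that("VCF GT coding follows the ALT-dosage definition", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
               "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
               "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./."), path)
  ds <- read_vcf(path)
  expect_equal(unname(ds$genotypes[, "v1"]), c(0L, 1L))
  expect_equal(unname(ds$genotypes[, "v2"]), c(2L, NA))

  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0/1"), path)
  expect_error(read_vcf(path), "non-diploid")
})

test_that("MAF filter honours the boundary and is idempotent", {
  # 10 individuals; snp1 monomorphic, snp2 one heterozygote (MAF 0.05),
  # snp3 common
  g <- cbind(rep(0L, 10),
             c(1L, rep(0L, 9)),
             c(rep(0L, 5), rep(2L, 5)))
  ds <- tiny_dataset(g)
  kept <- maf_filter(ds, 0.05)
  expect_equal(kept$map$id, c("s002", "s003"))  # boundary MAF 0.05 retained
  expect_identical(maf_filter(kept, 0.05)$genotypes, kept$genotypes)
  expect_error(maf_filter(tiny_dataset(matrix(0L, 4, 3)), 0.05), "empty panel")
  expect_error(maf_filter(ds, 0.7), "threshold")
})

test_that("MAF decisions match a brute-force recount on random genotypes", {
  set.seed(61)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 100, replace = TRUE,
                     prob = c(0.45, 0.2, 0.3, 0.05)), 30, 100)
  ds <- tiny_dataset(g)
  kept <- tryCatch(maf_filter(ds, 0.05)$map$id, error = function(e) character(0))
  manual <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j][!is.na(g[, j])]
    p <- sum(x) / (2 * length(x))
    min(p, 1 - p) >= 0.05
  }, TRUE)
  expect_equal(kept, ds$map$id[manual])
})

test_that("allele frequencies match direct tallies and sum to one", {
  g <- rbind(c(2L, 0L), c(2L, 1L), c(2L, 1L), c(2L, 0L))
  ds <- tiny_dataset(g, pops = c("a", "a", "b", "b"))
  tab <- allele_freq(ds, c("s001", "s002"))
  all2 <- tab[tab$marker == "s001" & tab$population == "a", ]
  expect_equal(all2$freq_b, 1.0)
  # counts AA=2, AB=2, BB=0 -> B freq 0.25 (pooled)
  pooled <- allele_freq(tiny_dataset(rbind(0L, 0L, 1L, 1L)),
                        "s001", by_population = FALSE)
  expect_equal(pooled$freq_b, 0.25)
  expect_equal(pooled$f_AA + pooled$f_AB + pooled$f_BB, 1)

  set.seed(62)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 40, replace = TRUE), 20, 40)
  ds <- tiny_dataset(g, pops = rep(c("x", "y"), each = 10))
  tab <- allele_freq(ds)
  for (r in sample(nrow(tab), 10)) {
    x <- g[ds$populations == tab$population[r], match(tab$marker[r], ds$map$id)]
    x <- x[!is.na(x)]
    expect_equal(tab$freq_b[r], sum(x) / (2 * length(x)))
    expect_equal(tab$n_AB[r], sum(x == 1))
  }
  expect_error(allele_freq(ds, "nope"), "unknown marker")
})
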