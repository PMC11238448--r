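test_that("pedigree construction sorts topologically and rejects cycles", {
  recs <- data.frame(id = c("z", "a", "b"), sire = c("a", NA, NA),
                     dam = c("b", NA, NA), stringsAsFactors = FALSE)
  ped <- pedigree(recs)
  expect_equal(ped$id[3], "z")
  expect_error(pedigree(data.frame(id = c("a", "b"), sire = c("b", "a"),
                                   dam = c(NA, NA))), "cycle")
  expect_error(pedigree(data.frame(id = "a", sire = "ghost", dam = NA)),
               "absent")
  expect_error(pedigree(data.frame(id = c("a", "a"), sire = NA, dam = NA)),
               "duplicate")
})

test_that("inbreeding reproduces the classic closed forms", {
  full_sib <- pedigree(data.frame(
    id = c("a", "b", "x", "y", "z"), sire = c(NA, NA, "a", "a", "x"),
    dam = c(NA, NA, "b", "b", "y"), stringsAsFactors = FALSE))
  Fv <- pedigree_inbreeding(full_sib)
  expect_equal(unname(Fv[c("a", "x", "z")]), c(0, 0, 0.25))

  half_sib <- pedigree(data.frame(
    id = c("a", "b", "c", "x", "y", "z"), sire = c(NA, NA, NA, "a", "a", "x"),
    dam = c(NA, NA, NA, "b", "c", "y"), stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_inbreeding(half_sib)["z"]), 0.125)

  # parent-offspring mating: F = 0.25
  po <- pedigree(data.frame(id = c("a", "b", "x", "z"),
                            sire = c(NA, NA, "a", "a"),
                            dam = c(NA, NA, "b", "x"), stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_inbreeding(po)["z"]), 0.25)
})

test_that("Meuwissen-Luo equals Wright path counting on random pedigrees", {
  for (seed in 1:20) {
    ped <- rand_pedigree(seed)
    expect_equal(pedigree_inbreeding(ped), oracle_inbreeding_paths(ped),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("pedigree admixture follows the parental-mean and cutoff rules", {
  f1 <- pedigree(data.frame(
    id = c("S", "D", "F1"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    birth_year = c(1990, 1990, 2000),
    breed = c("foreign", "home", NA), stringsAsFactors = FALSE))
  a <- pedigree_admixture(f1, home_breed = "home")
  expect_equal(unname(a["F1"]), 50.00)

  # F1 backcrossed to the home breed: 25
  bc <- pedigree(data.frame(
    id = c("S", "D", "D2", "F1", "BC"), sire = c(NA, NA, NA, "S", "F1"),
    dam = c(NA, NA, NA, "D", "D2"), birth_year = c(1990, 1990, 1990, 2000, 2010),
    breed = c("foreign", "home", "home", NA, NA), stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_admixture(bc, "home")["BC"]), 25.00)

  # purebred line: 0 throughout
  pure <- pedigree(data.frame(
    id = c("a", "b", "x"), sire = c(NA, NA, "a"), dam = c(NA, NA, "b"),
    birth_year = c(1980, 1980, 1995), breed = c("home", "home", NA),
    stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_admixture(pure, "home")), c(0, 0, 0))

  # the cutoff-year convention: an unlabelled founder born before the
  # cutoff counts as purebred; born after, it is an error
  old <- pedigree(data.frame(
    id = c("olda", "b", "x"), sire = c(NA, NA, "olda"), dam = c(NA, NA, "b"),
    birth_year = c(1940, 1990, 2000), breed = c(NA, "home", NA),
    stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_admixture(old, "home")["x"]), 0)
  young <- pedigree(data.frame(
    id = c("ya", "b", "x"), sire = c(NA, NA, "ya"), dam = c(NA, NA, "b"),
    birth_year = c(1990, 1990, 2000), breed = c(NA, "home", NA),
    stringsAsFactors = FALSE))
  expect_error(pedigree_admixture(young, "home"), "no breed label")
  # explicit founder fractions override the label rule
  frac <- pedigree(data.frame(
    id = c("S", "D", "F1"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    birth_year = c(1990, 1990, 2000), breed = c("foreign", "home", NA),
    foreign_pct = c(60, NA, NA), stringsAsFactors = FALSE))
  expect_equal(unname(pedigree_admixture(frac, "home")["F1"]), 30)
})

test_that("pedigree admixture equals the founder-fraction expectation of true_q", {
  cfg <- sim_config(n_breeds = 2, n_founders_per_breed = 8, n_generations = 3,
                    m_snps = 50,
                    crossbreeding_events = data.frame(
                      generation = 2L, sire_breed = "breed1",
                      dam_breed = "breed2", n_offspring = 6L),
                    seed = 13)
  ped <- generate_pedigree(cfg)
  a <- pedigree_admixture(ped, home_breed = "breed2",
                          purebred_cutoff_year = 1900)
  # expectation of true_q under gene dropping is the parental mean, which
  # is exactly what A_PED computes: verify against an explicit recursion
  expect_equal(unname(a[ped$breed == "breed1"][1]), 100)
  adm <- ped$id[ped$breed == "admixed"]
  expect_equal(unname(a[adm]), rep(50, length(adm)))
})

test_that("genomic-vs-pedigree comparison recovers known regression structure", {
  # exact identity
  x <- setNames(seq(0.01, 0.3, length.out = 20), paste0("i", 1:20))
  cmp <- compare_genomic_pedigree(froh = x, fped = x)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$slope, 1)
  expect_equal(cmp$intercept, 0, tolerance = 1e-12)

  # noisy linear model at n = 200
  set.seed(111)
  fped <- setNames(runif(200, 0, 0.3), paste0("i", 1:200))
  froh <- fped + rnorm(200, 0, 0.02)
  cmp2 <- compare_genomic_pedigree(froh = froh, fped = fped)
  expect_gt(cmp2$pearson_r, 0.9)
  expect_lt(abs(cmp2$slope - 1), 0.1)
  # agreement with lm() as the independent fitting oracle
  fit <- lm(froh ~ fped)
  expect_equal(cmp2$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(cmp2$r_squared, summary(fit)$r.squared, tolerance = 1e-10)

  # planted sire effects: adding sire/dam factors raises R^2
  set.seed(112)
  sires <- sample(paste0("s", 1:5), 100, replace = TRUE)
  dams <- sample(paste0("d", 1:8), 100, replace = TRUE)
  eff <- setNames(seq(-0.05, 0.05, length.out = 5), paste0("s", 1:5))
  fped3 <- setNames(runif(100, 0, 0.2), paste0("i", 1:100))
  froh3 <- fped3 + eff[sires] + rnorm(100, 0, 0.01)
  pf <- data.frame(id = paste0("i", 1:100), sire = sires, dam = dams,
                   stringsAsFactors = FALSE)
  cmp3 <- compare_genomic_pedigree(froh = froh3, fped = fped3,
                                   parent_factors = pf)
  expect_gt(attr(cmp3, "factor_r_squared"), cmp3$r_squared)

  expect_error(compare_genomic_pedigree(froh = x[1:2], fped = x[1:2]),
               "fewer than 3")
  # A_GEN vs A_PED path works too
  cmp4 <- compare_genomic_pedigree(agen = 100 * froh, aped = 100 * fped)
  expect_equal(cmp4$pair, "A_GEN ~ A_PED")
})
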