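test_that("observed heterozygosity matches hand values on toy cases", {
  # all homozygotes
  ds <- toy_dataset(rbind("10/10", "12/12"), pop = c("p1", "p1"))
  expect_equal(unname(observed_heterozygosity(ds, "dataset")$mean), 0)
  # one het, one hom
  ds <- toy_dataset(rbind("10/12", "12/12"), pop = c("p1", "p1"))
  expect_equal(unname(observed_heterozygosity(ds, "dataset")$mean), 0.5)
})

test_that("expected heterozygosity uses the uncorrected pooled formula", {
  # monomorphic locus
  ds <- toy_dataset(rbind("10/10", "10/10"), pop = c("p1", "p1"))
  expect_equal(unname(expected_heterozygosity(ds, "dataset")$per_locus[1, 1]), 0)
  # two alleles at 0.5/0.5
  ds <- toy_dataset(rbind("10/12", "10/12"), pop = c("p1", "p1"))
  expect_equal(unname(expected_heterozygosity(ds, "dataset")$mean), 0.5)
})

test_that("fixation index follows F = 1 - Ho/He with He = 0 undefined", {
  f <- fixation_index(c(0.5, 0, 0.169, 0.2), c(0.5, 0.4, 0.341, 0))
  expect_equal(unname(f$per_locus[1:3, 1]),
               c(0, 1, 1 - 0.169 / 0.341))
  expect_true(is.na(f$per_locus[4, 1]))      # He = 0 is excluded
  expect_equal(1 - 0.169 / 0.341, 0.5044, tolerance = 1e-4)
})

test_that("private alleles are counted by strict exclusivity", {
  ds <- toy_dataset(rbind("10/12", "14/14"), pop = c("p1", "p2"),
                    species_of_pop = c(p1 = "s1", p2 = "s2"))
  pa <- private_alleles(ds)
  expect_equal(unname(pa$counts[c("s1", "s2")]), c(2L, 1L))
  # identical allele sets: none private
  ds <- toy_dataset(rbind("10/12", "12/10"), pop = c("p1", "p2"),
                    species_of_pop = c(p1 = "s1", p2 = "s2"))
  expect_equal(sum(private_alleles(ds)$counts), 0L)
  # a single group is an error
  ds1 <- toy_dataset(rbind("10/12"), pop = "p1")
  expect_error(private_alleles(ds1), "2 groups")
})

test_that("per-population private-allele frequency counts private copies", {
  ds <- toy_dataset(rbind("10/14", "10/10", "12/12"),
                    pop = c("p1", "p1", "p2"),
                    species_of_pop = c(p1 = "s1", p2 = "s2"))
  pa <- private_alleles(ds)
  # in p1: alleles 10 (x3) and 14 (x1) are private to s1 -> 4/4 copies
  f1 <- pa$pop_freq$private_freq[pa$pop_freq$population == "p1"]
  expect_equal(f1, 1)
})

test_that("AMOVA reproduces the fixed and null differentiation endpoints", {
  # two populations fixed for different alleles: Phi_ST = 1
  ds <- toy_dataset(cbind(rep(c("10/10", "14/14"), each = 10)),
                    pop = rep(c("p1", "p2"), each = 10))
  am <- amova(ds, hierarchy = "population", n_perm = 199)
  expect_equal(unname(am$phi["phi_st"]), 1)
  expect_lt(am$p[["p_st"]], 0.05)

  # identical allele frequencies: Phi_ST near 0, p not significant
  set.seed(11)
  arr <- array(sample(c(10L, 12L), 2 * 60 * 2, replace = TRUE),
               dim = c(60, 2, 2))
  ds <- genotype_dataset(arr, pop = rep(c("p1", "p2"), each = 30))
  am <- amova(ds, hierarchy = "population", n_perm = 199)
  expect_lt(abs(am$phi[["phi_st"]]), 0.05)
  expect_gt(am$p[["p_st"]], 0.05)
})

test_that("AMOVA sums of squares match the pairwise-distance oracle", {
  set.seed(5)
  for (rep in 1:4) {
    ds <- random_dataset(n = 9, L = 3, n_pop = 3, n_species = 2,
                         missing_rate = 0.1)
    am <- amova(ds, hierarchy = "species/population", n_perm = 0)
    orc <- oracle_amova_ss(ds, ds$pop,
                           ds$species_of_pop)
    expect_equal(am$table$SS[1], orc$among_grp, tolerance = 1e-12)
    expect_equal(am$table$SS[2], orc$among_pop_within_grp, tolerance = 1e-12)
    expect_equal(am$table$SS[3], orc$within_pop, tolerance = 1e-12)
    expect_equal(am$table$SS[4], orc$total, tolerance = 1e-12)
  }
})

test_that("total sum of squares is invariant to relabeling within populations", {
  set.seed(6)
  ds <- random_dataset(n = 12, L = 4, n_pop = 3, n_species = 2,
                       missing_rate = 0)
  am1 <- amova(ds, "species/population", n_perm = 0)
  # permute individuals within each population (reorder rows)
  ord <- unlist(lapply(unique(ds$pop), function(p) sample(which(ds$pop == p))))
  ds2 <- subset_individuals(ds, ord)
  am2 <- amova(ds2, "species/population", n_perm = 0)
  expect_equal(am1$table$SS[4], am2$table$SS[4], tolerance = 1e-12)
  expect_equal(am1$phi, am2$phi, tolerance = 1e-12)
})

test_that("pairwise F_ST hits its endpoints and a self-split stays near zero", {
  ds <- toy_dataset(rbind("10/10", "10/10", "14/14", "14/14"),
                    pop = c("p1", "p1", "p2", "p2"))
  pw <- pairwise_fst(ds)
  expect_equal(pw$fst["p1", "p2"], 1)
  expect_equal(diag(pw$fst), c(p1 = 0, p2 = 0))
  expect_equal(pw$fst, t(pw$fst))

  # one panmictic population split in half at random: F_ST centered near 0
  set.seed(21)
  arr <- array(sample(c(10L, 12L, 14L), 2 * 100 * 3, replace = TRUE),
               dim = c(100, 3, 2))
  ds <- genotype_dataset(arr, pop = rep(c("h1", "h2"), 50))
  pw <- pairwise_fst(ds)
  expect_lt(pw$fst["h1", "h2"], 0.02)

  # undersized populations are skipped with a warning
  ds3 <- toy_dataset(rbind("10/10", "12/12", "14/14"),
                     pop = c("p1", "p1", "p2"))
  expect_warning(pairwise_fst(ds3), "skipping")
})

test_that("diversity statistics match the naive oracles to 1e-12", {
  set.seed(9)
  for (rep in 1:5) {
    ds <- random_dataset(n = 10, L = 4, n_pop = 2, n_species = 2,
                         missing_rate = 0.15)
    sp <- species_of_individual(ds)
    ho <- observed_heterozygosity(ds, "species")
    he <- expected_heterozygosity(ds, "species")
    for (s in unique(sp)) {
      expect_equal(unname(ho$per_locus[, s]), oracle_ho(ds, which(sp == s)),
                   tolerance = 1e-12)
      expect_equal(unname(he$per_locus[, s]), oracle_he(ds, which(sp == s)),
                   tolerance = 1e-12)
    }
    pa <- private_alleles(ds)
    orc <- oracle_private_counts(ds, sp)
    expect_equal(pa$counts[names(orc)], orc)
  }
})

test_that("geography regression matches closed-form least squares", {
  pf <- data.frame(population = paste0("p", 1:5), species = "s1",
                   private_freq = c(0.02, 0.04, 0.06, 0.08, 0.10))
  geo <- data.frame(population = paste0("p", 1:5),
                    latitude = c(23, 23.5, 24, 24.5, 25),
                    longitude = 121, altitude = c(500, 1000, 1500, 2000, 2500))
  # exact line: slope 2 (per 50,000 m), p ~ 0
  pf2 <- pf; pf2$private_freq <- 2 * geo$altitude
  r <- suppressWarnings(geography_regression(pf2, geo, predictors = "altitude"))
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)

  # constant response: slope 0, t = 0
  pf3 <- pf; pf3$private_freq <- 0.05
  r <- geography_regression(pf3, geo, predictors = "altitude")
  expect_equal(r$slope, 0, tolerance = 1e-12)
  expect_equal(r$t, 0, tolerance = 1e-12)

  # hand-computed OLS on a textbook 5-point set
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 7)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  pf4 <- pf; pf4$private_freq <- y
  geo4 <- geo; geo4$altitude <- x
  r <- geography_regression(pf4, geo4, predictors = "altitude")
  expect_equal(r$slope, beta, tolerance = 1e-10)
  se <- sqrt(sum(stats::lm(y ~ x)$residuals^2) / 3 / sum((x - mean(x))^2))
  expect_equal(r$t, beta / se, tolerance = 1e-10)

  # zero-variance predictor
  geo5 <- geo; geo5$altitude <- 1000
  expect_error(geography_regression(pf, geo5, predictors = "altitude"),
               "zero-variance")
})
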