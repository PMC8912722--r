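test_that("scenario specification validates its parameter constraints", {
  expect_error(scenario_spec("SC", 1e4, 1e3, 1e3, 1e3, 1e3,
                             t1 = 100, t2 = 200), "t2 < t1")
  expect_error(scenario_spec("SC", -1, 1e3, 1e3, 1e3, 1e3,
                             t1 = 200, t2 = 100))
  sp <- scenario_spec("AM", 1e4, 1e3, 1e3, 1e3, 1e3, m1 = 1e-4,
                      t1 = 200, t2 = 100)
  expect_s3_class(sp, "scenario_spec")
})

test_that("an immediate merge reduces to the panmictic pairwise expectation", {
  # t1 -> 0: a sampled pair coalesces in the ancestral deme of size Ne, so
  # the mean pairwise time must be 2 Ne generations
  ne <- 500
  sp <- scenario_spec("SI", ne, ne, ne, ne, ne, t1 = 1e-9, t2 = 5e-10,
                      mu = 0, n_loci = 1, n_cau = 1, n_mor = 1)
  set.seed(31)
  h <- replicate(10000, simulate_locus(sp, 1, 1)$height)
  expect_equal(mean(h), 2 * ne, tolerance = 0.05)
})

test_that("stepwise mutation reaches the Ohta-Kimura equilibrium diversity", {
  ne <- 1000; mu <- 5e-4
  sp <- scenario_spec("SI", ne, ne, ne, ne, ne, t1 = 1e-9, t2 = 5e-10,
                      mu = mu, n_loci = 500, n_cau = 25, n_mor = 25)
  set.seed(32)
  ds <- simulate_dataset(sp)
  he <- expected_heterozygosity(ds, "dataset")
  expect_equal(unname(mean(he$per_locus)), 1 - 1 / sqrt(1 + 8 * ne * mu),
               tolerance = 0.05)
})

test_that("simulated datasets have the requested shape and are seeded", {
  sp <- scenario_spec("SC", 1e4, 5e3, 5e3, 1e3, 1e3, m1 = 1e-4,
                      t1 = 2e4, t2 = 1e4, n_loci = 17, n_cau = 20, n_mor = 20)
  set.seed(33)
  ds1 <- simulate_dataset(sp)
  expect_equal(n_individuals(ds1), 40)
  expect_equal(n_loci(ds1), 17)
  expect_equal(as.vector(table(species_of_individual(ds1))[c("cau", "mor")]),
               c(20L, 20L))
  set.seed(33)
  ds2 <- simulate_dataset(sp)
  expect_identical(ds1$alleles, ds2$alleles)   # same seed, same data

  # mu = 0: every locus monomorphic at the ancestral state
  sp0 <- scenario_spec("SI", 1e3, 1e3, 1e3, 1e3, 1e3, t1 = 2e3, t2 = 1e3,
                       mu = 0, n_loci = 5, n_cau = 5, n_mor = 5)
  ds0 <- simulate_dataset(sp0)
  expect_true(all(ds0$alleles == 20L))
})

test_that("gene flow leaves a monotone signature across the migration grid", {
  # SC with increasing m1 must increasingly homogenize the species pair:
  # between-species F_ST decreases and shared-allele proportion rises
  set.seed(34)
  fst <- shared <- numeric(3)
  ms <- c(0, 1e-4, 1e-3)
  for (j in seq_along(ms)) {
    s <- colMeans(t(replicate(120, {
      sp <- scenario_spec("SC", 2e4, 5e3, 5e3, 2e3, 2e3,
                          m1 = ms[j], m2 = 0, t1 = 4e4, t2 = 2e4,
                          n_loci = 5, n_cau = 10, n_mor = 10)
      summary_stat_vector(simulate_dataset(sp))[c("fst", "shared")]
    })))
    fst[j] <- s["fst"]; shared[j] <- s["shared"]
  }
  expect_true(all(diff(fst) < 0))
  expect_true(all(diff(shared) > 0))
})

test_that("summary statistics are exchangeable and match the naive oracle", {
  set.seed(35)
  sp <- scenario_spec("CM", 1e4, 5e3, 5e3, 2e3, 2e3, m1 = 1e-4, m2 = 1e-4,
                      t1 = 3e4, t2 = 1e4, n_loci = 6, n_cau = 8, n_mor = 8)
  ds <- simulate_dataset(sp)
  s1 <- summary_stat_vector(ds)
  # permute individuals within each species
  ord <- c(sample(1:8), 8 + sample(1:8))
  s2 <- summary_stat_vector(subset_individuals(ds, ord))
  expect_equal(s1, s2, tolerance = 1e-12)

  # naive double-loop oracle on small datasets, including missing data
  for (rep in 1:3) {
    ds <- random_dataset(n = 8, L = 3, n_pop = 2, n_species = 2,
                         missing_rate = 0.15)
    expect_equal(summary_stat_vector(ds), oracle_summary_stats(ds),
                 tolerance = 1e-12)
  }
})

test_that("degenerate monomorphic data yield the conventional statistics", {
  ds <- toy_dataset(rbind("10/10", "10/10"), pop = c("p1", "p2"),
                    species_of_pop = c(p1 = "s1", p2 = "s2"))
  s <- summary_stat_vector(ds)
  expect_equal(unname(s[c("he_a", "he_b", "fst")]), c(0, 0, 0))
  expect_equal(unname(s["shared"]), 1)
})
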