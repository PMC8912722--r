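# Two fixed disjoint-allele populations: the fully separable base case.
separable_dataset <- function(n_per = 15, L = 8) {
  arr <- array(NA_integer_, dim = c(2 * n_per, L, 2))
  arr[1:n_per, , ] <- 10L
  arr[(n_per + 1):(2 * n_per), , ] <- 20L
  genotype_dataset(arr, pop = rep(c("pA", "pB"), each = n_per),
                   species_of_pop = c(pA = "sA", pB = "sB"))
}

test_that("K = 1 gives unit ancestry and chain validation works", {
  ds <- separable_dataset(5, 3)
  run <- gibbs_admixture(ds, K = 1, chain_len = 200, seed = 1)
  expect_true(all(run$Q == 1))
  expect_error(gibbs_admixture(ds, K = 2, chain_len = 100, burn_in = 100),
               "exceed")
})

test_that("ancestry rows stay on the simplex and chains are reproducible", {
  ds <- separable_dataset(8, 5)
  r1 <- gibbs_admixture(ds, K = 2, chain_len = 600, seed = 7)
  expect_equal(unname(rowSums(r1$Q)), rep(1, 16), tolerance = 1e-12)
  expect_true(all(is.finite(r1$loglik)))
  r2 <- gibbs_admixture(ds, K = 2, chain_len = 600, seed = 7)
  expect_identical(r1$Q, r2$Q)                  # same seed, same chain
})

test_that("fully separated populations are assigned to their own clusters", {
  ds <- separable_dataset(15, 8)
  # a weak ancestry prior lets the posterior mean reach the boundary
  runs <- align_replicates(lapply(1:2, function(s)
    gibbs_admixture(ds, K = 2, chain_len = 1500, seed = s, alpha = 0.05)))
  for (run in runs) {
    own <- c(rep(which.max(colMeans(run$Q[1:15, ])), 15),
             rep(which.max(colMeans(run$Q[16:30, ])), 15))
    q_own <- run$Q[cbind(1:30, own)]
    expect_true(all(q_own >= 0.99))
  }
  # different seeds agree after alignment
  expect_equal(runs[[1]]$Q, runs[[2]]$Q, tolerance = 0.02)
})

test_that("constructed F1 hybrids recover half-and-half ancestry", {
  base <- separable_dataset(15, 8)
  f1 <- array(NA_integer_, dim = c(6, 8, 2))
  f1[, , 1] <- 10L                 # one copy from each parental pool
  f1[, , 2] <- 20L
  arr <- array(NA_integer_, dim = c(36, 8, 2))
  arr[1:30, , ] <- base$alleles
  arr[31:36, , ] <- f1
  ds <- genotype_dataset(arr, pop = c(base$pop, rep("pH", 6)),
                         species_of_pop = c(pA = "sA", pB = "sB", pH = "sA"))
  run <- gibbs_admixture(ds, K = 2, chain_len = 2000, seed = 3)
  expect_equal(unname(run$Q[31:36, 1]), rep(0.5, 6), tolerance = 0.05)
})

test_that("replicate alignment undoes label switching", {
  Q <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.1, 0.2, 0.9, 0.8), ncol = 2)
  mk <- function(Qm, perm) {
    structure(list(Q = Qm[, perm, drop = FALSE], K = 2),
              class = "admixture_run")
  }
  runs <- list(mk(Q, 1:2), mk(Q, 2:1), mk(Q, 1:2))
  al <- align_replicates(runs)
  expect_equal(al[[2]]$Q, Q)
  expect_equal(al[[2]]$perm, c(2, 1))
  expect_equal(al[[3]]$perm, c(1, 2))
  # identical runs align to equality
  expect_equal(al[[1]]$Q, al[[3]]$Q)

  # K = 3 with a known 3-cycle
  Q3 <- matrix(runif(30), ncol = 3)
  Q3 <- Q3 / rowSums(Q3)
  r3 <- list(structure(list(Q = Q3, K = 3), class = "admixture_run"),
             structure(list(Q = Q3[, c(3, 1, 2)], K = 3),
                       class = "admixture_run"))
  al3 <- align_replicates(r3)
  expect_equal(al3[[2]]$Q, Q3, tolerance = 1e-12)
})

test_that("the Evanno table implements the second-difference formula", {
  # hand-computed case: deltaK(2) = |-45 - 2(-50) + (-100)| / 2 = 22.5
  tab <- data.frame(K = rep(1:3, each = 2),
                    ln_pk = c(-100, -100, -52, -48, -45, -45))
  dk <- evanno_delta_k(tab)
  expect_equal(dk$delta_k[dk$K == 2],
               abs(-45 - 2 * (-50) + (-100)) / stats::sd(c(-52, -48)))
  expect_true(is.na(dk$delta_k[dk$K == 1]) && is.na(dk$delta_k[dk$K == 3]))

  # likelihood linear in K: all interior deltas are 0
  lin <- data.frame(K = rep(1:4, each = 2),
                    ln_pk = rep(c(-40, -30, -20, -10), each = 2) + c(-1, 1))
  dk <- evanno_delta_k(lin)
  expect_equal(dk$delta_k[dk$K %in% 2:3], c(0, 0))

  # zero spread is flagged, not an error
  z <- data.frame(K = rep(1:3, each = 2), ln_pk = rep(c(-9, -5, -4), each = 2))
  dk <- evanno_delta_k(z)
  expect_true(is.na(dk$delta_k[dk$K == 2]))
  expect_match(dk$note[dk$K == 2], "sd=0")
  expect_error(evanno_delta_k(data.frame(K = c(1, 2), ln_pk = c(-2, -1))),
               ">= 3")
})

test_that("strongly two-clustered data put the Evanno optimum at K = 2", {
  ds <- separable_dataset(12, 8)
  lnpk <- do.call(rbind, lapply(1:3, function(K)
    data.frame(K = K, ln_pk = vapply(1:3, function(r)
      gibbs_admixture(ds, K, chain_len = 800, seed = 10 * K + r)$ln_pk,
      numeric(1)))))
  dk <- evanno_delta_k(lnpk)
  expect_equal(dk$K[which.max(dk$delta_k)], 2)
})

test_that("introgression classes follow the ancestry thresholds", {
  Q <- cbind(1 - c(0.04, 0.20, 0.6574, 0.9229), c(0.04, 0.20, 0.6574, 0.9229))
  arr <- array(10L, dim = c(4, 1, 2))
  ds <- genotype_dataset(arr, pop = rep("pA", 4),
                         species_of_pop = c(pA = "sA"))
  # force a two-species context via a second, empty-species mapping
  ds$species_of_pop <- c(pA = "sA", pB = "sB")
  ds$pop <- c("pA", "pA", "pA", "pB")
  calls <- classify_introgression(Q, ds, cluster_species = c("sA", "sB"))
  expect_equal(calls$class[1:3], c("pure", "introgressed", "hybrid"))
  # the fourth individual hosts species sB, so its foreign ancestry is
  # column 1 at 1 - 0.9229 = 0.0771, just over the introgression threshold
  expect_equal(calls$class[4], "introgressed")
  ds$pop <- rep("pA", 4)
  calls <- classify_introgression(Q, ds, cluster_species = c("sA", "sB"))
  expect_equal(calls$class[4], "misassigned")
  expect_error(classify_introgression(Q[, 1, drop = FALSE], ds), "K = 2")
})

test_that("introgression rates use the retained denominator", {
  calls <- data.frame(
    id = sprintf("i%02d", 1:12), population = "p",
    host_species = rep(c("sA", "sB"), each = 6),
    q_other = c(0.2, rep(0.01, 5), 0.3, 0.6, 0.95, rep(0.01, 3)),
    class = c("introgressed", rep("pure", 5),
              "introgressed", "hybrid", "misassigned", rep("pure", 3)))
  r <- introgression_rate(calls)
  expect_equal(r$percent[r$species == "sA"], 100 * 1 / 6)
  # the misassigned individual drops out of the denominator
  expect_equal(r$n_retained[r$species == "sB"], 5)
  expect_equal(r$percent[r$species == "sB"], 100 * 2 / 5)
})

test_that("geographic ranges of introgressed individuals match the truth", {
  calls <- data.frame(id = c("a", "b", "c"),
                      population = c("p1", "p2", "p1"),
                      host_species = "sA",
                      q_other = c(0.2, 0.3, 0.01),
                      class = c("introgressed", "introgressed", "pure"))
  geo <- data.frame(population = c("p1", "p2"),
                    latitude = c(23, 24), longitude = c(121, 121.3),
                    altitude = c(2000, 2375))
  g <- introgression_geography(calls, geo)
  expect_equal(g$ranges$alt_min, 2000)
  expect_equal(g$ranges$alt_max, 2375)
  expect_equal(g$ranges$n, 2)
  # a single individual gives a degenerate range
  g1 <- introgression_geography(calls[1, ], geo)
  expect_equal(c(g1$ranges$alt_min, g1$ranges$alt_max), c(2000, 2000))
  # no calls: empty result, not an error
  g0 <- introgression_geography(calls[calls$class == "hybrid", ], geo)
  expect_equal(nrow(g0$ranges), 0)
})
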