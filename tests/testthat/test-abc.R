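test_that("prior draws honor bounds and the t2 < t1 constraint", {
  pr <- prior_spec()
  set.seed(51)
  d <- sample_priors(pr, 5000)
  expect_true(all(d$t2 < d$t1))
  expect_true(all(d$ne_anc >= 1e2 & d$ne_anc <= 1e6))
  expect_true(all(d$m1[d$model == "SI"] == 0))
  expect_true(all(d$m1[d$model != "SI"] >= 1e-6))
  # uniform component: LLN check on t1
  expect_equal(mean(d$t1), mean(pr$t1_bounds), tolerance = 0.02)
  expect_equal(sort(unique(d$model)), c("AM", "CM", "SC", "SI"))
})

test_that("reference tables are reproducible and finite", {
  pr <- prior_spec(ne_bounds = c(1e2, 1e4), t1_bounds = c(1e3, 1e4),
                   m_bounds = c(1e-6, 1e-3))
  set.seed(52)
  t1 <- run_reference_table(pr, 60, n_loci = 3, n_cau = 5, n_mor = 5)
  set.seed(52)
  t2 <- run_reference_table(pr, 60, n_loci = 3, n_cau = 5, n_mor = 5)
  expect_identical(t1, t2)
  expect_true(all(is.finite(as.matrix(t1[, attr(t1, "stat_names")]))))
  # roughly uniform over the four models
  expect_true(all(table(t1$model) >= 5))
})

test_that("rejection retains the nearest simulations under standardization", {
  set.seed(53)
  tab <- data.frame(model = rep(c("A", "B"), 10),
                    s1 = rnorm(20), s2 = rnorm(20))
  attr(tab, "stat_names") <- c("s1", "s2")
  obs <- c(s1 = tab$s1[7], s2 = tab$s2[7])
  rej <- abc_reject(tab, obs, 3)
  expect_equal(rej$retained$dist[1], 0)          # exact match has distance 0
  expect_true(7 %in% rej$index)

  # n_keep = table size is the identity
  rej_all <- abc_reject(tab, obs, 20)
  expect_equal(sort(rej_all$index), 1:20)
  expect_error(abc_reject(tab, obs, 21), "exceeds")

  # brute-force check of the retained set on a 5-row toy
  toy <- data.frame(model = "A", s1 = c(0, 1, 2, 3, 4), s2 = c(0, 0, 0, 0, 0))
  attr(toy, "stat_names") <- c("s1", "s2")
  obs <- c(s1 = 1.2, s2 = 0)
  suppressWarnings(rej <- abc_reject(toy, obs, 2))   # s2 has MAD 0, dropped
  ctr <- median(toy$s1); sc <- mad(toy$s1)
  d_manual <- abs((toy$s1 - ctr) / sc - (1.2 - ctr) / sc)
  expect_equal(sort(rej$index), sort(order(d_manual)[1:2]))

  # row order is irrelevant up to ties
  set.seed(54)
  perm <- sample(20)
  tabp <- tab[perm, ]; attr(tabp, "stat_names") <- c("s1", "s2")
  obs <- c(s1 = 0.3, s2 = -0.2)
  r1 <- abc_reject(tab, obs, 5)
  r2 <- abc_reject(tabp, obs, 5)
  expect_equal(sort(r1$retained$dist), sort(r2$retained$dist))
})

test_that("model posteriors normalize, and Bayes factors are consistent ratios", {
  # constructed retained set with model frequencies matching the published
  # posterior-probability vector; the rejection method recovers it and the
  # Bayes factor SC vs SI is their ratio
  freq <- c(SC = 488, CM = 360, AM = 148, SI = 5)
  ret <- data.frame(model = rep(names(freq), freq),
                    s1 = 0, dist = seq_len(sum(freq)) / sum(freq))
  rej <- list(retained = ret, stat_cols = "s1",
              center = c(s1 = 0), scale = c(s1 = 1),
              observed_std = c(s1 = 0))
  mp <- model_posterior(rej, method = "rejection")
  expect_equal(sum(mp$pp), 1)
  # probabilities are clipped away from 0 and renormalized before the
  # Bayes factors are formed, hence the small slack
  expect_equal(unname(mp$pp["SC"]), 0.488, tolerance = 2e-3)
  expect_equal(unname(mp$pp["SI"]), 0.005, tolerance = 2e-3)
  expect_equal(unname(mp$bf["SC", "SI"]), 97.6, tolerance = 1e-6)
  # antisymmetry BF(i,j) * BF(j,i) = 1
  expect_equal(mp$bf * t(mp$bf), matrix(1, 4, 4, dimnames = dimnames(mp$bf)),
               tolerance = 1e-12)
})

test_that("two statistically identical models split the posterior evenly", {
  set.seed(55)
  n <- 400
  tab <- data.frame(model = rep(c("A", "B"), each = n / 2),
                    s1 = rnorm(n), s2 = rnorm(n))
  attr(tab, "stat_names") <- c("s1", "s2")
  obs <- c(s1 = 0, s2 = 0)
  rej <- abc_reject(tab, obs, 200)
  for (m in c("rejection", "mnlogistic")) {
    mp <- model_posterior(rej, method = m)
    expect_equal(sum(mp$pp), 1)
    expect_equal(unname(mp$pp["A"]), 0.5, tolerance = 0.12)
  }
})

test_that("goodness of fit separates central from outlying observations", {
  set.seed(56)
  tab <- data.frame(model = "A", s1 = rnorm(500), s2 = rnorm(500))
  attr(tab, "stat_names") <- c("s1", "s2")
  ctr <- c(s1 = median(tab$s1), s2 = median(tab$s2))
  g1 <- goodness_of_fit(tab, ctr, n_rep = 400)
  expect_gt(g1$p, 0.9)
  g2 <- goodness_of_fit(tab, c(s1 = 30, s2 = -30), n_rep = 400)
  expect_lt(g2$p, 0.01)
  expect_warning(goodness_of_fit(tab, ctr, n_rep = 50), "low-resolution")
})

test_that("the goodness-of-fit p-value is calibrated under the null", {
  # observations drawn from the same cloud must give a ~U(0,1) p-value
  set.seed(57)
  tab <- data.frame(model = "A", s1 = rnorm(800), s2 = rexp(800))
  attr(tab, "stat_names") <- c("s1", "s2")
  ps <- replicate(200, {
    obs <- c(s1 = rnorm(1), s2 = rexp(1))
    goodness_of_fit(tab, obs, n_rep = 790)$p
  })
  # discrete p-values tie; the KS statistic is still the right summary
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("weighted quantiles and modes match brute-force oracles", {
  set.seed(58)
  x <- rlnorm(300); w <- runif(300)
  for (p in c(0.025, 0.5, 0.975))
    expect_equal(weighted_quantile(x, w, p), oracle_wquantile(x, w, p))
  # point mass
  expect_equal(weighted_mode(rep(3, 5), rep(1, 5)), 3)
})

test_that("posterior estimation adjusts toward deterministic relationships", {
  set.seed(59)
  n <- 500
  s1 <- rnorm(n)
  ret <- data.frame(model = "A", par = exp(1 + 2 * s1), s1 = s1,
                    dist = runif(n, 0.2, 1))
  rej <- list(retained = ret, stat_cols = "s1",
              center = c(s1 = 0), scale = c(s1 = 1),
              observed_std = c(s1 = 0.7))
  post <- estimate_posteriors(rej, params = "par")
  # par is an exact (log-)linear function of s1: the posterior collapses
  # onto the implied value exp(1 + 2 * 0.7)
  expect_equal(post$summary$mode, exp(1 + 2 * 0.7), tolerance = 0.02)
  expect_lt(post$summary$q97.5 / post$summary$q2.5, 1.01)

  # a parameter independent of the statistics stays close to its
  # unadjusted weighted quantiles
  set.seed(60)
  ret2 <- data.frame(model = "A", par = rnorm(n), s1 = rnorm(n),
                     dist = runif(n, 0.2, 1))
  rej2 <- rej; rej2$retained <- ret2
  post2 <- estimate_posteriors(rej2, params = "par")
  w <- 1 - (ret2$dist / max(ret2$dist))^2
  expect_equal(post2$summary$q2.5,
               weighted_quantile(ret2$par, w, 0.025), tolerance = 0.3)
  expect_equal(post2$summary$q97.5,
               weighted_quantile(ret2$par, w, 0.975), tolerance = 0.3)
  # summaries are ordered and the mode lies inside the interval
  expect_true(post2$summary$q2.5 <= post2$summary$mode &&
              post2$summary$mode <= post2$summary$q97.5)
})

test_that("generation-to-year conversion applies the generation time", {
  expect_equal(generations_to_years(0)$years, 0)
  g <- generations_to_years(18870, 5)
  expect_equal(g$years, 94350)
  expect_equal(g$kyr, 94)
  expect_equal(generations_to_years(18870, 1)$kyr, 19)
  expect_error(generations_to_years(10, 0))
})

test_that("prior bounds constrain the regression adjustment when supplied", {
  set.seed(61)
  n <- 300
  s1 <- rnorm(n)
  # parameter correlated with the statistic; the observation far outside
  # the cloud would push an unbounded adjustment past the prior ceiling
  ret <- data.frame(model = "A", par = exp(4 + s1), s1 = s1,
                    dist = runif(n, 0.2, 1))
  rej <- list(retained = ret, stat_cols = "s1",
              center = c(s1 = 0), scale = c(s1 = 1),
              observed_std = c(s1 = 8))
  free <- estimate_posteriors(rej, params = "par")
  capped <- estimate_posteriors(rej, params = "par",
                                bounds = list(par = c(1, 1000)))
  expect_gt(max(free$adjusted[, "par"]), 1000)
  expect_true(all(capped$adjusted[, "par"] >= 1 &
                  capped$adjusted[, "par"] <= 1000))
  expect_true(capped$summary$q97.5 <= 1000)
})
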