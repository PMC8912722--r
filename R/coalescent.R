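#' Specify a two-deme divergence scenario
#'
#' The four isolation-with-migration scenarios contrasted by the pipeline
#' share one parameterisation: two species ("cau" = deme A, "mor" = deme B)
#' diverged from a common ancestor `t1` generations ago, sizes were allowed
#' to change at `t2 < t1`, and an asymmetric gene-flow window depends on the
#' model:
#' * `SI` — strict isolation, never any gene flow;
#' * `AM` — ancient migration, gene flow only in `(t2, t1)`;
#' * `SC` — secondary contact, gene flow only in `(0, t2)`;
#' * `CM` — continuous migration, gene flow in `(0, t1)`.
#'
#' `m1` is the forward per-generation migration rate from A into B, `m2` the
#' reverse. Backward in time (the simulator's frame) a lineage sampled in B
#' therefore jumps to A at rate `m1`.
#'
#' @param model one of `"SI"`, `"AM"`, `"SC"`, `"CM"`.
#' @param ne_anc,ne_cau_t1,ne_mor_t1,ne_cau_t2,ne_mor_t2 diploid effective
#'   sizes (individuals): ancestral, and per species in the old (`t2`,`t1`)
#'   and recent (`0`,`t2`) epochs.
#' @param m1,m2 migration rates per generation, in `[0, 1)`.
#' @param t1 divergence time, generations before present.
#' @param t2 size-change / gene-flow switch time, `0 < t2 < t1`.
#' @param mu per-locus per-generation stepwise mutation rate.
#' @param n_loci number of independent loci.
#' @param n_cau,n_mor diploid sample sizes per species.
#' @param anc_state ancestral allele state (repeat number).
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(model = c("SI", "AM", "SC", "CM"),
                          ne_anc, ne_cau_t1, ne_mor_t1, ne_cau_t2, ne_mor_t2,
                          m1 = 0, m2 = 0, t1, t2,
                          mu = 5e-4, n_loci = 17L, n_cau = 20L, n_mor = 20L,
                          anc_state = 20L) {
  model <- match.arg(model)
  sizes <- c(ne_anc, ne_cau_t1, ne_mor_t1, ne_cau_t2, ne_mor_t2)
  stopifnot(all(sizes > 0), t1 > 0, t2 > 0, t2 < t1,
            m1 >= 0, m1 < 1, m2 >= 0, m2 < 1, mu >= 0,
            n_loci >= 1, n_cau >= 1, n_mor >= 1, anc_state >= 2)
  structure(list(model = model, ne_anc = ne_anc,
                 ne_cau_t1 = ne_cau_t1, ne_mor_t1 = ne_mor_t1,
                 ne_cau_t2 = ne_cau_t2, ne_mor_t2 = ne_mor_t2,
                 m1 = m1, m2 = m2, t1 = t1, t2 = t2, mu = mu,
                 n_loci = as.integer(n_loci),
                 n_cau = as.integer(n_cau), n_mor = as.integer(n_mor),
                 anc_state = as.integer(anc_state)),
            class = "scenario_spec")
}

.model_code <- function(model) match(model, c("SI", "AM", "SC", "CM")) - 1L

#' Simulate one microsatellite locus under a divergence scenario
#'
#' Draws a structured-coalescent genealogy for haploid samples from the two
#' demes (epochs `(0,t2)`, `(t2,t1)`, then a single ancestral deme), moves
#' lineages between demes during the model's migration window, and drops
#' strict stepwise mutations (Poisson along branches, +/-1 repeat with equal
#' probability, states floored at 2 repeats).
#'
#' Uses R's global RNG: call `set.seed()` for reproducibility.
#'
#' @param spec a [scenario_spec()].
#' @param n_hap_cau,n_hap_mor haploid sample sizes (default `2 * n_cau`
#'   etc. from the spec).
#' @return list with `states` (integer allele states, cau lineages first),
#'   `deme` (1/2 labels), `height` (tree height in generations) and
#'   `n_boundary` (mutations clipped at the 2-repeat floor).
#' @export
simulate_locus <- function(spec, n_hap_cau = 2L * spec$n_cau,
                           n_hap_mor = 2L * spec$n_mor) {
  stopifnot(inherits(spec, "scenario_spec"))
  r <- sim_locus_cpp(as.integer(n_hap_cau), as.integer(n_hap_mor),
                     .model_code(spec$model),
                     spec$ne_cau_t2, spec$ne_mor_t2,
                     spec$ne_cau_t1, spec$ne_mor_t1, spec$ne_anc,
                     spec$m1, spec$m2, spec$t1, spec$t2,
                     spec$mu, spec$anc_state)
  r$deme <- rep(1:2, c(n_hap_cau, n_hap_mor))
  r
}

#' Simulate a full diploid dataset under a scenario
#'
#' Simulates `n_loci` independent loci and pairs haploid lineages
#' sequentially into diploid individuals within each deme.
#'
#' @param spec a [scenario_spec()].
#' @return a [genotype_dataset()] with one population per species
#'   (`"cau"`, `"mor"`); tree heights per locus are attached as attribute
#'   `"heights"`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n1 <- spec$n_cau; n2 <- spec$n_mor
  h1 <- 2L * n1; h2 <- 2L * n2
  arr <- array(NA_integer_, dim = c(n1 + n2, spec$n_loci, 2L))
  heights <- numeric(spec$n_loci)
  for (l in seq_len(spec$n_loci)) {
    r <- simulate_locus(spec, h1, h2)
    s <- r$states
    arr[seq_len(n1), l, 1] <- s[2 * seq_len(n1) - 1]
    arr[seq_len(n1), l, 2] <- s[2 * seq_len(n1)]
    arr[n1 + seq_len(n2), l, 1] <- s[h1 + 2 * seq_len(n2) - 1]
    arr[n1 + seq_len(n2), l, 2] <- s[h1 + 2 * seq_len(n2)]
    heights[l] <- r$height
  }
  ds <- genotype_dataset(
    arr,
    individual_ids = c(paste0("cau_", seq_len(n1)), paste0("mor_", seq_len(n2))),
    locus_names = paste0("locus_", seq_len(spec$n_loci)),
    pop = rep(c("cau", "mor"), c(n1, n2)),
    species_of_pop = c(cau = "cau", mor = "mor"))
  attr(ds, "heights") <- heights
  ds
}

#' Fixed-order SSR summary-statistic vector
#'
#' The statistic set used for ABC: per species, the mean (over loci) of
#' expected heterozygosity, observed heterozygosity, allele count,
#' allele-size variance and Garza-Williamson M-ratio; jointly, the
#' between-species F_ST (pooled-frequency Hs/Ht, ratio of sums over loci),
#' the mean squared difference in mean allele size (delta-mu squared), the
#' proportion of shared alleles, and private-allele counts scaled per 100
#' sampled copies. Missing genotypes are dropped locus-wise. Monomorphic
#' data yield the conventional `He = 0`, `F_ST = 0`.
#'
#' @param x a [genotype_dataset()] containing exactly two species.
#' @return named numeric vector of length 16.
#' @export
summary_stat_vector <- function(x) {
  sp <- species_of_individual(x)
  species <- unique(sp)
  stopifnot(length(species) == 2)
  a1 <- x$alleles[, , 1, drop = TRUE]
  a2 <- x$alleles[, , 2, drop = TRUE]
  if (is.null(dim(a1))) { a1 <- matrix(a1, ncol = n_loci(x)); a2 <- matrix(a2, ncol = n_loci(x)) }
  summary_stats_cpp(a1, a2, as.integer(sp == species[2]))
}
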