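# Bayesian admixture clustering in the STRUCTURE mould: a Gibbs sampler on
# the no-linkage admixture model with independent Dirichlet allele-frequency
# priors, Evanno delta-K for choosing the cluster number, replicate
# alignment, and the Q-threshold introgression classification.

#' Gibbs sampler for the admixture model
#'
#' Latent per-allele-copy cluster assignments `Z` are sampled given the
#' cluster allele frequencies `P` and individual ancestries `Q`; `P` is then
#' drawn from its Dirichlet posterior given `Z` (prior `Dirichlet(lambda)`
#' per cluster x locus) and each `Q` row from `Dirichlet(alpha + counts)`.
#' The ancestry prior `alpha` is fixed (default `1/K`, uniform on the
#' simplex), not inferred. Missing alleles are skipped. Reported `Q` and `P`
#' are posterior means over post-burn-in sweeps.
#'
#' @param x a [genotype_dataset()].
#' @param K number of clusters.
#' @param chain_len total Gibbs sweeps (default 50000).
#' @param burn_in burn-in sweeps (default 20% of `chain_len`).
#' @param seed integer seed for the run (recorded in the result).
#' @param alpha Dirichlet ancestry prior (default `1/K`).
#' @param lambda Dirichlet allele-frequency prior.
#' @return an `admixture_run`: `Q` (individuals x K), `loglik` trace,
#'   `ln_pk` (model log-evidence estimate: mean minus half the variance of
#'   the trace), plus the run settings.
#' @export
gibbs_admixture <- function(x, K, chain_len = 50000L,
                            burn_in = as.integer(0.2 * chain_len),
                            seed = 1L, alpha = 1 / K, lambda = 1) {
  stopifnot(K >= 1)
  if (chain_len <= burn_in) stop("chain_len must exceed burn_in")
  code <- .code_alleles(x)
  n <- n_individuals(x); L <- n_loci(x)
  geno <- matrix(-1L, n, 2L * L)
  geno[, 2 * seq_len(L) - 1L] <- code$a1
  geno[, 2 * seq_len(L)] <- code$a2
  if (K > sum(code$n_alleles))
    warning("K exceeds total allele diversity; clusters cannot all be distinct")
  set.seed(seed)
  r <- gibbs_admixture_cpp(geno, code$n_alleles, as.integer(K),
                           as.integer(chain_len), as.integer(burn_in),
                           alpha, lambda)
  ll <- r$loglik[(burn_in + 1):chain_len]
  Q <- r$Q
  rownames(Q) <- x$individual_ids
  structure(list(Q = Q, P = r$P, loglik = r$loglik,
                 ln_pk = mean(ll) - stats::var(ll) / 2,
                 K = K, chain_len = chain_len, burn_in = burn_in,
                 seed = seed, alpha = alpha, lambda = lambda),
            class = "admixture_run")
}

#' Align replicate runs to a common cluster labelling
#'
#' Label switching across replicates is resolved greedily: for each run, the
#' cluster permutation maximising the summed correlation between its Q
#' columns and those of the first run is applied.
#'
#' @param runs list of `admixture_run` objects with equal `K`.
#' @return the list with every `Q` permuted into the first run's labelling;
#'   each run records its permutation as `$perm`.
#' @export
align_replicates <- function(runs) {
  stopifnot(length(runs) >= 1)
  K <- runs[[1]]$K
  stopifnot(all(vapply(runs, function(r) r$K, numeric(1)) == K))
  ref <- runs[[1]]$Q
  runs[[1]]$perm <- seq_len(K)
  if (length(runs) == 1 || K == 1) return(runs)
  for (j in seq_along(runs)[-1]) {
    Q <- runs[[j]]$Q
    perm <- integer(K)
    used <- logical(K)
    # greedy assignment by decreasing column correlation
    cors <- matrix(-Inf, K, K)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      cc <- suppressWarnings(stats::cor(ref[, a], Q[, b]))
      cors[a, b] <- if (is.na(cc)) -sum((ref[, a] - Q[, b])^2) else cc
    }
    for (step in seq_len(K)) {
      ij <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      perm[ij[1]] <- ij[2]
      cors[ij[1], ] <- -Inf
      cors[, ij[2]] <- -Inf
    }
    runs[[j]]$Q <- Q[, perm, drop = FALSE]
    runs[[j]]$perm <- perm
  }
  runs
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / SD(L(K))` from
#' per-replicate `ln P(X|K)` values over at least three consecutive K.
#'
#' @param ln_pk data frame or list with columns/elements `K` and `ln_pk`
#'   (one row per replicate), or a list of `admixture_run`s.
#' @return data frame per K: mean and SD of `ln P(X|K)`, `delta_k` (NA at
#'   the ends and where SD is 0, flagged via `note`).
#' @export
evanno_delta_k <- function(ln_pk) {
  if (is.list(ln_pk) && !is.data.frame(ln_pk) &&
      inherits(ln_pk[[1]], "admixture_run"))
    ln_pk <- data.frame(K = vapply(ln_pk, function(r) r$K, numeric(1)),
                        ln_pk = vapply(ln_pk, function(r) r$ln_pk, numeric(1)))
  agg_m <- tapply(ln_pk$ln_pk, ln_pk$K, mean)
  agg_s <- tapply(ln_pk$ln_pk, ln_pk$K, stats::sd)
  Ks <- as.integer(names(agg_m))
  if (length(Ks) < 3) stop("delta-K needs >= 3 consecutive K values")
  out <- data.frame(K = Ks, mean_ln_pk = as.numeric(agg_m),
                    sd_ln_pk = as.numeric(agg_s),
                    delta_k = NA_real_, note = "")
  for (i in seq_along(Ks)) {
    if (i == 1 || i == length(Ks)) next
    if (Ks[i - 1] != Ks[i] - 1L || Ks[i + 1] != Ks[i] + 1L) next
    s <- agg_s[i]
    if (is.na(s) || s == 0) { out$note[i] <- "sd=0; delta-K undefined"; next }
    out$delta_k[i] <- abs(agg_m[i + 1] - 2 * agg_m[i] + agg_m[i - 1]) / s
  }
  out
}

#' Classify individuals by foreign ancestry
#'
#' For a two-cluster aligned run, each individual's ancestry from the other
#' species' cluster (`Q_other`) is thresholded into `pure`
#' (`Q_other <= 0.05`), `introgressed` (`(0.05, 0.50]`), `hybrid`
#' (`(0.50, 0.90]`) and `misassigned` (`> 0.90`). The 0.05 introgression
#' threshold is the standard admixture-coefficient cutoff; the hybrid and
#' misassignment cutoffs are configurable.
#'
#' @param run an aligned K=2 `admixture_run` (or a 2-column Q matrix).
#' @param x the [genotype_dataset()] the run was fit on.
#' @param cluster_species character vector of length 2: the species each
#'   cluster column represents. Default assigns each cluster to the species
#'   with the highest mean ancestry in it.
#' @param thresholds increasing vector `c(pure_max, introgressed_max,
#'   hybrid_max)`.
#' @return data frame per individual: `id`, `population`, `host_species`,
#'   `q_other`, `class`.
#' @export
classify_introgression <- function(run, x, cluster_species = NULL,
                                   thresholds = c(0.05, 0.50, 0.90)) {
  Q <- if (inherits(run, "admixture_run")) run$Q else run
  if (ncol(Q) != 2) stop("introgression classification is defined for K = 2")
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  host <- species_of_individual(x)
  species <- unique(unname(x$species_of_pop))
  stopifnot(length(species) == 2)
  if (is.null(cluster_species)) {
    if (all(species %in% host)) {
      m1 <- c(mean(Q[host == species[1], 1]), mean(Q[host == species[2], 1]))
      cluster_species <- if (m1[1] >= m1[2]) species else rev(species)
    } else {
      cluster_species <- species
    }
  }
  own_col <- match(host, cluster_species)
  q_other <- Q[cbind(seq_len(nrow(Q)), 3L - own_col)]
  class <- cut(q_other, c(-Inf, thresholds, Inf),
               labels = c("pure", "introgressed", "hybrid", "misassigned"))
  data.frame(id = x$individual_ids, population = x$pop,
             host_species = host, q_other = q_other,
             class = as.character(class))
}

#' Share of introgressed individuals per species
#'
#' Individuals whose foreign ancestry exceeds the introgression threshold
#' but who are not misassigned (those are treated as field
#' misidentifications and removed from the denominator).
#'
#' @param calls output of [classify_introgression()].
#' @return data frame per species: `n_retained`, `n_introgressed`,
#'   `percent`.
#' @export
introgression_rate <- function(calls) {
  out <- lapply(split(calls, calls$host_species), function(d) {
    kept <- d[d$class != "misassigned", ]
    n_int <- sum(kept$class %in% c("introgressed", "hybrid"))
    data.frame(species = d$host_species[1], n_retained = nrow(kept),
               n_introgressed = n_int,
               percent = 100 * n_int / nrow(kept))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Geographic ranges of introgressed individuals
#'
#' Min-max altitude, longitude and latitude among individuals of each
#' non-pure class within each species, from the dataset's per-population
#' geography, plus per-population counts. Absence of introgressed
#' individuals yields empty ranges, not an error.
#'
#' @param calls output of [classify_introgression()].
#' @param geography per-population metadata table.
#' @param classes which classes to summarise.
#' @return list with `ranges` (data frame) and `pop_counts`.
#' @export
introgression_geography <- function(calls, geography,
                                    classes = c("introgressed", "hybrid")) {
  d <- calls[calls$class %in% classes, ]
  d <- merge(d, geography, by = "population")
  if (nrow(d) == 0)
    return(list(ranges = data.frame(), pop_counts = data.frame()))
  ranges <- do.call(rbind, lapply(split(d, d$host_species), function(s)
    data.frame(species = s$host_species[1], n = nrow(s),
               alt_min = min(s$altitude), alt_max = max(s$altitude),
               lon_min = min(s$longitude), lon_max = max(s$longitude),
               lat_min = min(s$latitude), lat_max = max(s$latitude))))
  rownames(ranges) <- NULL
  pc <- as.data.frame(table(population = d$population), stringsAsFactors = FALSE)
  names(pc)[2] <- "n_introgressed"
  list(ranges = ranges, pop_counts = pc)
}
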