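# GenAlEx-equivalent diversity and differentiation statistics. Conventions:
# expected heterozygosity is the uncorrected 1 - sum(p^2) on frequencies
# pooled over the requested scope; means over loci include loci that are
# monomorphic within a group as long as they are polymorphic in the dataset;
# negative variance components and pairwise F_ST estimates are truncated at 0.

.scope_groups <- function(x, scope = c("species", "population", "dataset")) {
  scope <- match.arg(scope)
  switch(scope,
         species = species_of_individual(x),
         population = x$pop,
         dataset = rep("all", n_individuals(x)))
}

.polymorphic_loci <- function(x) {
  vapply(seq_len(n_loci(x)), function(l) {
    v <- c(x$alleles[, l, 1], x$alleles[, l, 2])
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
}

.mean_se <- function(m) {
  # m: loci x groups matrix; column-wise mean and SE over loci (SD/sqrt(L))
  mean_ <- colMeans(m, na.rm = TRUE)
  se_ <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    stats::sd(v) / sqrt(length(v))
  })
  list(mean = mean_, se = se_)
}

#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygous individuals among non-missing
#' genotypes, within each group of the chosen scope, plus the mean and
#' standard error over loci. Loci monomorphic in the whole dataset are
#' excluded from the means; loci with no data in a group are flagged.
#'
#' @param x a [genotype_dataset()].
#' @param scope grouping for the statistic: `"species"` (default),
#'   `"population"`, or `"dataset"`.
#' @return list with `per_locus` (loci x groups matrix), `mean`, `se`, and
#'   `loci_used`.
#' @export
observed_heterozygosity <- function(x, scope = "species") {
  grp <- .scope_groups(x, scope)
  groups <- unique(grp)
  L <- n_loci(x)
  m <- matrix(NA_real_, L, length(groups),
              dimnames = list(x$locus_names, groups))
  for (g in groups) {
    idx <- grp == g
    a1 <- x$alleles[idx, , 1, drop = FALSE]
    a2 <- x$alleles[idx, , 2, drop = FALSE]
    ok <- !is.na(a1)
    het <- (a1 != a2) & ok
    m[, g] <- colSums(het, na.rm = TRUE) / pmax(colSums(ok), 1L)
    m[colSums(ok) == 0, g] <- NA_real_
  }
  poly <- .polymorphic_loci(x)
  if (any(!poly))
    message("excluding ", sum(!poly), " dataset-monomorphic loci from means")
  if (any(is.na(m[poly, , drop = FALSE])))
    message("some loci have no data in some groups; excluded from their means")
  s <- .mean_se(m[poly, , drop = FALSE])
  list(per_locus = m, mean = s$mean, se = s$se, loci_used = sum(poly))
}

#' Expected heterozygosity
#'
#' GenAlEx-style uncorrected expected heterozygosity
#' `He = 1 - sum(p_i^2)` from allele frequencies pooled over each group of
#' the chosen scope, per locus, plus the mean and SE over loci.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus`, `mean`, `se`, `loci_used`.
#' @export
expected_heterozygosity <- function(x, scope = "species") {
  grp <- .scope_groups(x, scope)
  groups <- unique(grp)
  L <- n_loci(x)
  m <- matrix(NA_real_, L, length(groups),
              dimnames = list(x$locus_names, groups))
  for (g in groups) {
    idx <- grp == g
    for (l in seq_len(L)) {
      v <- c(x$alleles[idx, l, 1], x$alleles[idx, l, 2])
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      p <- tabulate(factor(v)) / length(v)
      m[l, g] <- 1 - sum(p^2)
    }
  }
  poly <- .polymorphic_loci(x)
  s <- .mean_se(m[poly, , drop = FALSE])
  list(per_locus = m, mean = s$mean, se = s$se, loci_used = sum(poly))
}

#' Fixation index F = 1 - Ho/He
#'
#' Computed per locus from matching observed- and expected-heterozygosity
#' tables; loci with `He = 0` are undefined and excluded from the means.
#'
#' @param ho,he results of [observed_heterozygosity()] and
#'   [expected_heterozygosity()] on the same dataset and scope, or plain
#'   numeric vectors/matrices of matching shape.
#' @return list with `per_locus`, `mean`, `se`.
#' @export
fixation_index <- function(ho, he) {
  hom <- if (is.list(ho)) ho$per_locus else ho
  hem <- if (is.list(he)) he$per_locus else he
  f <- 1 - hom / hem
  f[!is.na(hem) & hem == 0] <- NA_real_
  if (is.null(dim(f))) f <- matrix(f, ncol = 1)
  s <- .mean_se(f)
  list(per_locus = f, mean = s$mean, se = s$se)
}

#' Private alleles per group
#'
#' An allele is private to a group (default: species) if it is observed in
#' that group and in no other. Also reports, for every population, the
#' private-allele frequency: the summed within-population frequency of
#' allele copies that are private to the population's species.
#'
#' @param x a [genotype_dataset()].
#' @param by grouping: `"species"` or `"population"`.
#' @return list with `counts` (named integer vector per group),
#'   `per_locus` (data frame of private alleles), and `pop_freq`
#'   (per-population private-allele frequency, when `by = "species"`).
#' @export
private_alleles <- function(x, by = "species") {
  grp <- .scope_groups(x, by)
  groups <- unique(grp)
  if (length(groups) < 2)
    stop("private alleles require at least 2 groups")
  L <- n_loci(x)
  rows <- list()
  for (l in seq_len(L)) {
    seen <- lapply(groups, function(g) {
      v <- c(x$alleles[grp == g, l, 1], x$alleles[grp == g, l, 2])
      unique(v[!is.na(v)])
    })
    names(seen) <- groups
    for (g in groups) {
      others <- unlist(seen[setdiff(groups, g)])
      priv <- setdiff(seen[[g]], others)
      if (length(priv) > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(locus = x$locus_names[l], group = g, allele = priv)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(locus = character(0), group = character(0),
                         allele = integer(0))
  counts <- stats::setNames(integer(length(groups)), groups)
  tt <- table(tab$group)
  counts[names(tt)] <- as.integer(tt)

  pop_freq <- NULL
  if (by == "species") {
    pops <- unique(x$pop)
    pf <- numeric(length(pops))
    for (j in seq_along(pops)) {
      idx <- x$pop == pops[j]
      sp <- x$species_of_pop[[pops[j]]]
      tot <- 0; prv <- 0
      for (l in seq_len(L)) {
        v <- c(x$alleles[idx, l, 1], x$alleles[idx, l, 2])
        v <- v[!is.na(v)]
        tot <- tot + length(v)
        pa <- tab$allele[tab$group == sp & tab$locus == x$locus_names[l]]
        prv <- prv + sum(v %in% pa)
      }
      pf[j] <- if (tot > 0) prv / tot else NA_real_
    }
    pop_freq <- data.frame(population = pops,
                           species = unname(x$species_of_pop[pops]),
                           private_freq = pf)
  }
  list(counts = counts, per_locus = tab, pop_freq = pop_freq)
}

.code_alleles <- function(x) {
  L <- n_loci(x)
  a1 <- matrix(-1L, n_individuals(x), L)
  a2 <- a1
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    v1 <- x$alleles[, l, 1]; v2 <- x$alleles[, l, 2]
    lev <- sort(unique(c(v1, v2)))
    lev <- lev[!is.na(lev)]
    n_alleles[l] <- max(length(lev), 1L)
    c1 <- match(v1, lev) - 1L; c2 <- match(v2, lev) - 1L
    c1[is.na(c1)] <- -1L; c2[is.na(c2)] <- -1L
    a1[, l] <- c1; a2[, l] <- c2
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles)
}

#' Hierarchical AMOVA with permutation tests
#'
#' Analysis of molecular variance on allele-identity distances (F_ST-type,
#' the GenAlEx codominant default), with allele copies as units grouped by
#' population and populations nested in species. Variance components are
#' computed per locus (locus-wise complete data) and summed over loci.
#' Permutation p-values: Phi_ST permutes individuals among populations,
#' Phi_SC permutes individuals among populations within species, Phi_CT
#' permutes whole populations among species; `p = (#{perm >= obs}+1)/(N+1)`.
#'
#' @param x a [genotype_dataset()].
#' @param hierarchy `"species/population"` (3-level) or `"population"`
#'   (2-level, species ignored).
#' @param n_perm number of permutations (default 9999).
#' @return list of class `amova_result` with the source-of-variation table,
#'   Phi statistics and p-values.
#' @export
amova <- function(x, hierarchy = "species/population", n_perm = 9999) {
  code <- .code_alleles(x)
  pops <- unique(x$pop)
  pop_idx <- match(x$pop, pops) - 1L
  if (hierarchy == "species/population") {
    sp <- unique(unname(x$species_of_pop[pops]))
    if (length(sp) < 2) stop("3-level AMOVA needs >= 2 species")
    grp <- match(unname(x$species_of_pop[pops]), sp) - 1L
  } else if (hierarchy == "population") {
    grp <- rep(0L, length(pops))
  } else stop("unknown hierarchy: ", hierarchy)

  res <- amova_cpp(code$a1, code$a2, pop_idx, as.integer(grp),
                   code$n_alleles, as.integer(n_perm))
  three <- hierarchy == "species/population"
  va <- max(res$va, 0); vb <- max(res$vb, 0); vc <- max(res$vc, 0)
  if (res$va < 0 || res$vb < 0)
    message("negative variance component truncated to 0")
  tot <- va + vb + vc
  n_cop <- sum(!is.na(x$alleles[, , 1])) + sum(!is.na(x$alleles[, , 2]))
  # design df (from the full design, units = allele copies)
  N <- 2L * n_individuals(x); P <- length(pops)
  G <- if (three) length(unique(unname(x$species_of_pop[pops]))) else 1L
  p_st <- (res$ge_st + 1) / (n_perm + 1)
  p_sc <- (res$ge_sc + 1) / (n_perm + 1)
  p_ct <- if (three) (res$ge_ct + 1) / (n_perm + 1) else NA_real_
  if (three) {
    tab <- data.frame(
      source = c("among species", "among populations within species",
                 "within populations", "total"),
      df = c(G - 1L, P - G, N - P, N - 1L),
      SS = c(res$ssd_ag, res$ssd_ap, res$ssd_wp,
             res$ssd_ag + res$ssd_ap + res$ssd_wp),
      var_comp = c(va, vb, vc, tot),
      pct = 100 * c(va, vb, vc, tot) / tot)
  } else {
    tab <- data.frame(
      source = c("among populations", "within populations", "total"),
      df = c(P - 1L, N - P, N - 1L),
      SS = c(res$ssd_ap, res$ssd_wp, res$ssd_ap + res$ssd_wp),
      var_comp = c(vb, vc, tot),
      pct = 100 * c(vb, vc, tot) / tot)
  }
  structure(list(table = tab,
                 phi = c(phi_ct = if (three) res$phi_ct else NA_real_,
                         phi_sc = if (three) res$phi_sc else NA_real_,
                         phi_st = res$phi_st),
                 p = c(p_ct = p_ct, p_sc = p_sc, p_st = p_st),
                 n_perm = n_perm, hierarchy = hierarchy),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$hierarchy, "), ", x$n_perm, " permutations\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  phi <- x$phi[!is.na(x$phi)]
  p <- x$p[paste0("p_", sub("phi_", "", names(phi)))]
  for (i in seq_along(phi))
    cat(sprintf("  %s = %.3f (p = %.2g)\n", names(phi)[i], phi[i], p[i]))
  invisible(x)
}

#' Pairwise F_ST matrix among populations
#'
#' Two-level AMOVA-based F_ST (allele-identity distance) for every pair of
#' populations; negative estimates are truncated at 0. Also reports the mean
#' pairwise F_ST within each species and a Mann-Whitney U comparison of the
#' two sets of within-species pairwise values.
#'
#' @param x a [genotype_dataset()].
#' @param min_n minimum individuals per population; smaller populations are
#'   skipped with a warning.
#' @return list with `fst` (symmetric matrix), `within_species_mean`,
#'   and `species_test` (Mann-Whitney comparison, if 2 species).
#' @export
pairwise_fst <- function(x, min_n = 2) {
  tab <- table(x$pop)
  small <- names(tab)[tab < min_n]
  if (length(small) > 0) {
    warning("skipping populations with < ", min_n, " individuals: ",
            paste(small, collapse = ", "))
    x <- subset_individuals(x, !(x$pop %in% small))
  }
  code <- .code_alleles(x)
  pops <- unique(x$pop)
  pop_idx <- match(x$pop, pops) - 1L
  m <- pairwise_fst_cpp(code$a1, code$a2, pop_idx, length(pops),
                        code$n_alleles)
  dimnames(m) <- list(pops, pops)
  n_neg <- sum(m[upper.tri(m)] < 0, na.rm = TRUE)
  if (n_neg > 0)
    message(n_neg, " negative pairwise F_ST estimates truncated to 0")
  m[m < 0] <- 0
  sp <- unname(x$species_of_pop[pops])
  species <- unique(sp)
  wmeans <- stats::setNames(numeric(length(species)), species)
  wvals <- list()
  for (s in species) {
    sub <- m[sp == s, sp == s, drop = FALSE]
    v <- sub[upper.tri(sub)]
    wvals[[s]] <- v
    wmeans[s] <- mean(v, na.rm = TRUE)
  }
  test <- NULL
  if (length(species) == 2 &&
      length(wvals[[1]]) > 0 && length(wvals[[2]]) > 0)
    test <- mann_whitney_u(wvals[[1]], wvals[[2]])
  list(fst = m, within_species_mean = wmeans, species_test = test)
}

#' Regressions of private-allele frequency on geography
#'
#' Ordinary least squares of per-population private-allele frequency on one
#' geographic predictor at a time (altitude, longitude, latitude), fit
#' separately within each species, with a two-sided t-test on the slope.
#'
#' @param pop_freq data frame with columns `population`, `species`,
#'   `private_freq` (as from [private_alleles()]).
#' @param geography per-population metadata with `population`, `latitude`,
#'   `longitude`, `altitude`.
#' @param predictors which predictors to test.
#' @return data frame with one row per species x predictor: slope, t, p, n.
#' @export
geography_regression <- function(pop_freq, geography,
                                 predictors = c("altitude", "longitude",
                                                "latitude")) {
  geo_cols <- geography[, c("population", intersect(predictors,
                                                    names(geography)))]
  d <- merge(pop_freq, geo_cols, by = "population")
  out <- list()
  for (s in unique(d$species)) {
    ds <- d[d$species == s, ]
    if (nrow(ds) < 3) stop("need >= 3 populations per species for regression")
    for (pr in predictors) {
      xv <- ds[[pr]]
      if (stats::var(xv) == 0) stop("zero-variance predictor: ", pr)
      if (stats::var(ds$private_freq) == 0) {
        # constant response: the slope is exactly zero, not 0/0
        out[[length(out) + 1L]] <- data.frame(
          species = s, predictor = pr, slope = 0, t = 0, p = 1, n = nrow(ds))
        next
      }
      fit <- stats::lm(ds$private_freq ~ xv)
      cf <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        species = s, predictor = pr,
        slope = cf[2, 1], t = cf[2, 3], p = cf[2, 4], n = nrow(ds))
    }
  }
  do.call(rbind, out)
}

#' Per-species diversity summary table
#'
#' Sample sizes, allele counts, private alleles, and mean +/- SE (over loci)
#' of Ho, He and F for each species, in the layout of a standard SSR
#' diversity report.
#'
#' @param x a [genotype_dataset()] with two or more species.
#' @return data frame, one column block per species.
#' @export
diversity_table <- function(x) {
  sp <- species_of_individual(x)
  ho <- observed_heterozygosity(x, scope = "species")
  he <- expected_heterozygosity(x, scope = "species")
  f <- fixation_index(ho, he)
  pa <- private_alleles(x, by = "species")
  species <- unique(sp)
  n_all <- vapply(species, function(s) {
    sum(vapply(seq_len(n_loci(x)), function(l) {
      v <- c(x$alleles[sp == s, l, 1], x$alleles[sp == s, l, 2])
      length(unique(v[!is.na(v)]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(
    species = species,
    n = as.integer(table(sp)[species]),
    n_alleles = as.integer(n_all),
    private_alleles = as.integer(pa$counts[species]),
    Ho = ho$mean[species], Ho_se = ho$se[species],
    He = he$mean[species], He_se = he$se[species],
    F = f$mean[species], F_se = f$se[species],
    row.names = NULL)
}
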