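# Naive, double-loop reference implementations used as independent oracles,
# plus small dataset builders. These deliberately share no code with the
# package's optimized paths.

# build a dataset from a matrix of strings "a/b" ("./." = missing)
toy_dataset <- function(geno, pop, species_of_pop = NULL, ids = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  arr <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    parts <- strsplit(geno[i, l], "/")[[1]]
    if (parts[1] != ".") {
      arr[i, l, 1] <- as.integer(parts[1])
      arr[i, l, 2] <- as.integer(parts[2])
    }
  }
  genotype_dataset(arr, individual_ids = ids, pop = pop,
                   species_of_pop = species_of_pop)
}

random_dataset <- function(n = 8, L = 3, n_pop = 2, n_species = 1,
                           alleles = c(10L, 12L, 14L, 16L),
                           missing_rate = 0.1) {
  arr <- array(sample(alleles, n * L * 2, replace = TRUE), dim = c(n, L, 2))
  if (missing_rate > 0) {
    mask <- matrix(runif(n * L) < missing_rate, n, L)
    arr[, , 1][mask] <- NA_integer_
    arr[, , 2][mask] <- NA_integer_
  }
  pops <- paste0("p", sort(rep_len(seq_len(n_pop), n)))  # contiguous blocks
  sp <- stats::setNames(paste0("s", rep_len(seq_len(n_species), n_pop)),
                        paste0("p", seq_len(n_pop)))
  genotype_dataset(arr, pop = pops, species_of_pop = sp)
}

# observed heterozygosity per locus within one group of individuals
oracle_ho <- function(x, idx) {
  vapply(seq_len(n_loci(x)), function(l) {
    num <- 0; den <- 0
    for (i in idx) {
      a <- x$alleles[i, l, 1]; b <- x$alleles[i, l, 2]
      if (is.na(a)) next
      den <- den + 1
      if (a != b) num <- num + 1
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}

# uncorrected expected heterozygosity per locus, pooled over a group
oracle_he <- function(x, idx) {
  vapply(seq_len(n_loci(x)), function(l) {
    v <- c(x$alleles[idx, l, 1], x$alleles[idx, l, 2])
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    1 - sum((table(v) / length(v))^2)
  }, numeric(1))
}

# private-allele counts per group by exhaustive set comparison
oracle_private_counts <- function(x, grp) {
  groups <- unique(grp)
  counts <- stats::setNames(integer(length(groups)), groups)
  for (l in seq_len(n_loci(x))) {
    seen <- lapply(groups, function(g) {
      v <- c(x$alleles[grp == g, l, 1], x$alleles[grp == g, l, 2])
      unique(v[!is.na(v)])
    })
    names(seen) <- groups
    for (g in groups) {
      others <- unique(unlist(seen[setdiff(groups, g)]))
      counts[g] <- counts[g] + length(setdiff(seen[[g]], others))
    }
  }
  counts
}

# AMOVA sums of squares from explicit pairwise mismatch distances among
# allele copies, locus by locus (pairwise-complete), summed over loci
oracle_amova_ss <- function(x, pop, grp_of_pop) {
  L <- n_loci(x)
  ss_t <- 0; ss_wp <- 0; ss_wg <- 0
  for (l in seq_len(L)) {
    copies <- c(x$alleles[, l, 1], x$alleles[, l, 2])
    cpop <- rep(pop, 2)
    cgrp <- grp_of_pop[cpop]
    ok <- !is.na(copies)
    copies <- copies[ok]; cpop <- cpop[ok]; cgrp <- cgrp[ok]
    N <- length(copies)
    if (N < 2) next
    d <- outer(copies, copies, FUN = function(a, b) as.numeric(a != b))
    ss_t <- ss_t + sum(d[upper.tri(d)]) / N
    for (p in unique(cpop)) {
      idx <- which(cpop == p)
      if (length(idx) < 2) next
      dp <- d[idx, idx, drop = FALSE]
      ss_wp <- ss_wp + sum(dp[upper.tri(dp)]) / length(idx)
    }
    for (g in unique(cgrp)) {
      idx <- which(cgrp == g)
      if (length(idx) < 2) next
      dg <- d[idx, idx, drop = FALSE]
      ss_wg <- ss_wg + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  list(total = ss_t, within_pop = ss_wp,
       among_pop_within_grp = ss_wg - ss_wp,
       among_grp = ss_t - ss_wg)
}

# naive summary-statistic vector on a two-species dataset
oracle_summary_stats <- function(x) {
  sp <- species_of_individual(x)
  species <- unique(sp)
  L <- n_loci(x)
  per_species <- function(s) {
    idx <- which(sp == s)
    he <- c(); ho <- c(); ka <- c(); va <- c(); mr <- c()
    for (l in seq_len(L)) {
      v <- c(x$alleles[idx, l, 1], x$alleles[idx, l, 2])
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      p <- table(v) / length(v)
      he <- c(he, 1 - sum(p^2))
      ka <- c(ka, length(p))
      va <- c(va, mean(v^2) - mean(v)^2)
      mr <- c(mr, length(p) / (max(v) - min(v) + 1))
      hh <- oracle_ho(x, idx)[l]
      ho <- c(ho, hh)
    }
    c(mean(he), mean(ho), mean(ka), mean(va), mean(mr))
  }
  s1 <- per_species(species[1]); s2 <- per_species(species[2])
  ht <- 0; hs <- 0; dmu2 <- c(); shared_n <- 0; union_n <- 0
  priv <- c(0, 0); copies <- c(0, 0)
  for (l in seq_len(L)) {
    v1 <- c(x$alleles[sp == species[1], l, 1], x$alleles[sp == species[1], l, 2])
    v2 <- c(x$alleles[sp == species[2], l, 1], x$alleles[sp == species[2], l, 2])
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    copies <- copies + c(length(v1), length(v2))
    if (length(v1) == 0 || length(v2) == 0) next
    pool <- c(v1, v2)
    ht <- ht + 1 - sum((table(pool) / length(pool))^2)
    hs <- hs + ((1 - sum((table(v1) / length(v1))^2)) +
                (1 - sum((table(v2) / length(v2))^2))) / 2
    dmu2 <- c(dmu2, (mean(v1) - mean(v2))^2)
    u <- union(v1, v2)
    union_n <- union_n + length(u)
    shared_n <- shared_n + length(intersect(v1, v2))
    priv <- priv + c(length(setdiff(v1, v2)), length(setdiff(v2, v1)))
  }
  out <- c(s1, s2,
           if (ht > 0) (ht - hs) / ht else 0,
           mean(dmu2), shared_n / union_n,
           100 * priv / copies)
  names(out) <- c("he_a", "ho_a", "ka_a", "va_a", "mr_a",
                  "he_b", "ho_b", "kb_b", "vb_b", "mr_b",
                  "fst", "dmu2", "shared", "priv_a", "priv_b")
  out
}

# exact two-sided Mann-Whitney p-value by enumeration of all assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  u_obs <- u_of(a, b)
  n <- ncol(idx)
  us <- vapply(seq_len(n), function(j) {
    sel <- idx[, j]
    u_of(pooled[sel], pooled[-sel])
  }, numeric(1))
  mu <- n1 * (length(b)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force weighted quantile (linear scan)
oracle_wquantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cum <- 0
  for (i in seq_along(x)) {
    cum <- cum + w[i]
    if (cum >= p) return(x[i])
  }
  x[length(x)]
}
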