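# Seeded synthetic fixtures with the statistical structure of the two-maple
# study design: two species with strong between-species differentiation,
# Balding-Nichols population scatter within species, species-private allele
# pools (altitude-enriched in species A), inbreeding, a small set of
# introgressed / hybrid / misassigned individuals with known true ancestry,
# and a configurable missing-data rate. Fixtures are frequency-model draws
# (fast and targetable); the coalescent simulator is the mechanistic
# generator used for ABC.

#' Study-scale template for the synthetic generator
#'
#' Defaults mirror the two-species study design the package emulates:
#' 371 individuals of species "cau" in 20 populations and 286 of "mor" in
#' 19; 17 loci; between-species AMOVA Phi_CT 0.478; within-species pairwise
#' F_ST 0.144 / 0.106; species-pooled expected heterozygosity 0.341 / 0.261
#' and observed heterozygosity 0.169 / 0.180 (the gap sets the inbreeding
#' level); 61 / 21 species-private alleles with the private pool of "cau"
#' enriched along altitude; 9 introgressed individuals in "cau" (restricted
#' to the highest-altitude populations) and 14 introgressed + 1 hybrid + 5
#' misassigned in "mor"; 2% missing genotypes.
#'
#' @param n_pop,n_ind individuals and populations per species.
#' @param n_loci number of loci.
#' @param phi_ct target between-species Phi_CT.
#' @param fst within-species pairwise F_ST targets.
#' @param he,ho species-pooled expected/observed heterozygosity targets.
#' @param private_alleles species-private allele counts.
#' @param n_introgressed,n_hybrid,n_misassigned class counts per species.
#' @param q_ranges true foreign-ancestry ranges per class.
#' @param altitude_effect relative amplitude of the altitude enrichment of
#'   species A's private-allele weight (0 = none).
#' @param missing_rate per-genotype missing probability.
#' @return a `study_template` list.
#' @export
study_template <- function(n_pop = c(cau = 20L, mor = 19L),
                           n_ind = c(cau = 371L, mor = 286L),
                           n_loci = 17L,
                           phi_ct = 0.478,
                           fst = c(cau = 0.144, mor = 0.106),
                           he = c(cau = 0.341, mor = 0.261),
                           ho = c(cau = 0.169, mor = 0.180),
                           private_alleles = c(cau = 61L, mor = 21L),
                           n_introgressed = c(cau = 9L, mor = 14L),
                           n_hybrid = c(cau = 0L, mor = 1L),
                           n_misassigned = c(cau = 0L, mor = 5L),
                           q_ranges = list(introgressed = c(0.06, 0.45),
                                           hybrid = c(0.55, 0.85),
                                           misassigned = c(0.92, 0.998)),
                           altitude_effect = 0.8,
                           missing_rate = 0.02) {
  stopifnot(phi_ct > 0, phi_ct < 1, all(fst > 0 & fst < 1),
            all(he > 0 & he < 1), all(ho >= 0), all(ho <= he),
            missing_rate >= 0, missing_rate < 1)
  structure(list(species = c("cau", "mor"), n_pop = n_pop, n_ind = n_ind,
                 n_loci = n_loci, phi_ct = phi_ct, fst = fst,
                 he = he, ho = ho, private_alleles = private_alleles,
                 n_introgressed = n_introgressed, n_hybrid = n_hybrid,
                 n_misassigned = n_misassigned, q_ranges = q_ranges,
                 altitude_effect = altitude_effect,
                 missing_rate = missing_rate),
            class = "study_template")
}

#' Small template for fast test suites
#'
#' Same structure as [study_template()] at a fraction of the size: 3
#' populations x 12 individuals per species, no missing data by default.
#'
#' @param ... overrides passed to [study_template()].
#' @export
mini_template <- function(...) {
  args <- list(n_pop = c(cau = 3L, mor = 3L),
               n_ind = c(cau = 36L, mor = 36L),
               n_introgressed = c(cau = 2L, mor = 2L),
               n_hybrid = c(cau = 0L, mor = 1L),
               n_misassigned = c(cau = 0L, mor = 1L),
               missing_rate = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(study_template, args)
}

.geo_profile <- function(k, r) {
  w <- r^(seq_len(k) - 1)
  w / sum(w)
}

# distribute m items over L cells as evenly as possible
.spread <- function(m, L) {
  base <- m %/% L
  extra <- m %% L
  counts <- rep(base, L)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}
#' Build the calibrated allele-frequency model for a template
#'
#' Constructs, per locus, a pool of five shared alleles, two "divergence"
#' alleles (carrying the between-species divergence in species B), and the
#' species-private pools, then calibrates the model against the template
#' targets using closed-form expected allele-identity probabilities:
#' a per-locus geometric concentration parameter is solved against the
#' species-pooled expected-heterozygosity targets, the fraction of divergent
#' loci against the target Phi_CT, the Balding-Nichols Dirichlet
#' concentration against the within-species pairwise F_ST targets, and the
#' inbreeding level against the observed-heterozygosity targets. The
#' expected dilution from the template's admixed individuals (who draw
#' foreign copies from the other species) is folded into all four
#' calibrations. Every shared/divergence allele keeps a floor frequency in
#' both species so that none of them turns spuriously private in a draw.
#'
#' Population frequencies are later drawn Dirichlet around the species base
#' with concentration `(1 - F_ST)/F_ST`; the private-allele weight is
#' deterministic per population and scales with altitude in species A.
#'
#' @param template a [study_template()].
#' @return a `frequency_model` list: per-species base frequency vectors per
#'   locus, allele size labels, Dirichlet concentrations, inbreeding
#'   levels, and the achieved analytic targets.
#' @export
generate_frequency_model <- function(template) {
  tp <- template
  L <- tp$n_loci
  n_shared <- 5L
  n_div <- 2L
  k_priv_c <- .spread(tp$private_alleles[["cau"]], L)
  k_priv_m <- .spread(tp$private_alleles[["mor"]], L)
  floor_f <- 0.008   # minimum base frequency of every shared/divergence allele
  per_priv <- 0.011  # species-base frequency of each private allele
  # contiguous allele sizes per locus (adjacent repeat scores, as in real
  # SSR data; a gappy ladder would distort range-based statistics)
  sizes <- lapply(seq_len(L), function(l) {
    base <- 100L + 40L * l
    kc <- max(k_priv_c[l], 1L)
    list(shared = base + seq_len(n_shared),
         div = base + n_shared + seq_len(n_div),
         priv_c = base + n_shared + n_div + seq_len(kc),
         priv_m = base + n_shared + n_div + kc + seq_len(max(k_priv_m[l], 1)))
  })
  # per-locus He targets spread around the species means (for realism)
  spread <- seq(-0.11, 0.11, length.out = L)
  he_targets <- list(
    cau = local({
      h <- pmin(pmax(tp$he[["cau"]] + spread, 0.16), 0.75)
      h - mean(h) + tp$he[["cau"]]
    }),
    mor = local({
      h <- pmin(pmax(tp$he[["mor"]] + rev(spread), 0.16), 0.70)
      h - mean(h) + tp$he[["mor"]]
    }))

  # expected foreign-copy fraction per species from the admixture design
  qmid <- vapply(tp$q_ranges, mean, numeric(1))
  qbar <- stats::setNames(numeric(2), tp$species)
  adm_frac <- qbar
  for (sp in tp$species) {
    cnt <- c(tp$n_introgressed[[sp]], tp$n_hybrid[[sp]], tp$n_misassigned[[sp]])
    qbar[sp] <- sum(cnt * qmid[c("introgressed", "hybrid", "misassigned")]) /
      tp$n_ind[[sp]]
    adm_frac[sp] <- sum(cnt) / tp$n_ind[[sp]]
  }

  # full base-frequency vector over the locus pool
  # layout: 1..5 shared, 6..7 divergence, then cau privates, then mor privates
  # For species A (`cau`), mu_l is the extra loading it places on the first
  # divergence allele (the continuous between-species contact dial); for
  # species B (`mor`), mu_l in {0,1} switches the locus between the shared
  # profile and the divergence alleles.
  vec_for <- function(sp, l, r, mu_l) {
    kpc <- k_priv_c[l]; kpm <- k_priv_m[l]
    npos <- 7L + max(kpc, 1L) + max(kpm, 1L)
    v <- numeric(npos)
    kp <- if (sp == "cau") kpc else kpm
    w_np <- 1 - kp * per_priv
    loading <- if (sp == "cau") c((1 - mu_l) * .geo_profile(n_shared, r),
                                  mu_l, 0)
               else c((1 - mu_l) * .geo_profile(n_shared, r),
                      mu_l * .geo_profile(n_div, r))
    v[1:7] <- floor_f + loading * (w_np - 7 * floor_f)
    if (sp == "cau" && kpc > 0) v[7L + seq_len(kpc)] <- per_priv
    if (sp == "mor" && kpm > 0) v[7L + max(kpc, 1L) + seq_len(kpm)] <- per_priv
    v
  }
  donor_of <- function(v, l) {  # other-species profile seen by admixed hosts
    d <- v
    d[-(1:7)] <- 0
    d / sum(d)
  }
  solve_r <- function(sp, l, mu_l, he_target, qb = 0, d = NULL) {
    f <- function(r) {
      v <- vec_for(sp, l, r, mu_l)
      eff <- if (qb > 0) (1 - qb) * v + qb * d else v
      (1 - sum(eff^2)) - he_target
    }
    if (f(1e-4) >= 0) return(1e-4)
    if (f(1) <= 0) return(1)
    stats::uniroot(f, c(1e-4, 1), tol = 1e-10)$root
  }
  build <- function(v_load) {
    # v_load in [0,1]: divergent loci fill one by one; the boundary locus
    # stays fully divergent in species B while species A keeps a decaying
    # share of its first divergence allele, so the He solve stays feasible
    x <- v_load * L
    n_full <- floor(x)
    partial <- x - n_full
    mu_m <- as.numeric(seq_len(L) <= n_full + (partial > 1e-9))
    mu_c <- numeric(L)
    if (partial > 1e-9 && n_full < L)
      mu_c[n_full + 1L] <- (1 - partial) * 0.45
    # pass 1: plain solve (defines the donor profiles)
    cau1 <- lapply(seq_len(L), function(l)
      vec_for("cau", l, solve_r("cau", l, mu_c[l], he_targets$cau[l]),
              mu_c[l]))
    mor1 <- lapply(seq_len(L), function(l)
      vec_for("mor", l, solve_r("mor", l, mu_m[l], he_targets$mor[l], 0),
              mu_m[l]))
    # pass 2: re-solve the concentration with the admixture dilution in
    cau <- lapply(seq_len(L), function(l)
      vec_for("cau", l,
              solve_r("cau", l, mu_c[l], he_targets$cau[l], qbar[["cau"]],
                      donor_of(mor1[[l]], l)), mu_c[l]))
    mor <- lapply(seq_len(L), function(l)
      vec_for("mor", l,
              solve_r("mor", l, mu_m[l], he_targets$mor[l], qbar[["mor"]],
                      donor_of(cau1[[l]], l)), mu_m[l]))
    list(cau = cau, mor = mor, mu = mu_m)
  }
  eff_of <- function(mod, l) {
    fc <- (1 - qbar[["cau"]]) * mod$cau[[l]] +
      qbar[["cau"]] * donor_of(mod$mor[[l]], l)
    fm <- (1 - qbar[["mor"]]) * mod$mor[[l]] +
      qbar[["mor"]] * donor_of(mod$cau[[l]], l)
    list(fc = fc, fm = fm)
  }
  phi_ct_of <- function(mod) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      e <- eff_of(mod, l)
      jb <- sum(e$fc * e$fm)
      js <- (sum(e$fc^2) + sum(e$fm^2)) / 2
      num <- num + (js - jb)
      den <- den + (1 - jb)
    }
    num / den
  }
  f <- function(v_load) phi_ct_of(build(v_load)) - tp$phi_ct
  if (f(0) > 0 || f(1) < 0)
    stop("target Phi_CT unattainable; attainable range approximately [",
         round(phi_ct_of(build(0)), 3), ", ", round(phi_ct_of(build(1)), 3),
         "]")
  v_load <- stats::uniroot(f, c(0, 1), tol = 1e-5)$root
  mod <- build(v_load)

  # Dirichlet concentration: solve the expected pairwise F_ST (with the
  # admixture dilution) for fst0, then theta = (1 - fst0)/fst0
  theta <- stats::setNames(numeric(2), tp$species)
  he_w_own <- stats::setNames(numeric(2), tp$species)  # within-pop He, own part
  for (sp in tp$species) {
    other <- setdiff(tp$species, sp)
    qb <- qbar[[sp]]
    pair_fst <- function(fst0) {
      # only the "common" shared alleles (base >= 0.02) scatter across
      # populations; rare floor alleles and privates are deterministic
      num <- 0; den <- 0
      for (l in seq_len(L)) {
        b <- mod[[sp]][[l]]
        d <- donor_of(mod[[other]][[l]], l)
        common <- which(b[1:7] >= 0.02)
        w_c <- sum(b[common])
        np <- b[common] / w_c
        js_own <- sum(b^2)
        jw_own <- js_own + w_c^2 * fst0 * (1 - sum(np^2))
        cross <- 2 * qb * (1 - qb) * sum(b * d) + qb^2 * sum(d^2)
        jw <- (1 - qb)^2 * jw_own + cross
        js <- (1 - qb)^2 * js_own + cross
        num <- num + (jw - js)
        den <- den + (1 - js)
      }
      num / den
    }
    g <- function(fst0) pair_fst(fst0) - tp$fst[[sp]]
    if (g(0.9) < 0) stop("target F_ST unattainable for ", sp)
    fst0 <- stats::uniroot(g, c(1e-4, 0.9), tol = 1e-8)$root
    theta[sp] <- (1 - fst0) / fst0
    hw <- 0
    for (l in seq_len(L)) {
      b <- mod[[sp]][[l]]
      common <- which(b[1:7] >= 0.02)
      w_c <- sum(b[common])
      np <- b[common] / w_c
      jw_own <- sum(b^2) + w_c^2 * fst0 * (1 - sum(np^2))
      hw <- hw + (1 - jw_own)
    }
    he_w_own[sp] <- hw / L
  }

  # inbreeding: solve (1 - f) from the Ho target, accounting for the extra
  # heterozygosity the admixed individuals contribute
  inb <- stats::setNames(numeric(2), tp$species)
  for (sp in tp$species) {
    other <- setdiff(tp$species, sp)
    adm_ho <- 0
    for (cls in c("introgressed", "hybrid", "misassigned")) {
      ncls <- switch(cls, introgressed = tp$n_introgressed[[sp]],
                     hybrid = tp$n_hybrid[[sp]],
                     misassigned = tp$n_misassigned[[sp]])
      if (ncls == 0) next
      q <- qmid[[cls]]
      he_cls <- mean(vapply(seq_len(L), function(l) {
        mix <- (1 - q) * mod[[sp]][[l]] + q * donor_of(mod[[other]][[l]], l)
        1 - sum(mix^2)
      }, numeric(1)))
      adm_ho <- adm_ho + ncls / tp$n_ind[[sp]] * he_cls
    }
    target_pure <- (tp$ho[[sp]] - adm_ho) / (1 - adm_frac[[sp]])
    inb[sp] <- max(0, min(0.95, 1 - target_pure / he_w_own[[sp]]))
  }
  structure(list(template = tp, sizes = sizes, base = mod, theta = theta,
                 inbreeding = inb, divergence_loading = v_load,
                 analytic_phi_ct = phi_ct_of(mod)),
            class = "frequency_model")
}

.make_geography <- function(tp) {
  pops_c <- sprintf("cau_p%02d", seq_len(tp$n_pop[["cau"]]))
  pops_m <- sprintf("mor_p%02d", seq_len(tp$n_pop[["mor"]]))
  # altitudes are assigned in a fixed scrambled order so that altitude is
  # not collinear with the latitude/longitude transects (the private-allele
  # enrichment should track altitude only)
  scramble <- function(k) order((seq_len(k) * 7L) %% k, seq_len(k))
  alt_c <- round(seq(300, 2400, length.out = length(pops_c)))
  alt_m <- round(seq(1400, 2700, length.out = length(pops_m)))
  data.frame(
    population = c(pops_c, pops_m),
    species = rep(c("cau", "mor"), c(length(pops_c), length(pops_m))),
    latitude = round(c(seq(22.6, 24.6, length.out = length(pops_c)),
                       seq(23.2, 24.7, length.out = length(pops_m))), 3),
    longitude = round(c(seq(120.7, 121.4, length.out = length(pops_c)),
                        seq(120.8, 121.5, length.out = length(pops_m))), 3),
    altitude = c(alt_c[scramble(length(pops_c))],
                 alt_m[scramble(length(pops_m))]))
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }
  g / sum(g)
}

#' Draw a full synthetic dataset (plus truth table) from a template
#'
#' Builds (or reuses) the calibrated frequency model, draws per-population
#' allele frequencies, then genotypes with the template's inbreeding level;
#' designated individuals are drawn as mixtures with known true foreign
#' ancestry (introgressed individuals of species A sit in its
#' highest-altitude populations), and genotypes are masked at the missing
#' rate. Uses R's global RNG; `set.seed()` makes the draw reproducible.
#'
#' @param template a [study_template()].
#' @param freq_model optional pre-built [generate_frequency_model()].
#' @return a [genotype_dataset()] with geography attached; the truth table
#'   (id, population, species, class, true `q_other`, altitude) is in
#'   attribute `"truth"`, the frequency model in `"freq_model"`.
#' @export
generate_dataset <- function(template, freq_model = NULL) {
  tp <- template
  fm <- if (is.null(freq_model)) generate_frequency_model(tp) else freq_model
  geo <- .make_geography(tp)
  L <- tp$n_loci
  geo$alt_mult <- 1
  idx_c <- geo$species == "cau"
  if (tp$altitude_effect > 0) {
    a <- geo$altitude[idx_c]
    g <- 1 + tp$altitude_effect * (a - mean(a)) / (max(a) - min(a))
    geo$alt_mult[idx_c] <- g / mean(g)
  }

  # per-population frequency vectors over the locus's full allele pool
  pop_freqs <- list()
  pool_sizes <- lapply(seq_len(L), function(l) {
    s <- fm$sizes[[l]]
    c(s$shared, s$div, s$priv_c, s$priv_m)
  })
  for (p in seq_len(nrow(geo))) {
    sp <- geo$species[p]
    other <- setdiff(tp$species, sp)
    pf <- vector("list", L)
    for (l in seq_len(L)) {
      b <- fm$base[[sp]][[l]]
      priv_idx <- which(b > 0 & seq_along(b) > 7)
      w_priv <- min(sum(b[priv_idx]) * geo$alt_mult[p], 0.5)
      rare7 <- which(b[1:7] < 0.02)
      common7 <- setdiff(1:7, rare7)
      np <- b[common7] / sum(b[common7])
      shared_draw <- .rdirichlet1(fm$theta[[sp]] * np)
      f <- numeric(length(pool_sizes[[l]]))
      f[rare7] <- b[rare7]              # rare alleles: no population scatter
      f[common7] <- (1 - w_priv - sum(b[rare7])) * shared_draw
      if (length(priv_idx) > 0)
        f[priv_idx] <- w_priv / length(priv_idx)
      pf[[l]] <- f / sum(f)
    }
    pop_freqs[[geo$population[p]]] <- pf
  }
  # species-level mean frequencies for foreign-ancestry draws; donor private
  # pools are zeroed so foreign copies never leak private alleles across the
  # species boundary (keeps observed private counts at the calibrated level)
  species_freq <- lapply(tp$species, function(sp) {
    pops <- geo$population[geo$species == sp]
    lapply(seq_len(L), function(l) {
      f <- Reduce(`+`, lapply(pops, function(p) pop_freqs[[p]][[l]])) /
        length(pops)
      f[-seq_len(7)] <- 0   # shared + divergence positions only
      f / sum(f)
    })
  })
  names(species_freq) <- tp$species

  # assign individuals to populations (near-even split)
  assign_pop <- function(sp) {
    pops <- geo$population[geo$species == sp]
    rep(pops, .spread(tp$n_ind[[sp]], length(pops)))
  }
  pop_of <- c(assign_pop("cau"), assign_pop("mor"))
  sp_of <- rep(tp$species, tp$n_ind[tp$species])
  n <- length(pop_of)
  ids <- sprintf("%s_i%03d", sp_of, unlist(lapply(tp$n_ind[tp$species], seq_len)))

  # designate admixture classes with true foreign ancestry
  class <- rep("pure", n)
  q_other <- numeric(n)
  for (sp in tp$species) {
    idx <- which(sp_of == sp)
    picks <- integer(0)
    if (sp == "cau" && tp$n_introgressed[[sp]] > 0) {
      # restrict introgression to the highest-altitude populations
      alt <- geo$altitude[match(pop_of[idx], geo$population)]
      ord <- idx[order(-alt)]
      top <- ord[seq_len(min(length(ord), 4 * tp$n_introgressed[[sp]]))]
      picks <- sample(top, tp$n_introgressed[[sp]])
    } else if (tp$n_introgressed[[sp]] > 0) {
      picks <- sample(idx, tp$n_introgressed[[sp]])
    }
    class[picks] <- "introgressed"
    q_other[picks] <- stats::runif(length(picks), tp$q_ranges$introgressed[1],
                                   tp$q_ranges$introgressed[2])
    rest <- setdiff(idx, picks)
    if (tp$n_hybrid[[sp]] > 0) {
      hy <- sample(rest, tp$n_hybrid[[sp]])
      class[hy] <- "hybrid"
      q_other[hy] <- stats::runif(length(hy), tp$q_ranges$hybrid[1],
                                  tp$q_ranges$hybrid[2])
      rest <- setdiff(rest, hy)
    }
    if (tp$n_misassigned[[sp]] > 0) {
      ms <- sample(rest, tp$n_misassigned[[sp]])
      class[ms] <- "misassigned"
      q_other[ms] <- stats::runif(length(ms), tp$q_ranges$misassigned[1],
                                  tp$q_ranges$misassigned[2])
    }
  }

  arr <- array(NA_integer_, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    sp <- sp_of[i]
    other <- setdiff(tp$species, sp)
    own <- pop_freqs[[pop_of[i]]]
    f_inb <- fm$inbreeding[[sp]]
    for (l in seq_len(L)) {
      pool <- pool_sizes[[l]]
      draw_copy <- function() {
        if (stats::runif(1) < q_other[i])
          sample(pool, 1, prob = species_freq[[other]][[l]])
        else sample(pool, 1, prob = own[[l]])
      }
      a1 <- draw_copy()
      a2 <- if (q_other[i] == 0 && stats::runif(1) < f_inb) a1 else draw_copy()
      arr[i, l, ] <- c(a1, a2)
    }
  }
  if (tp$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < tp$missing_rate, n, L)
    for (s in 1:2) arr[, , s][mask] <- NA_integer_
  }
  ds <- genotype_dataset(
    arr, individual_ids = ids, locus_names = sprintf("locus_%02d", seq_len(L)),
    pop = pop_of,
    species_of_pop = stats::setNames(geo$species, geo$population),
    geography = geo[, c("population", "species", "latitude", "longitude",
                        "altitude")])
  attr(ds, "truth") <- data.frame(
    id = ids, population = pop_of, species = sp_of, class = class,
    q_other = q_other,
    altitude = geo$altitude[match(pop_of, geo$population)])
  attr(ds, "freq_model") <- fm
  ds
}

#' Pseudo-observed summary statistics from a scenario
#'
#' One [simulate_dataset()] + [summary_stat_vector()] call packaged as an
#' "observed" vector for ABC validation.
#'
#' @param spec a [scenario_spec()].
#' @return named numeric statistic vector with the generating spec attached
#'   as attribute `"scenario"`.
#' @export
generate_observed_stats <- function(spec) {
  s <- summary_stat_vector(simulate_dataset(spec))
  attr(s, "scenario") <- spec
  s
}
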