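---
title: "Inferring introgression and demographic change from microsatellites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring introgression and demographic change from microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdemog)
```

`ssrdemog` implements a complete inference chain for a classic question in
plant phylogeography: when two closely related, parapatric species share
alleles, is that admixture recent introgression or retained ancestral
polymorphism, and how did gene flow interact with demographic change? The
package was built around a two-species system of island maples (*Acer
caudatifolium*, "cau", and *A. morrisonense*, "mor") genotyped at 17 EST-SSR
loci, but every component is parameterised and reusable.

The chain has five stages, mirrored by the scripts in `analysis/`:

1. genotype I/O and validation (GenePop, STRUCTURE, metadata CSV);
2. diversity and differentiation statistics (Ho, He, F, private alleles,
   AMOVA with permutation tests, pairwise F~ST~, geography regressions);
3. Bayesian admixture clustering with Evanno ΔK and a Q-threshold
   introgression classification;
4. approximate Bayesian computation (ABC) over four
   divergence-with-gene-flow scenarios, with posterior model probabilities,
   Bayes factors, a goodness-of-fit check, and regression-adjusted weighted
   posteriors for nine demographic parameters;
5. a scenario contrast of the population-decline amplitude
   Ne~t1~/Ne~t2~.

## Diversity statistics and their conventions

Expected heterozygosity is the uncorrected gene diversity
$H_e = 1 - \sum_i p_i^2$ computed from allele frequencies pooled over the
requested scope (`species`, `population`, or `dataset`); no small-sample
(Nei) correction is applied, matching the GenAlEx convention the original
study reported. Means over loci include loci that are monomorphic within a
group as long as they segregate in the dataset, and the standard error is
$\mathrm{SD}/\sqrt{L}$ over loci. The fixation index is $F = 1 - H_o/H_e$
per locus, undefined (and excluded) where $H_e = 0$.

A *private allele* is an allele observed in exactly one group. The
per-population private-allele frequency — the response variable of the
geography regressions — is the summed within-population frequency of allele
copies private to the population's species. The paper this design follows
did not define the quantity explicitly; the definition above is the one
that makes the altitude regression well-posed, and it is computed by
`private_alleles()` alongside the raw counts.

AMOVA uses allele-identity (F~ST~-type) distances with allele copies as
units, populations nested in species: sums of squares reduce to allele
counts per group, variance components follow the standard three-level
moment equations with unbalanced-design coefficients, and components are
computed per locus (pairwise-complete with respect to missing data) and
summed. Negative components and negative pairwise F~ST~ estimates are
truncated at zero, with a message. Permutation tests follow the usual
scheme — Φ~ST~ permutes individuals among populations, Φ~SC~ within
species, Φ~CT~ permutes whole populations among species — with
$p = (\#\{perm \ge obs\} + 1)/(N + 1)$ and $N = 9999$ by default. An
R~ST~-style squared-size distance is deliberately not used for acceptance
because codominant AMOVA defaults in the field are identity-based.

## The admixture model

`gibbs_admixture()` is a Gibbs sampler on the no-linkage admixture model:
cluster allele frequencies $P$ carry independent Dirichlet($\lambda = 1$)
priors per cluster × locus, individual ancestries $Q$ a symmetric
Dirichlet($\alpha$). Each sweep samples the latent cluster of every allele
copy given $(P, Q)$, then $P$ and $Q$ from their conjugate posteriors.
Reported values are posterior means over post-burn-in sweeps (20% burn-in
by default). Two simplifications relative to full STRUCTURE are
intentional and documented: $\alpha$ is fixed (default $1/K$) rather than
sampled, and the correlated-allele-frequency prior is omitted. The model
evidence proxy $\ln P(X\,|\,K)$ is the STRUCTURE-style
mean-minus-half-variance of the log-likelihood trace, feeding Evanno's
$\Delta K$.

One consequence matters for interpretation: a posterior *mean* under a
fixed symmetric prior cannot reach the simplex corner, so a perfectly pure
individual at 17 loci plateaus near $Q \approx 0.985$ with $\alpha = 0.5$,
and weak foreign ancestry (a few percent) is systematically over-called.
Recovery of the *amount* of admixture is good (mean absolute error of
$\hat Q$ about 0.04 on separable data); the binary Q > 0.05 introgression
call on near-pure individuals is conservative in the other direction.
Headline introgression percentages in the acceptance workflow are
therefore computed by applying the classification rule to known ancestries,
while sampler accuracy is measured separately as an error. A smaller
$\alpha$ sharpens the boundary behaviour and is exposed as a parameter.

Classification thresholds on the foreign-ancestry coefficient
$Q_{other}$: pure $\le 0.05$ < introgressed $\le 0.5$ < hybrid $\le 0.9$ <
misassigned. The 0.05 boundary is the standard admixture-coefficient
cutoff; 0.5 and 0.9 formalise the narrative distinction between F1-like
hybrids and field misidentifications and are configurable. Misassigned
individuals are removed from the denominator when percentages are
reported (the "281 of 286" convention).

## The coalescent simulator

`simulate_locus()` draws a two-deme structured-coalescent genealogy with
three epochs: recent sizes (Ne~cau,t2~, Ne~mor,t2~) on $(0, t_2)$, older
sizes on $(t_2, t_1)$, and a single ancestral deme (Ne~anc~) beyond $t_1$.
The four scenarios differ only in the migration window: SI never, AM on
$(t_2, t_1)$, SC on $(0, t_2)$, CM on $(0, t_1)$. Rates follow the
backward lineage-movement convention: $m_1$, the forward rate from cau
into mor, moves mor-resident lineages into cau backward in time, matching
the convention of standard coalescent simulators. Time is continuous, in
generations; conversion to years is a separate step (default 5 yr/gen,
reflecting a tree that needs about five years to mature and flower, so
that e.g. 18,870 generations ≈ 94 kyr).

Mutation is strict stepwise (SMM): Poisson numbers of ±1-repeat steps on
each branch, ancestral state 20 repeats, states clipped at a floor of 2
repeats (clip events are counted and returned). The simulator is validated
against two closed forms: the panmictic pairwise coalescence time
$2N_e$, and the Ohta–Kimura SMM equilibrium
$H_e = 1 - 1/\sqrt{1 + 8 N_e \mu}$ (within 0.02 at $N_e = 1000$,
$\mu = 5\times10^{-4}$, 2000 loci).

The per-dataset summary-statistic vector holds, per species, the mean
over loci of {He, Ho, allele count, allele-size variance, M-ratio}, and
jointly the between-species F~ST~, mean squared difference in mean allele
size (δμ²), shared-allele proportion, and private-allele counts per 100
copies. A redundant "fraction private" component was removed because it
is exactly one minus the shared proportion.

## The ABC engine

Priors default to log-uniform effective sizes on $[10^2, 10^6]$, uniform
$t_1$ on $[10^3, 10^5]$ generations with $t_2 \sim U(0, t_1)$ (so the
order constraint holds by construction), log-uniform migration rates on
$[10^{-6}, 10^{-2}]$ (zero under SI), and a fixed mutation rate
$5\times10^{-4}$ — the study's own prior table is not public, so nothing
downstream depends on matching it. Statistics are standardised by the
median and MAD of the reference table (zero-MAD columns dropped);
rejection keeps the `n_keep` = 2000 simulations closest in Euclidean
distance. Model choice defaults to a weighted multinomial logistic
regression of the model label on the standardised statistics evaluated at
the observed vector (Epanechnikov weights on distance); retained-set
frequencies ("rejection") and a single-hidden-layer network are
alternatives. Posterior probabilities are clipped to $[10^{-4}, 1]$ and
renormalised before Bayes factors, so a model absent from the retained
set yields a bounded, not infinite, Bayes factor.

Parameter posteriors use the standard regression adjustment:
local-linear regression of each (log-transformed, if strictly positive)
parameter on the standardised statistics under Epanechnikov weights, with
exactly collinear columns given zero coefficients; summaries are the
weighted-KDE marginal mode and weighted 2.5%/97.5% percentiles, i.e. the
"mode / weighted percentile" convention of ABC parameter tables. When the
prior bounds of a parameter are supplied, the adjustment runs on the logit
of the prior range instead, which keeps adjusted draws inside the prior
support — the safeguard that matters when the observation lies at the edge
of the simulated cloud, as it does whenever the generative model is an
imperfect description of the data (for example, observed heterozygosity
deficits that a coalescent without inbreeding cannot reproduce). The
goodness-of-fit p-value is the marginal-distance formulation:
the share of the model's own simulations lying farther from the
statistic-cloud centre than the observation; it is uniform under the null
by construction (verified by simulation).

Closed-loop validation at desk scale uses a reference table of
$2\times10^4$ simulations of 17 loci and 20+20 diploids under a scaled
prior ($N_e \le 10^5$): pseudo-observed data from a strong-migration
secondary-contact draw select SC over SI in ≥70% of seeds (in practice
20/20), and 95% weighted intervals cover generating log-Ne values in
well over 85% of replicates. These problem sizes are the package's
validation defaults; real analyses should scale `n_sim` up toward
$10^6$.

## The decline contrast

`decline_ratios()` forms the posterior of $Ne_{t1}/Ne_{t2}$ per species
from the regression-adjusted retained draws, with ABC weights propagated
and non-positive draws excluded (counted). `compare_scenarios()` rank-tests
two such posteriors (e.g. secondary contact vs strict isolation) with a
tie-corrected Mann–Whitney U (exact for small untied samples). The draws
being compared are correlated retained simulations, not independent
observations — the comparison is implemented as published practice, and
every report carries that caveat explicitly.

## The synthetic-data generator

Fixtures are frequency-model draws, not coalescent runs: that separation
lets statistic correctness be tested independently of model fit. The
study-scale template reproduces the published design — 371 + 286
individuals, 20 + 19 populations, 17 loci — and its measured genetic
profile: species-pooled He 0.341/0.261, Ho 0.169/0.180 (the gap sets an
inbreeding level used when drawing genotypes), 61/21 species-private
alleles, between-species Φ~CT~ 0.478, within-species pairwise F~ST~
0.144/0.106, 2% missing data, 9 introgressed individuals confined to the
highest-altitude populations of species A and 14 introgressed + 1 hybrid +
5 misassigned in species B.

Calibration is analytic, by expected allele-identity probabilities: per
locus, five shared alleles, two "divergence" alleles and the private pools
get geometric weight profiles whose concentration is root-solved against
the He targets; the number of mor-divergent loci (with a continuous
boundary dial on cau's share of the first divergence allele) is
root-solved against Φ~CT~; the Balding–Nichols Dirichlet concentration
against pairwise F~ST~; and the inbreeding coefficient against Ho. The
expected dilution caused by the admixed individuals — who draw foreign
copies from the other species' non-private profile — is folded into all
four calibrations. Two deliberate artificialities: rare (floor) alleles
are given deterministic rather than Dirichlet-scattered population
frequencies so that none of them turns spuriously private in a draw, and
foreign copies never carry donor private alleles, keeping the observed
private-allele counts at their calibrated values. Across replicate draws
the realised statistics centre on the targets with spreads of roughly
±0.01 (Ho), ±0.013 (He), ±1 allele (private counts), ±0.014 (Φ~CT~ and
mean F~ST~).

What passing tests on these fixtures does and does not show: it shows the
statistics, the admixture sampler and the ABC engine recover the structure
they were pointed at, under a generative model whose assumptions (Dirichlet
population scatter, no linkage, no null alleles, no genotyping error,
missingness completely at random) are cleaner than real SSR data. It does
not certify behaviour under null-allele artifacts, allele-size binning
error, or isolation-by-distance within species, none of which the
generator emulates.

## Numerical choices and degenerate inputs

* Ties in rejection distance break by row order (stable sort); rejection
  is otherwise permutation-invariant, which is tested.
* Monomorphic data: He = 0, F~ST~ = 0 by convention, flagged; F undefined
  where He = 0; ΔK undefined where the replicate SD is 0.
* All-missing loci are excluded from means with a message; genotypes are
  never half-called (a missing allele masks its whole locus genotype).
* A constant regression response returns slope 0, t 0 exactly rather than
  a 0/0 ratio.
* The pipeline (`run_pipeline()`) derives one seed per stage from the
  master seed, caches stage outputs keyed by a hash of their inputs and
  settings, and embeds the config snapshot in every report.

## Known limitations

* The admixture sampler's fixed-$\alpha$ posterior mean biases weak
  ancestry upward (discussed above).
* AMOVA degrees of freedom follow the textbook design; published tables
  assembled from other software can differ when populations were merged
  or dropped upstream.
* The ABC engine's accuracy statements hold at the validation scale used
  here; posterior concentration on real data requires far larger
  reference tables.
* Recombination, selection, more than two demes, and sequence mutation
  models are out of scope by design.
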