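---
title: "Tracking heterosis in a Line x Tester panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking heterosis in a Line x Tester panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lxtmap)
```

# The problem

Hybrid breeding in upland cotton (*Gossypium hirsutum*) exploits
heterosis: the superiority of an F1 hybrid over a parental reference for
yield and fiber-quality traits.  A Line x Tester (LxT) mating design —
many female lines each crossed to a small set of elite male testers —
lets a breeding program measure heterosis at scale and decompose hybrid
performance into general combining ability (GCA, a parental main effect)
and specific combining ability (SCA, a cross-specific interaction).
When the same panel is fingerprinted with multi-band dominant markers
(silver-stained SSR fragments scored 1/0 per band), marker-trait
association mapping can be run not only on trait phenotypes but on GCA,
SCA and the heterosis statistics themselves, turning heterosis into a
mappable dependent variable (hQTLs).

`lxtmap` implements that whole chain as composable R functions: typed
I/O for band matrices and multi-environment phenotypes, descriptive and
RCBD statistics, the LxT decomposition, five heterosis statistics,
admixture-model clustering with Evanno delta-K, linkage disequilibrium
(LD) with permutation tests and logarithmic decay fitting, a Q+K mixed
linear model scan orchestrated over the 32 genotype/phenotype
combinations an LxT design supports, stable-QTL consensus calling and
favorable-allele mining.  A synthetic-data module generates LxT
populations with known QTL architecture, so every stage is testable
against a ground truth.

# Data model

* **Band matrix** — individuals x bands, entries 1/0/NA.  A multi-band
  SSR contributes one column per band (`NAU2631-1`, `NAU2631-2`, ...);
  bands are treated as independent dominant markers.  Two on-disk
  dialects differ only in the missing token: `-9` (STRUCTURE style) and
  `?` (TASSEL style).
* **Marker map** — one row per band: marker, chromosome (1-26 for
  allotetraploid cotton; A subgenome = 1-13, D = 14-26), position in bp,
  band id.  Inter-marker distance is `|pos_i - pos_j|` bp, reported in
  kb/Mb where conventional.
* **Phenotype table** — long records (individual, trait, location, year,
  replicate, value) over the ten traits PH, BW, LP, BN, FL, FS, MIC, FU,
  FE, FUI.
* **LxT design** — lines, testers, the cross-to-F1 map, and two check
  cultivars (K3, K4) used for standard heterosis.

# The synthetic-data generator

`sim_config()` defaults encode the study conditions the package targets:
284 lines x 5 testers, 203 multi-band SSRs (2-6 bands each) spread over
26 chromosomes, and trials in 10 locations x 2 years with 3 replicates
in a randomized complete block design.  Latent structure is simulated by
a correlated-frequency model: each band has an ancestral frequency
`u ~ U(0.1, 0.9)`, and each of the `n_subpops` subpopulations draws its
frequency from `Beta(u(1-F)/F, (1-u)(1-F)/F)` with drift `F = 0.15` by
default — a moderate differentiation typical of cultivated germplasm
groups.  Lines are assigned to subpopulations in equal blocks; testers
are drawn from the ancestral pool, mirroring elite cultivars of mixed
provenance.

F1 genotypes use dominant band union: a band is present in the F1 iff
either parent shows it, missing only when both parents are missing.
True heterozygosity is tracked only through the parents' carrier states.

Genetic values use a minimal additive/dominance coding per causal band
(the first band of a causal marker): parents and checks contribute `2a`
if they carry the band, `0` otherwise; an F1 contributes `2a` when both
parents carry it, `a + d` when exactly one does, `0` when neither.
This makes line GCA respond to `a` and mid-parent heterosis respond to
`d`, which is exactly the contrast the association machinery must
recover.  Phenotype records add a location-year effect (drawn once per
environment and shared across genotypes, matching RCBD assumptions), a
block effect within environment, and i.i.d. residual noise.  The trait
genetic architecture of a real cotton panel is unknown; simulated effect
sizes are free parameters of the experiment, not estimates of any
population.

What the generator does **not** emulate: linkage between markers (no
recombination model — parents are fixed inbreds and only F1s are
produced), genotype x environment interaction beyond additive
environment shifts, spatial field trends, and genotyping error.  Tests
that pass on this generator therefore validate the statistical
machinery, not robustness to those real-data features.

# Combining ability and heterosis

With balanced cross means `x_ij`, `combining_ability()` computes

```
g_i = xbar_i. - mu,   g_j = xbar_.j - mu,
s_ij = x_ij - xbar_i. - xbar_.j + mu
```

so that `mu + g_i + g_j + s_ij` reconstructs every cross mean exactly
and all `g` and `s` sum to zero — identities the tests assert to 1e-8.
The plot-level ANOVA partitions crosses into lines, testers and
line x tester strata (replications = location-year-replicate blocks).
Variance components follow the classical LxT expectations:
`sigma2_sca = (MS_lxt - MS_error)/r`, per-parent-type GCA components
from half-sib covariances `(MS_lines - MS_lxt)/(rt)` and
`(MS_testers - MS_lxt)/(rl)`, and a combined
`sigma2_gca = ((MS_lines + MS_testers)/2 - MS_lxt) / (r(l+t)/2)`.
The combined scaling constant is one of several in use in the
literature; the per-parent-type components are reported alongside so
nothing hinges on that choice.  Negative estimates are clamped to zero
with a warning.

The five heterosis statistics use the textbook forms (the field's
standard references give several variants; these are fixed here and
configurable by direction table):

* MP = 100 (F1 - MPv)/MPv with MPv the mid-parent value,
* HB = 100 (F1 - BP)/BP with BP the better parent *in the trait's
  desired direction* (micronaire is the one lower-is-better trait),
* HI = 100 F1/MPv,
* K3, K4 = 100 (F1 - check)/check.

Standard heterosis is environment-matched when replicated data are
available: the F1-vs-check ratio is formed per location-year against
that environment's check mean, then averaged — avoiding confounding by
G x E in the check.  With entry means only, overall means are used.

# Entry means and phenotype statistics

Association phenotypes default to shrunken entry means: per trait the
raw genotype mean is shrunk toward the grand mean with weight
`sigma2_g/(sigma2_g + sigma2_res/r_i)` using method-of-moments variance
components — a BLUP-style adjustment that is exact when residual
variance is zero and demonstrably lowers MSE against simulated truth.
Summaries use type-7 quartiles and n-1 SDs; PCA operates on the trait
correlation matrix with the sign convention that each component's
largest-magnitude loading is positive; RCBD ANOVA uses the exact
sums-of-squares partition (verified against `aov`).

# Population structure

`admixture_mcmc()` is a Gibbs sampler for the admixture model on binary
band data, treating each individual's band row as haploid observations
(one allele draw per band).  A diploid dominant-marker likelihood cannot
be reconstructed from single-row 0/1 coding, so the haploid treatment is
the honest model for this encoding.  The sampler alternates ancestry
assignments `z`, band frequencies `p` under a correlated-frequency prior
(Beta around the sample frequency with drift `F = 0.05`), and admixture
proportions `q ~ Dirichlet(alpha = 1)`.  `LnP(D)` is estimated as
`mean(lnL) - var(lnL)/2` over post-burn-in sweeps — the estimator whose
differences Evanno's delta-K consumes.  Default lengths follow the
field's convention of 100,000/100,000 sweeps; the package's own analyses
and tests use short presets (hundreds of sweeps), which the clean
simulated structure of the test panels justifies empirically.  `evanno()`
computes `deltaK(K) = |L''(K)| / SD_runs(LnPD(K))` and selects the
argmax, falling back to the smallest K with a warning when no peak
exists; `assign_subpops()` applies the strict `Q > 0.5` rule, labelling
everything else admixed.  Tests compare memberships up to label
permutation, since component labels are not identifiable.

# Linkage disequilibrium

Band-pair LD uses the haploid 2x2 table: `D = p_AB - p_A p_B`,
`r2 = D^2/(p_A(1-p_A) p_B(1-p_B))`, `D' = |D|/D_max`.  Locus-level r2
and D' are weighted averages over the locus pair's band pairs, weights
proportional to products of marginal band frequencies (the common
multi-allelic convention).  Rare bands (frequency < 0.05, strict) are
masked to missing first.  Permutation significance shuffles one locus's
individual labels: `p = (1 + #{r2_perm >= r2_obs})/(S + 1)`, with 1000
shuffles the field default.  Pairs with fewer than 4 complete
individuals are skipped rather than imputed — a permutation p below that
is meaningless.  The background LD level is the 99th percentile of r2
over unlinked (different-chromosome) pairs.  Decay is fitted as
`r2 = a + b ln(d)` over linked pairs with `p < 0.001`, zero distances
replaced by 1e-7 before the log; the decay distance solves the fitted
curve against `r2 = 0.2`.  When the intercept sits below the threshold
the entire observed range is sub-threshold and the decay distance is
reported NA rather than extrapolated below one distance unit.

# Q+K association mapping

Kinship is simple-matching similarity over non-missing band calls,
min-rescaled so the least-related observed pair anchors 0, with unit
diagonal and a 1e-6 ridge if the matrix is not PSD.  This estimator is
chosen because dominant band data carry no diplotypes for an
IBD-calibrated kinship; it is the package's documented, swappable
default.

The mixed model `y = Xb + u + e`, `u ~ N(0, sigma2_g K)`,
`e ~ N(0, sigma2_e I)` is fitted by REML: K is eigendecomposed once and
the profiled REML criterion is optimized over
`lambda = sigma2_e/sigma2_g` on a log scale in [1e-5, 1e5].  Band tests
then hold the variance components fixed across markers (the P3D
shortcut, standard for this model family and orders of magnitude
faster): in the whitened coordinates each band's F-test comes from the
reduction in generalized residual sum of squares, with `r2` reported as
that reduction as a fraction of the covariate-only generalized RSS.
With `K = I` and no covariates the scan reduces exactly to the OLS
F-test — the oracle the tests check to 1e-6.  Missing band calls are
mean-imputed per band for the scan (the standard GWAS-software device;
complete-case testing would require refitting variance components per
band).  Q covariates enter as K-1 membership columns (last dropped
against the intercept).

The 32 genotype/phenotype combinations are enumerated from the design:
11 trait-phenotype combinations (maternal-line genotypes against each
tester's F1 phenotypes, each F1 set against itself, parents against
themselves), 6 GCA (parents, plus each F1 set where a cross carries its
maternal line's GCA), 5 SCA (each F1 set against its crosses' SCA), and
10 heterosis (maternal and F1-set genotypes against the five metrics,
each metric a separate scan).  Records carry the tester attribution
needed downstream.

# Stable QTLs and favorable alleles

Records pass the strict `-log10(p) > 3` filter (`alpha = 0.001`).  A
(trait, marker) pair is a **stable QTL** when supported in combinations
attributable to at least 3 distinct testers.  The supporting-variable
whitelist defaults to all eight variables (phenotype, GCA, SCA, HB, HI,
MP, K3, K4); a five-variable preset (phenotype, GCA, HB, MP, K4) is
provided because published practice varies on whether SCA/HI/K3 count —
both behaviors are reproducible.  Effect typing reads the support set:
GCA implies additive gene action, any of SCA/HB/HI/MP/K3/K4 implies
dominance, both implies "both"; trait-phenotype-only support cannot
separate the two and is typed "both" with a low-confidence flag.  Note
that in an LxT design a pure-dominance locus still shifts average F1
performance and hence GCA, so a GCA scan *can* legitimately detect it;
the typing rule is a classification of evidence channels, not a
biological partition.  Pleiotropy = stable for >= 2 traits; subgenome
tallies split chromosomes at 13/14 (A/D).

The allele effect of band *i* for a trait is

```
a_i = mean(phenotype | carriers of band i) - mean(phenotype | all)
```

computed within each record's own genotype/phenotype combination (the
per-combination choice matters because the same band can have different
carrier sets in different F1 panels).  An allele is favorable when the
sign of `a_i` matches the trait's desired direction; per-trait maxima
and minima and per-tester favorable counts are reported.

# Numerical choices and problem sizes

* All randomness flows through per-stage seeds derived from one master
  seed; every generator and sampler is deterministic under its seed.
* Negative variance-component estimates are clamped to zero and logged;
  zero denominators in heterosis yield NA with a warning; monomorphic
  bands are skipped, not imputed.
* The packaged tests and the acceptance script run at desk scale, chosen
  as the smallest sizes at which the stochastic properties are stable:
  up to 200 lines x 5 testers, 60-150 markers, structure panels of 120
  individuals with 30 diagnostic bands per subpopulation pair and
  MCMC presets of 150/300 sweeps, LD permutation tests with 199-1000
  shuffles, and >= 5000 band tests for the type-I-error check.

# Known limitations

* The haploid treatment of dominant bands underestimates heterozygote
  information; with codominant data a diploid likelihood would be
  preferable throughout.
* The LxT variance-component scaling constants vary across textbooks;
  per-parent-type components are reported to make the choice auditable.
* The decay model `r2 = a + b ln(d)` is a descriptive trend, not a
  population-genetic expectation (e.g. Hill-Weir); it is used because it
  is what the fitted-threshold decay-distance convention assumes.
* Headline counts from any real panel (numbers of associations, stable
  markers, favorable alleles, decay distances) are dataset-dependent;
  the package reproduces procedures and their verifiable properties,
  not those numbers.
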