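---
title: "Disentangling layered admixture from paired mito-nuclear sequence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling layered admixture from paired mito-nuclear sequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonuclear)
library(dplyr)
```

## The analysis problem

Pest populations that went through repeated episodes of isolation,
hybridization and human-mediated transport carry several *layers* of
admixture. A single marker cannot resolve them: the mitochondrial genome
(haploid, maternally inherited) has a much smaller effective size than the
nuclear genome — one third in haplodiploid arthropods (diploid females,
haploid males: `2*N_f + N_m` nuclear gene copies against `N_f`
mitochondrial ones), one quarter in diplodiploids — so it sorts lineages
faster and reflects *recent* events, while nuclear sequences retain an
*older* picture. Reading the two markers jointly, per isolate (a random
sample of individuals representative of one population: a farm building, a
wild bird colony), lets one distinguish:

* **hybrid swarms** — populations composed entirely of admixed descendants
  of two or more formerly isolated lineages (every diploid individual
  carries alleles of several lineages);
* **motley populations** — very recent secondary contact, with unadmixed
  individuals of divergent origins side by side and almost no admixed
  individuals;
* **founder expansions** — star-like haplotype clouds left by small founder
  groups that later grew.

`mitonuclear` implements the full analysis chain for one haploid
mitochondrial fragment (COI-like, 543 bp by default) and one diploid
nuclear fragment with indel series (tropomyosin-intron-like, 729 aligned
columns), plus a structured-coalescent simulator that generates exactly
this kind of data with known truth, so every stage of the chain is testable
without access to any particular empirical dataset.

## Data model and gap conventions

An `aligned_dataset` stores one locus: per individual, one (haploid) or two
(diploid, both alleles resolved) aligned residue strings over
`A,C,G,T,-,N`, with per-individual metadata (isolate, habitat, geography).
Alignment columns are 1-based; `N` is always missing data; ambiguity codes
other than `N` are rejected because the analysis operates on resolved
alleles. The two allele strings of an individual are an unordered pair —
no gametic phase across loci is assumed or used.

Two gap conventions run through the package, mirroring the two dataset
variants this analysis family reports:

* `ignore_gap_columns` — columns containing a gap anywhere in the dataset
  are removed before comparison (complete deletion, the DnaSP-style "gaps
  unconsidered" convention). Removal is dataset-wide, not per pair, so
  haplotype identity stays transitive.
* `fifth_state` — the gap is an ordinary fifth character state.

Diversity statistics feeding the genetic-profile classifier are computed
with `ignore_gap_columns`: the classifier's diversity windows correspond to
printed values produced under that convention, and scoring each multi-column
indel series as dozens of per-column differences would roughly double
nuclear diversity. Clustering matrices default to `fifth_state` (indels do
carry ancestry signal there), and the indel series additionally enter as 8
binary presence/absence loci via `encode_indel_series()`.

## Diversity and demography statistics

`diversity_summary()` returns per-unit segregating sites `S`, haplotype
count `h`, haplotype diversity `Hd = n/(n-1) (1 - sum p_i^2)`, per-site
nucleotide diversity `pi` (Nei's unbiased estimator, equal to the average
proportion of differing sites over all unordered sequence pairs) and
Tajima's D (the classical constants; `NA`, never 0, when `S = 0`). With
complete data `pi` is computed by the equivalent column-frequency formula
for speed; any missing data falls back to pairwise deletion over pairs.

`mismatch_distribution()` counts pairwise differences over sequence pairs
(not collapsed haplotypes, so haplotype frequencies weight the
distribution). `fit_sudden_expansion()` fits Li's transient solution for a
population jumping from mutation-scaled size `theta0` to `theta1` at
mutational time `tau = 2ut`:

`F_j = F^eq_j(theta1) + exp(-tau (theta1+1)/theta1) * sum_{i<=j}
tau^(j-i)/(j-i)! * (F^eq_i(theta0) - F^eq_i(theta1))`,

with `F^eq_j(theta) = theta^j/(1+theta)^(j+1)`, by least squares on the
normalized frequencies. Numerical choices: parameters are optimised on log
(and logit for `theta1`) scale by deterministic multi-start Nelder-Mead;
`theta1` is capped at `1e5` (an effectively infinite post-expansion size)
because the surface is a ridge in `(theta1, tau)`; a degenerate
distribution (all mass in one class) is fitted with `tau` at that class and
a warning. Goodness of fit (`mismatch_gof()`) uses a parametric bootstrap
(default `B = 200`): coalescent samples of the same size are drawn under
the fitted history (pairwise coalescence rate `2/theta(t)` in mutational
time, mutation rate 1 per lineage), refitted with a lighter two-start
search, and `P` is the fraction of simulated statistics at least as large
as the observed SSD or Harpending raggedness (`r = sum` of squared
successive frequency steps, including the closing step to zero).

Shape labels reproduce the conventional by-eye classes with a fixed rule:
`1h`/`2h` for one or two haplotypes; otherwise frequencies are smoothed
with a 3-bin moving average and local maxima with prominence at least 5% of
the total mass are counted — two or more peaks give `bi`, else `uni`.

## LD screening

`pairwise_ld()` dichotomizes each polymorphic site major-allele-vs-rest and
reports, per site pair, `r_LD` (absolute correlation of the indicators) and
a two-tailed Fisher exact P-value on the 2x2 table; no multiple-testing
correction is applied (the number of tests is recorded so users can apply
one). `exclude_linked_sites()` removes *both* members of every pair with
`P < alpha` and `r_LD` above the threshold (default 0.5), producing the
"filtered" dataset variant; `compare_clusterings()` then quantifies
robustness as the best label-permutation agreement of majority assignments
between full and filtered runs. Exclusion is monotone: lowering the
threshold never shrinks the excluded set.

## Admixture clustering and model choice

`run_admixture()` is a Gibbs sampler for the standard admixture model:
every allele copy carries a cluster label sampled given the individual's
ancestry vector `Q` and cluster allele frequencies `P`; `P` has a
`Dirichlet(lambda + counts)` full conditional with `lambda = 1`; `Q` is
`Dirichlet(alpha + counts)`; the admixture parameter `alpha` moves by
random-walk Metropolis under a uniform prior on `(0, 10]`. Haploid
mitochondrial loci enter as single allele copies, never duplicated. The
model probability `lnPD` is the usual estimator: mean minus half the
variance of the data log-likelihood over retained sweeps. A
`no_admixture` variant assigns whole individuals instead.

`select_k()` applies the second-order rate-of-change criterion:
`deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` over
replicate runs, choosing the smallest K among peaks within 5% of the
maximum (near-equal multiple peaks are recorded — hierarchically structured
data genuinely produce them). Two design choices matter here and were made
after explicit experiments:

* **Model choice runs under the no-admixture model.** The deltaK signal
  lives in the *between-replicate instability* of `lnPD` at under-fitted
  `K`. A well-mixing admixture sampler settles in the same merge mode in
  every replicate, so `sd(L(K))` stays tiny below the true `K` and deltaK
  degenerates to its well-known preference for `K = 2`. The no-admixture
  chains land in different cluster-merge modes across replicates at
  under-fitted `K`, restoring the variance the statistic keys on, while at
  the true `K` the correct mode dominates. Ancestry estimation afterwards
  always uses the admixture model.
* **Each replicate reports its best chain over a small number of restarts**
  (default 2). A chain occasionally sticks in a poor local mode even at the
  true `K`; restarts are a within-replicate mode-finding device and leave
  the between-replicate spread intact.

A deltaK profile without a dominant peak (maximum below five times the
median of the remaining values) marks the choice unreliable — the expected
outcome for a panmictic sample.

`hierarchical_analysis()` applies the protocol recursively: assign
individuals to their majority cluster above a context threshold (defaults
0.8 mitochondrial, 0.6 nuclear, 0.7 combined — configuration, not
hard-coded) or group homogeneous isolates (mean majority ancestry at least
0.9), then re-run model choice within each subset of sufficient size.
`flag_intercluster_heterozygotes()` flags diploid individuals whose two
largest ancestry components both fall in the half-and-half band (default
`[0.405, 0.595]`) and reports the implicated cluster pair.

## F-statistics

All F-statistics are Phi-statistics: AMOVA decompositions of the matrix of
pairwise sequence differences (the number of differing sites playing the
role of the squared distance), not allele-identity statistics — the
convention under which this family of results is normally produced for
sequence data. The nested decomposition supports among-groups,
among-isolates-within-groups, among-individuals-within-isolates and
within-individuals levels with exact unbalanced-design coefficients
(computed from the projection-trace identities, solved as a triangular
system), negative components retained and reported. Permutation schemes are
level-specific: whole isolates among groups, individuals among isolates
within groups, and allele copies among individuals for the
heterozygote-deficit component behind `F_IS`. Pairwise `Phi_ST`
(`pairwise_phist()`) permutes *genotypes* by default — both alleles of an
individual move together — because nuclear alleles of one individual are
not independent under Hardy-Weinberg disequilibrium; `allele` and
`individual` units are available, and the genotype-vs-allele distinction
measurably changes P-values on HWD data.

## The genetic-profile classifier

`classify_gp()` condenses each isolate into one of six demographic-history
profiles from five statistics: the mito/nuclear diversity ratio, the two
nucleotide diversities, the number of first-level nuclear clusters
represented in the isolate (`k_t1()`: clusters where some member has
ancestry at least 0.4 — catching both homozygous members and half-and-half
heterozygotes), and the signs of Tajima's D. The rules are evaluated
jointly, not singly; the ratio threshold 0.5 flags candidate secondary
contact because equilibrium expectations keep mitochondrial diversity well
below nuclear. Point diversities printed for single-isolate profiles are
treated as observed exemplars, not thresholds, so the single-isolate
profiles key on their discriminating feature (`ratio > 1` for GP4, a
single nuclear cluster for GP6). The same joint-discrimination logic
governs which diversity windows are enforced: GP1 and GP3 (both `K_T1 = 2`
with a low ratio) are separated by their nuclear-diversity bounds, which
are therefore kept, while GP2 is already unique as the only profile with
`K_T1 = 3` and a low ratio, so its printed nuclear-diversity range is not
part of the predicate — on a single non-recombining
fragment of this length the realized between-lineage divergence has a
coefficient of variation near 25%, wider than that window, so no
demographic scenario could satisfy it reliably and the window carries no
discriminating information. Every classification carries a full
criterion trace; isolates matching several profiles return the ambiguous
set, isolates matching none return `NA`. "Diverse D values" is not a
computable predicate and is only recorded in the trace as the observed sign
pattern. `s_maj()` implements the majority star group: the most frequent
mitochondrial haplotype plus haplotypes at most two mutational steps away;
when that group exceeds 60% of the isolate's sequences (strictly, by
sequence abundance), `S_maj` is the number of segregating sites inside it.

## The simulator

`simulate_scenario()` draws structured-coalescent gene trees per locus with
per-deme effective copy numbers set by the inheritance system (mito `N_f`;
nuclear `2*N_f + N_m` haplodiploid, `2*(N_f + N_m)` diplodiploid), so the
3-fold (resp. 4-fold) effective-size contrast is built in and is verified
by the package's calibration targets. Time runs pastward in generations
with exponential waiting times between coalescences (a discrete-event
continuous approximation); events are deme splits, founding/replacement
admixture pulses (with optional F1 pairing, per-individual pairing for
motley contact, and separate mitochondrial source proportions or a fixed
maternal source), bottlenecks and size changes. Substitutions follow the
infinite-sites model mapped to distinct columns (collisions re-drawn);
indel series toggle by a two-state process on designated intervals and are
emitted as gap blocks. Identical scenario and seed give identical output.

What the generator emulates: deep lineage radiation, hybrid swarms,
motley secondary contact, female-skewed founder groups (which collapse the
mitochondrial pool while sparing nuclear copies — the mechanism behind
mito/nuclear diversity inversions), haplodiploid copy-number contrasts, and
localized indel evolution. What it does not emulate: selection,
recombination within a fragment (negligible over such short gene
fragments), continuous migration (only pulses), sequencing error, or
alignment uncertainty. Tests passing on simulated data therefore validate
the statistical machinery and the scenario logic, not robustness to
technical noise in real chromatograms.

`scripted_scenarios()` packages seven parameterizations whose statistic
signatures land in the six profile windows plus the motley pattern; the
parameter sketches are in its help page. Their calibration is a design
exercise in its own right, and three choices deserve note:

* source demes are moderate (500 females + 500 males) so reference
  isolates retain within-lineage diversity (clonal references make cluster
  identity unstable), while the ancestral deme shrinks after the radiation
  in the window-bounded scenarios — the exponential tail of ancestral
  coalescence otherwise dominates the variance of realized divergence;
* swarm/focal demes are large (3000 + 3000) so sampled lineages do not
  coalesce away between the founding pulse and sampling;
* first-level clustering in the scenario validation runs at `K` equal to
  the number of reference lineages in the sampling design (the
  reference-panel convention). On hybrid-swarm datasets deltaK collapses
  to the uppermost hierarchical level — the multi-peak behaviour such data
  genuinely produce — so data-driven model choice is validated separately
  on plain multi-population simulations.

With a 729-column nuclear fragment, an enforced diversity window such as
GP3's upper bound spans only about twice the coalescent-plus-mutational
standard deviation of realized diversity, so profile recovery rates around
80-90% per scenario are the realistic ceiling at these locus lengths; the
scenarios aim at the centre of each constraint region rather than at
certainty.

## Validation problem sizes

The test-suite simulations are desk-scale by design: 10-30 individuals per
unit, MCMC runs of a few thousand sweeps with 3 replicates per `K`,
permutation tests at 99-10000 permutations, parametric bootstraps at
B = 50-200, and 10-200 replicate simulations per property. The
effective-size calibration uses 200 replicate samples of 20 individuals.
All stochastic entry points take explicit seeds; replicate `r` of a
multi-replicate procedure derives its seed by fixed offsets, so every
reported number is reproducible.

## A worked sketch

```{r example, eval = FALSE}
scn <- sim_island_scenario(n_pop = 2, n_per = 15, n_hybrid = 10,
                           t_split = 8000)
s <- simulate_scenario(scn, seed = 5)

gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
sel <- select_k(gm, k_range = 1:4, replicates = 3,
                burn_in = 800, reps = 3000, seed = 11)
run <- run_admixture(gm, K = sel$chosen_K, burn_in = 1000, reps = 4000,
                     seed = 3)
flag_intercluster_heterozygotes(run) |> dplyr::filter(flagged)
autoplot(run)

amova(s$nuclear, n_perm = 999, seed = 7)
diversity_summary(s$mito) |>
  pi_ratio_flag(diversity_summary(s$nuclear))
```

## Known limitations

* The Gibbs sampler has no CLUMPP-style multi-run alignment beyond greedy
  label matching, no spatial priors, and no linkage model (the latter is
  unstable on short single fragments and deliberately out of scope).
* deltaK inherits its documented bias toward the uppermost structure
  level; the hierarchical protocol, not the raw deltaK value, is the unit
  of interpretation on layered data.
* The sudden-expansion fit assumes a single instantaneous size change; a
  bimodal mismatch distribution fits it poorly by construction, which is
  exactly what the SSD bootstrap is meant to flag.
* Profile windows are calibrated for the default locus lengths (543 and
  729 columns); much shorter fragments widen the realized-diversity spread
  and lower recovery rates.
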