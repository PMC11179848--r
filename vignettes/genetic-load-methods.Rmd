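---
title: "Methods: predicting and measuring the deleterious burden in declining populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and measuring the deleterious burden in declining populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(genload)
```

# The problem

Small, declining populations of long-lived organisms accumulate two
opposing genetic signals. Drift lets weakly deleterious mutations rise
in frequency and fix, inflating the genetic load; at the same time
inbreeding exposes (partially) recessive deleterious alleles as
homozygotes, letting purifying selection remove them — genetic
purging. Which force wins depends on the homozygous effect $s$, the
dominance $h$, and the demographic and mating history. `genload`
provides (i) a deterministic model that predicts the expected number of
derived deleterious alleles per diploid genome along an arbitrary
piecewise-constant demographic trajectory, (ii) a stochastic
Wright–Fisher simulator used as an independent oracle and as the
genotype source for synthetic cohorts, and (iii) the empirical
statistics by which purging is diagnosed in resequencing data:
$\pi_0/\pi_4$, individual heterozygosity, runs of homozygosity (ROH)
and $F_{ROH}$, and derived-allele burden ratios stratified by zygosity
and by ROH membership.

# The burden model

## State and dynamics

A mutation category is described by genotype fitnesses $1$, $1-hs$,
$1-s$ and a haploid genomic influx $\lambda$ (new mutations per haploid
genome per generation; every output is exactly linear in $\lambda$, and
$\lambda = 1$ is the reporting convention). In a diploid population of
size $N$ the derived copy count $j \in \{0, \dots, 2N\}$ evolves by one
deterministic generation of viability selection,
$$ q' = \frac{q\,w_d}{\bar w}, \qquad
   w_d = p(1-hs) + q(1-s),\;
   \bar w = p\,[p + q(1-hs)] + q\,w_d, $$
followed by binomial resampling of $2N$ gametes. `wf_transition_matrix()`
realizes this as a dense row-stochastic matrix with absorbing states at
$0$ and $2N$; `msd_equilibrium()` solves the stationary segregating
density under an influx of $2N\lambda$ mutations per generation
entering at one copy, by a direct linear solve on the transient states
(a fixed-point iteration, tolerance $10^{-10}$, is kept as a fallback).
The expected segregating burden per diploid genome is
$n_{seg} = \sum_j (j/N)\, m_j$.

`evolve_burden()` iterates the matrix one generation at a time along a
`demographic_trajectory()`. At an epoch boundary the density is
remapped to the new state space by one generation of binomial sampling
into $2N_{new}$ gametes. Fixed sites contribute 2 copies per genome;
because an irreversible-mutation model has no absolute fixed-count
equilibrium, the constant ancestral fixation flux is subtracted so the
pre-decline baseline is flat and all change reflects demography. Mass
conservation (injected = segregating + fixed + lost) is tracked every
generation and stays below $10^{-9}$ relative error.

## Numerical choices

* Dense matrices are guarded at $2N + 1 \le 4001$ states. Larger
  populations go through `rescale_scenario()`, which divides sizes and
  durations by $c$ and multiplies $s$ **and** $\lambda$ by $c$. All
  three rescalings are needed to keep the dynamics invariant: $4Ns$
  fixes the diffusion behaviour, durations in units of $N$ generations
  fix the time axis, and scaling $\lambda$ keeps the per-epoch influx
  (and hence $n_{seg}$, which for neutral mutations equals $8N\lambda$)
  unchanged. The approximation degrades as the scaled $s$ approaches 1.
* New mutations enter at copy count 1 of the current epoch, the
  standard Wright–Fisher convention.
* Boundary states never pass through the selection update, so lethal
  alleles ($s = 1$) are handled without a zero-mean-fitness
  singularity; an interior state with $\bar w \le 0$ raises an error.
* The time axis is generations; `generations_to_years()` converts for
  labeling with a default generation time of 50 years (long-lived
  conifers). The default parameter grid is $s \in \{0.001, 0.01, 0.1\}$
  (weakly, mildly, strongly deleterious) crossed with
  $h \in \{0.05, 0.25, 0.45\}$ (highly recessive, partially recessive,
  roughly additive); $h = 0.05$ rather than $0$ avoids assuming a large
  hidden recessive burden in the ancestral population.

## Two equilibrium objects, not one

The linear-influx density treats mutation lineages as independent,
which is exact for genome-wide burdens at small per-site rates but
over-counts when a single site's equilibrium frequency is not small
(lineages at one site are coupled through its bounded frequency). The
per-site question — the mean derived frequency at a recurrently mutating
site — is therefore answered by a separate object,
`equilibrium_mean_frequency()`, the stationary distribution of the
single-site Wright–Fisher chain with two-way mutation at rate $u$. Its
deterministic limits, $u/(hs)$ for partially dominant selection
($4Nhs \gg 1$) and $\sqrt{u/s}$ for full recessives ($4Ns \gg 1$ with
weak drift at the balance frequency), are recovered within 10% and 15%
at $N = 500$, $s = 0.1$ with $u = 10^{-4}$ and $u = 2.5\times 10^{-3}$
respectively; the $u$ values are chosen from those validity conditions
(for the recessive case, $Ns\hat q^2 \approx 12$ keeps drift at the
balance frequency small while $\hat q = 0.16$ stays modest).

# The stochastic engine

`simulate_site()` runs the same update with actual binomial sampling.
`sim_equilibrium_burden()` exploits a renewal identity: at
stationarity the standing density is the superposition of all past
injection cohorts, so
$n_{seg} = 2\lambda\, E\!\left[\sum_t j_t\right]$ over the segregating
lifetime of a single mutation entering at one copy. Ten thousand
independent lifetimes give a clean Monte-Carlo mean and standard
error, and the fraction absorbed at $2N$ estimates the fixation
probability — the package's independent cross-check of the matrix
engine (`compare_engines()` reports per-grid-cell $z$-scores).
`simulate_burden()` instead simulates whole replicate populations
(Poisson influx, all sites unlinked), initialized by Poisson-sampling
standing sites from the matrix equilibrium density; because one
population already averages tens of thousands of sites, a couple of
dozen replicate populations give usable standard errors for the
time-resolved comparison.

# The synthetic-cohort generator

The generator defines the study conditions; its defaults are fixed
once and describe a rare/widespread species pair at desk scale:

* **Cohorts.** 32 "rare" and 51 "widespread" individuals, mirroring a
  typical rare-conifer resequencing design.
* **Demography.** Both populations descend from one ancestral MSD
  equilibrium at $N = 1000$; the rare population declines
  ($1000 \to 400 \to 150$ over 1000 generations) and the widespread one
  recovers ($1000 \to 700 \to 1000$).
* **Mating.** The decisive purging parameter is population inbreeding:
  the frequency dynamics use inbred genotype proportions
  $p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq$ with $F = 0.25$ (rare) versus
  $F = 0.05$ (widespread). This matters because small-$N$ drift alone
  *inverts* the deleterious-to-synonymous ratio contrast: neutral
  diversity collapses on the $4N$-generation timescale faster than
  mutation–selection–drift deleterious variation, which is
  continuously replenished. Inbreeding exposes recessives directly,
  with effective per-copy selection $\approx s[h + F(1-h)]$, so the
  chosen regime is "decline long relative to the purging timescale
  $1/(s[h+F(1-h)])$, moderate relative to $4N$" — the regime in which
  declining inbred populations show *lower* normalized deleterious
  burdens.
* **Sites.** Four effect classes — synonymous $(0, 0.5)$, tolerated
  $(0.001, 0.35)$, deleterious $(0.1, 0.05)$, LoF $(0.3, 0.02)$ — with
  budgets equal to the expected number of ancestrally segregating
  sites. Standing sites share their origin between the cohorts
  (sampled from the equilibrium density, then forward-simulated
  independently through each trajectory); post-split private sites are
  Poisson-sampled from the matrix engine's exact influx-only terminal
  density at the class's implied influx rate, including drift-fixed
  private sites. Coordinates are uniform over 4 × 5 Mb contigs
  (~6 variant rows/kb), a density chosen so that per-individual
  heterozygous-site density (~0.2–0.4/kb) carries enough information
  for ROH inference; per-base-normalized statistics make the absolute
  genome size irrelevant.
* **Autozygosity.** ROH tracts are implanted to per-individual targets
  (uniform on 0.15–0.29, mean 0.22, for the rare cohort; 0.05–0.19,
  mean 0.12, widespread — the $F_{ROH}$ contrast reported between
  inbred rare conifers and widespread relatives), with exponential
  lengths (mean 500 kb, truncated to 150 kb–3 Mb; the implant minimum
  sits above the caller's 100 kb retention threshold so truth tracts
  cannot straddle the boundary class), a 50 kb separation
  buffer so truth tracts stay resolvable, and the last tract trimmed to
  land on the target. Inside a tract the shared allele is derived with
  probability $q(1-s)^G / [q(1-s)^G + 1-q]$ with $G = 10$ effective
  generations of homozygous exposure — a tract is identical by descent
  from an ancestor roughly tract-age generations back, and a derived
  homozygote must have survived selection in that lineage; $G$ is kept
  conservative because mutations also arise within the tract lineage.
  A heterozygote error knob (default 0.001) models caller noise.
* **Outgroups and missingness.** Two outgroup allele columns mutate
  the true ancestral allele independently with probability 0.05
  (Jukes–Cantor-style, uniform over the other three bases), exercising
  the polarizer's agreement, conflict and mismatch paths. Genotypes
  drop out missing-completely-at-random at rate 0.02; the missingness
  process is a documented knob, not an inference target.

What the generator does **not** emulate: linkage (sites are unlinked,
so LD decay curves are flat at the $1/n$ sampling floor), spatially
varying mutation or recombination rates, reference bias, genotyping
error outside ROH, and emergent (pedigree) inbreeding — ROH are
implanted, not coalescent. Passing tests therefore demonstrate the
correctness and internal consistency of the statistics and the
direction of selection-driven contrasts, not calibration against any
real genome.

# The empirical pipeline

* **Degeneracy.** `classify_degeneracy()` enumerates all four bases at
  every position of each complete in-frame codon, strand-aware; a site
  is 4-fold if all substitutions are synonymous, 0-fold if none are.
  Transcripts with frame violations or internal stops are skipped with
  a log entry. The implementation is a precomputed 64 × 3 lookup table;
  tests verify it against an independent brute-force enumeration.
* **Diversity.** Per-site $\pi = 2\hat p\hat q\, n/(n-1)$ over observed
  alleles, summed in 100 kb windows sliding by 10 kb and divided by
  window length; monomorphic bases contribute zero. Individual
  heterozygosity is heterozygous calls per callable bp — the same scale
  as $\pi$ — with the method-of-moments inbreeding coefficient
  $F_{het} = 1 - O(het)/E(het)$ also reported.
* **ROH.** A two-state HMM per individual: heterozygote emission
  $\varepsilon$ (default $10^{-3}$) in the autozygous state and the
  Hardy–Weinberg $2\hat p\hat q$ (floored at $10^{-3}$) outside;
  distance-dependent switch probabilities $1 - e^{-r d}$ with
  $r_{out} = 2 \times 10^{-6}$/bp (mean tract ~500 kb) and
  $r_{in} = 5 \times 10^{-7}$/bp (stationary autozygosity prior 0.2).
  Viterbi runs become segments with midpoint-extended boundaries,
  retained at ≥ 100 kb, with > 1 Mb labeled as the recent-inbreeding
  class.
  The caller is validated by truth recovery on implanted tracts
  (every individual's $F_{ROH}$ within ±10%), not by matching any
  external tool's undocumented defaults. Missing genotypes emit
  nothing but still accumulate transition distance.
* **Polarization.** Explicit outgroup parsimony instead of a
  probabilistic ancestral-state model: strict mode requires both
  outgroups to agree and match an ingroup allele; relaxed mode accepts
  a single informative outgroup, flagged. Conflicts and double
  mismatches are excluded from burden counts. At the default 0.05
  divergence per outgroup branch, strict-mode misassignment is well
  under 5% (both outgroups must independently hit the same derived
  allele).
* **Burden ratios.** Derived counts follow 2·hom + het; missing
  genotypes leave both numerators and denominators. Ratios are
  class-to-synonymous within the same zygosity stratum (het/hom) or
  the same genomic stratum (inside/outside the individual's own ROH).
  Welch's unequal-variance $t$-test on per-individual ratios is the
  only hypothesis test, with no multiple-testing correction — the
  handful of planned comparisons is reported as-is.
* **LD decay.** Genotype-dosage $r^2$ on randomly subsampled
  intra-contig pairs within 1 Mb, binned by distance, with the
  half-maximum decay distance reported. Missing dosages are mean-imputed
  for the correlation.

# Problem sizes

The shipped defaults are desk-scale choices: dense solves at
$2N \le 2000$ states, $10^4$ simulator lifetimes per grid cell,
~135 000 variant rows × 83 individuals per synthetic cohort, and five
replicate seeds for the directional suite. `scripts/acceptance.R`
reruns the entire set — oracle checks, balance limits, nine-cell engine
comparison, bottleneck purging dynamics, $F_{ROH}$ recovery, and the
five-seed directional suite — from a single seed.

# Known limitations

* The matrix engine is per-site independent and linear in $\lambda$;
  no interference among sites, no linked sweeps.
* The purging model's random-mating contract ($F = 0$) is used for all
  burden predictions; inbreeding enters only the generator's frequency
  dynamics. A full inbreeding-aware prediction would need $F$ as a
  trajectory input.
* Fixed-burden accounting is relative to the ancestral flux; strongly
  purged scenarios can in principle drive the net fixed burden slightly
  negative (fixation flux below the ancestral baseline), which is a
  feature of the relative convention, not mass loss.
* The ROH caller's boundary resolution is limited by variant spacing:
  segment edges are placed at the midpoint between the boundary
  autozygous site and its neighbour, which is unbiased on average but
  jitters by about half an inter-site gap per edge.
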