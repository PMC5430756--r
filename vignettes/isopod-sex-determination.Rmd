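---
title: "Inferring sex determination systems and their turnover in terrestrial isopods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex determination systems and their turnover in terrestrial isopods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopodSD)
```

## The problem

Terrestrial isopods (Oniscidea) determine sex genetically, but the identity
of the heterogametic sex flips between lineages: some species are male
heterogametic (XY males / XX females), others female heterogametic (ZW
females / ZZ males), and the two systems are interleaved across the
phylogeny. Feminizing *Wolbachia* endosymbionts — maternally inherited
bacteria that convert genetic males into functional females — are thought to
drive these turnovers. `isopodSD` implements the full quantitative chain
needed to study this: predicting progeny sex ratios from crosses of
sex-reversed females, classifying a species' heterogametic system from brood
counts, and counting transitions between systems on a dated phylogeny.

## The crossing design and its Mendelian model

Isopods are sexually undifferentiated at birth and male differentiation is
hormonal, so implanting androgenic glands into a young genetic female
produces a functional phenotypic male — a *neomale*. Crossing a neomale with
its sisters crosses two identical sex-chromosome genotypes, and the progeny
sex ratio diagnoses the system:

* Female heterogamety: ZW neomale × ZW female → ¼ ZZ (male), ½ ZW, ¼ WW
  (both female) if the WW genotype is viable, i.e. **25% males**; dropping WW
  and renormalizing gives **1/3 males** if WW is inviable.
* Male heterogamety: XX neomale × XX female → **100% XX females**.

`cross()` implements this as an equal-probability gamete union with
viability filtering and renormalization; `genotype()` carries a
`reversed` flag so crosses validate on the functional phenotype rather
than the genotypic sex. The distinction between the 25% and 1/3
expectations is the WW-viability diagnosis: viable WW implies the Z and W
chromosomes are still largely homomorphic, i.e. sex chromosomes at an
incipient stage. `wolbachia_progeny()` covers the cytoplasmic case, in
which all individuals are ZZ and the brood sex ratio equals the maternal
transmission rate (~0.9). Feminization is modeled per offspring as a
Bernoulli draw with that rate; intracellular titer dynamics are out of
scope because only the transmission rate enters any downstream analysis.

```{r cross}
cross(genotype("ZW", reversed = TRUE), genotype("ZW"))
```

## From brood counts to a species call

`filter_broods()` applies two discard rules in a fixed order, mirroring the
experimental contaminants: broods from *Wolbachia*-positive mothers first
(their female bias mimics the heterogamety signal), then broods whose sex
ratio is compatible with 1:1 at level α (interpreted as a failed sex
reversal — the implanted animal was an undifferentiated male, so the cross
was an ordinary male × female one). Mothers with untested infection status
are treated as negative by default (with a warning), since the original
experiments PCR-screened every mother but simulated data may not.

`classify_species()` then:

1. tests heterogeneity of sex ratios across broods (Pearson χ² on the
   brood × sex table); a significant result blocks pooling and returns
   `UNDETERMINED` — inconsistent broods should not be averaged;
2. pools counts and tests the pooled ratio against 1:1, 1/3 males and
   1/4 males (1-df Pearson χ², no continuity correction — the analysis
   convention of the original study; a Yates flag is exposed), and against
   the all-female XY expectation with an exact binomial test
   (`exact_zero_male_test()`), because a χ² against an expected proportion
   of zero is undefined. The test's `male_leak_rate` (default 0) allows a
   nuisance male rate; with zero leak a single male falsifies XY;
3. walks a fixed decision tree: significant *male* excess →
   `UNDETERMINED` (the *Armadillidium assimile* all-male pattern, which no
   heterogametic prediction explains); zero-male test retained while both
   ZW expectations are rejected → `XY`; otherwise `ZW` with WW viability
   `viable` / `inviable` / `indeterminate` by which of the 1/3 and 1/4
   nulls is rejected. All three nulls rejected → `UNDETERMINED` rather
   than forcing a call. A species whose only brood is all-female but too
   small to reject the ZW expectations is returned as `XY` with
   `xy_candidate`/`low_power` flags.

α = 0.05 throughout. `viability_power()` quantifies the sample sizes this
decision needs: at 30 pooled offspring the power to separate 1/4 from 1/3
is below 0.10 (which is why a 30-offspring species stays `indeterminate`),
reaching ~0.99 only near 500 offspring.

## Counting transitions on the phylogeny

Tip states are coded two ways: `two_state` (XY, ZW; the unexplained
*A. assimile* system treated as unknown) and `three_state` (XY, ZW, OTHER).
`UNKNOWN` tips are uninformative in both frameworks: zero parsimony cost
for every state, all-ones partial likelihoods. Both codings assume all W
chromosomes are homologous and all Y chromosomes are homologous, so
turnovers that preserve the heterogametic type are invisible and every
count is a lower bound.

**Parsimony.** `parsimony_min_transitions()` is a Sankoff dynamic program
with unit costs; branch lengths are ignored.
`parsimony_direction_counts()` enumerates *all* labelings achieving the
minimum (rather than committing to ACCTRAN/DELTRAN, which the scale of
this problem does not require) and tallies changes per direction; an
enumeration cap (default 10⁶, never approached on trees of this size)
falls back to a single flagged labeling. On the packaged tree the
two-state minimum is 3 — one XY→ZW at the base of the derived terrestrial
clade and two ZW→XY (one within Armadillidiidae, one between the two
*Porcellio dilatatus* subspecies) — and the reconstruction is unique;
the three-state minimum is 4.

**Maximum likelihood.** `mk_model()` builds the Mk rate matrix (`ER`: one
shared rate; `SYM`: one rate per unordered pair; units: expected
transitions per lineage per million years). `mk_loglik()` is Felsenstein
pruning with per-node log-scaling; transition probabilities come from an
eigendecomposition of the symmetric rate matrix (tolerance at the level of
machine precision; tiny negative round-off is clipped). The root prior
defaults to uniform — the stationary distribution of any ER/SYM chain, and
the convention used for unknown systems. `fit_mk()` maximizes over
log-rates with deterministic bounded searches (golden-section for ER,
L-BFGS-B started from the ER solution for SYM); a constant character
drives the rate to the lower search bound and is flagged
`monotone_likelihood` instead of being reported as a converged estimate.
`ancestral_marginals()` gives per-node posterior state probabilities (the
pie charts of ancestral-state figures) via the standard down/up pass.

**Stochastic mapping.** `stochastic_maps()` samples joint ancestral states
from their conditional distribution and then substitution histories along
each branch conditional on endpoints. The default branch sampler is
uniformization, chosen because it is exact and has bounded runtime even on
branches whose endpoint combination is improbable; forward-simulation
rejection sampling is available behind a flag and switches to
uniformization automatically after 100 failed tries. Expected counts are
means over maps (1,000 by default) and split by direction. ML expected
counts exceed the parsimony minimum because long waits on short internal
branches admit unobserved double transitions; on the packaged tree they
land in the low-to-mid teens, with ZW→XY roughly twice XY→ZW — the
direction asymmetry is the robust feature, the total depends on the
(partly interpolated) chronogram and should be read as a plausibility
band, not a point estimate.

**Absolute rates.** `absolute_rate()` performs the summed-branch scaling
of per-branch synonymous substitution estimates (e.g. CodeML output) by
branch ages: Σ dS / Σ age, and dN/dS = Σ dN / Σ dS. Codon-model fitting
itself is out of scope; the function consumes its output table.

## The packaged fixtures

`fixture_isopod_tree()` encodes the 26-taxon dated phylogeny from its
text-anchored clades (Tylidae sister to all other Oniscidea;
Porcellionidae sister to Trachelipodidae; paraphyletic Philosciidae
including *Oniscus asellus*; the (*A. siculorum*, *A. assimile*) pair;
Amphipoda closer to Isopoda than Decapoda among the outgroups). The eight
published median node ages (307, 117, 66, 38, 36, 35, 25, 15 My) are
honored exactly; all other ages are even interpolations along the chain
between bracketing printed ages, flagged `interpolated` in
`fixture_node_ages()` — a deliberate choice to avoid measuring numbers off
a figure. Within-genus branching order is only weakly anchored; the
parsimony counts are insensitive to it because every XY tip inside the
derived clade is a terminal singleton. `fixture_state_table()` carries the
published heterogametic types: 10 ZW, 5 XY, *A. assimile* as
OTHER/unknown, 8 unassessed.

`fixture_brood_table()` is a **synthetic stand-in** for the per-brood
supplementary data, which this package does not redistribute. It matches
every published aggregate — 43 broods from 11 species; 5 Wolbachia
discards; 11 balanced discards; 27 kept broods from 7 species; and the
per-species verdict pattern, including the 30-offspring species whose WW
viability stays unresolved and the all-male species — but its individual
brood counts are invented. Results computed from it validate the pipeline
mechanics, not the original measurements.

## What the simulators emulate — and what they do not

`simulate_experiment()` reproduces the experiment's structure: injected
females die (default rate 60/135), or turn out to be undifferentiated
males so the sire is a genetic male and the brood is ~1:1 (default
25/135), mothers carry *Wolbachia* with study-level prevalence (5/43,
transmission 0.9), and brood sizes are negative-binomial (mean 40,
dispersion 8 — the study reports only ranges, and isopod broods of a few
dozen with moderate overdispersion are typical). Sex counts are binomial
with the male proportion implied by the cross model. Not emulated: brood
failure after pairing, embryonic mortality (none was observed in the
study), within-species variation in brood size regimes, the unexplained
all-male system, or any sequence-level process. Passing recovery tests
therefore show the statistical pipeline is sound under binomial sampling
and the modeled contaminants — not that real broods are binomial.

`simulate_mk_history()` is a Gillespie simulation of the Mk chain with
full event histories, used as the ground-truth oracle for rate recovery
and for checking the stochastic-mapping sampler against analytic expected
counts.

## A structural limit on end-to-end recovery

One property deserves honesty: with study-like contamination, the full
simulate → filter → classify chain recovers the true system in ~90% of
replicates (≈95% ZW-viable, ≈99% ZW-inviable, ≈91% XY at large pooled
sizes), not more, and the shortfall is structural rather than numerical.
A genetic-male-sired brood escapes the balanced-ratio filter with
probability exactly α = 0.05 (the size of the test); with a handful of
such broods per experiment, a few percent of replicates retain one. A
retained contaminant brood usually triggers the heterogeneity gate (an
honest `UNDETERMINED`), and under male heterogamety even a single escaped
brood defeats the strict zero-male XY test. Independently, the
heterogeneity gate itself is a size-0.05 test, so ~5% of perfectly clean
multi-brood experiments are blocked by chance. Raising recovery would
require weakening one of the deliberately conservative rules (pooling
despite heterogeneity, or a nonzero default male leak), which we decline
to do; the refusals are the procedure working as designed.

## Problem sizes and reproducibility

All Monte-Carlo components take explicit integer seeds and are
bit-reproducible given (configuration, seed); seeds are applied locally so
callers' RNG state is untouched. The shipped analyses use 1,000 stochastic
maps (the study's setting); the test suite exercises rate recovery on 50
simulated 100-tip trees, classifier recovery on 600 simulated experiments,
exhaustive-enumeration cross-checks on trees of up to 10 tips, and 10,000
Monte-Carlo draws for test-size checks.
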