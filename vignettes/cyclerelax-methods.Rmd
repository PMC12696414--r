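---
title: "Models and methods behind cyclerelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyclerelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Aphids divide into species that alternate seasonally between a woody
primary host and an herbaceous secondary host (heteroecy) and species
that complete their life cycle on a single host (monoecy). If the genes
supporting host alternation become dispensable in monoecious lineages,
they should evolve under relaxed purifying selection there: elevated
dN/dS on monoecious terminal branches, and a site-wise dN/dS
distribution compressed toward 1. `cyclerelax` implements the full
statistical machinery for that comparison — branch-partitioned codon
models, a selection-intensity test, the alignment-cleaning rules that
precede them, GO enrichment of candidate sets, and a simulator that
generates data with exactly the structure the analysis assumes.

## The codon model

All likelihoods use a GY94-family codon model on the 61 sense codons of
the standard genetic code (stop codons are excluded from the state space
and can never be emitted). The instantaneous rate from codon *i* to *j*
is zero unless the codons differ at exactly one position, and otherwise

  q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous],

with target-codon frequency `pi_j`, transition/transversion ratio
`kappa`, and dN/dS `omega`. Each branch class's generator is scaled to
unit expected substitution rate at stationarity, so branch lengths are
expected substitutions per codon under that branch's own omega. This is
the simplest self-consistent convention; it differs from Codeml's
shared internal tree scaling, which affects the branch-length scale but
not likelihood-ratio tests or the omega estimates, because every model
compared shares the same convention. Branch lengths are fixed at the
input tree's values during fitting (Codeml re-estimates them; at desk
scale we treat the gene tree as known — a documented divergence).

Codon frequencies are fixed at their empirical values with a
pseudo-count of 0.5 per sense codon (an empirical-frequency convention
in the spirit of Codeml's `CodonFreq = 3`), which guarantees strict
positivity. `kappa` is estimated jointly with the omegas. Transition
probabilities are computed by spectral decomposition of the
pi-symmetrized generator (exact for a reversible chain); the pruning
recursion rescales partial likelihoods per site to avoid underflow.
Codons containing `N`, IUPAC ambiguity letters, or gaps are treated as
missing data with a uniform partial likelihood over all 61 states, so an
all-missing site contributes zero log-likelihood.

## Branch models and the LRT

The two-ratio model (M0) gives all terminal branches one dN/dS and all
internal (background) branches another. The three-ratio model (M1)
splits the terminal ratio by life cycle: monoecious terminal,
heteroecious terminal, background. M1 nests M0 (constrain the two
terminal ratios equal), so the comparison is a likelihood-ratio test
with one degree of freedom against the chi-square upper tail. Across
orthologs, p-values are Benjamini–Hochberg corrected and significance
is called at adjusted p < 0.05. The "direction" of each significant
ortholog compares the M1 estimates of the two terminal-class ratios
directly.

## The selection-intensity (RELAX-style) test

The selection-intensity test uses a three-category site model: site
categories with dN/dS `omega_1 <= omega_2 <= omega_3` and proportions
`p` are shared by all branches; test branches raise each category's
omega to the power `k`. Since `x^k` is closer to 1 than `x` for every
`x != 1` when `k < 1`, `k < 1` means the test-branch distribution is
compressed toward neutrality (relaxed selection) and `k > 1` means it
is pushed away (intensified selection). The null fixes `k = 1`; the
alternative frees it; the LRT again has one degree of freedom. Three
categories is the common default for this test family; the count is a
design choice, not estimated.

Terminal branches of the tested life cycle are the test set, the other
terminal branches are the reference set, and internal branches are
unclassified: their life-cycle state is not knowable, so they carry the
reference omega distribution (k = 1) and contribute to the likelihood
without any test-specific parameter. Branches cannot simply be dropped
from a pruning likelihood, and this treatment adds no parameters to
either model being compared, so the test's degrees of freedom are
unaffected. The two test families (monoecious-test M_M, heteroecious-test
M_H) are BH-corrected separately, mirroring the two separate model
comparisons. Verdicts are `relaxed` (adjusted p < 0.05 and k < 1),
`intensified` (adjusted p < 0.05 and k > 1), else `null`; the
cross-classification counts the three supporting categories
(relaxed-in-mono and intensified-in-het; relaxed-in-mono only;
intensified-in-het only) and their overlap with the M1-significant
mono-higher orthologs.

## Optimization

All positive parameters are optimized on the log scale with box bounds
(omega in [1e-4, 20], kappa in [0.1, 50], k in [0.05, 20]); category
proportions use a stick-breaking logit. Each fit runs a short
Nelder–Mead exploration from at least three grid starts, polishes the
best run, and then restarts once from the optimum as a fixed-point
check; the convergence flag requires the restart to change the
log-likelihood by less than 1e-6. M1 additionally warm-starts from the
M0 optimum, and the RELAX alternative warm-starts from the null optimum
with k = 1 — which also guarantees the nesting inequalities
lnL(M1) >= lnL(M0) and lnL(alt) >= lnL(null) by construction. The
category likelihood is invariant to jointly permuting categories and
proportions, so categories are left unordered during optimization and
sorted only for reporting. Orthologs whose fits fail to converge are
reported as NA and excluded from the BH family (m = number of converged
tests).

## Alignment preparation

The cleaning pipeline implements, in fixed order:

1. **Isoform selection** (across species): the isoform identified in the
   most query species is retained; ties break by greater length, then
   lexicographically smallest id.
2. **Coverage filter**: an ortholog is kept when present in at least
   `ceiling(0.5 * group size)` species of *each* life-cycle group —
   "at least 50%" of a count must round up.
3. **Codon-gappy trimming**: whole codon columns are removed when at
   least two sequences are gapped there (gappyness >= 2/n), keeping only
   species-specific gaps. A sequence is gapped in a codon column if any
   of its three positions is `-`, the conservative codon-aware reading,
   and the frame is always preserved. The same trimmer with a different
   threshold covers protein-level trimming uses.
4. **Ambiguity homogenization**: every IUPAC ambiguity letter becomes `N`.
5. **Divergence z-score filter**: each row's divergence from the
   majority-rule consensus (modal A/C/G/T per column, ties alphabetical
   for determinism) is converted to a z-score; rows outside [-2.5, 2.5]
   are removed. Two conventions exist for the denominator — all columns,
   or only the row's unambiguous sites; the package defaults to
   comparable sites (a row's own gaps say nothing about its divergence)
   and exposes the other behind a flag. z-scores use the sample (n-1)
   standard deviation; with fewer than 3 rows the filter is skipped with
   a warning, and a zero standard deviation removes nothing.

A useful closed form: if all rows but one are identical, the divergent
row's z-score is (n-1)/sqrt(n) regardless of how divergent it is. So the
filter *can* remove a planted outlier among 10 clean sequences
(10/sqrt(11) ≈ 3.02 > 2.5) and *provably cannot* among 5
(5/sqrt(6) ≈ 2.04 < 2.5) — the fixtures the tests use.

## The simulator

`sim_config()` defaults are the study conditions the tests and the
acceptance script assume: a balanced 8-tip tree (4 monoecious + 4
heteroecious, traits interleaved along the tip order so both classes are
spread across the tree, as in a phylogeny with repeated life-cycle
transitions), kappa = 2, uniform codon frequencies, 400 codons, and
per-class dN/dS set to the reported per-class medians (monoecious
terminal 0.1116, background 0.0849, heteroecious terminal 0.0605).
kappa and the codon frequencies are not reported per ortholog anywhere
usable, so kappa = 2 (a typical transition bias) and uniform frequencies
are declared defaults, not derived values. Branch lengths default to 0.2
(terminal) and 0.1 (internal) expected substitutions per codon — enough
divergence for the branch models to be informative at a few hundred
codons without saturating, comparable to within-subfamily divergences.

The root sequence is drawn from the stationary frequencies and each
branch evolves sites through the exact transition matrix `exp(Qt)` (no
Gillespie discretization). In a relax scenario the site category is
drawn once at the root and held fixed across branches — the site-model
convention of the test being emulated — and test branches use
`omega^k`. Stop codons never occur because they are outside the state
space. Everything is reproducible from (config, seed).

Artifact injection appends divergent copies of the first row (per-site
substitution with a configurable probability), gaps out chosen codon
columns, and sprinkles IUPAC ambiguity codes, exercising every cleaning
filter. What the simulator deliberately does *not* emulate: indel
evolution, recombination, ortholog-inference errors beyond the
divergent-sequence injector, among-site rate variation beyond the
category mixture, and codon-usage heterogeneity across lineages. Tests
passing on simulated data therefore certify the statistical machinery,
not robustness to every artifact of real genome-scale data.

## Enrichment

GO over-representation uses the hypergeometric upper tail
P(X >= k) for X ~ Hypergeometric(N, K, n), computed in log space, one
test per term present in a candidate gene, BH-corrected over the tested
terms. The background is restricted to annotated orthologs (unannotated
genes are excluded from both N and n), matching an annotated-background
definition. Terms carried by fewer than two background genes are not
tested (singleton terms produce only noise); this floor is configurable.
No GO-DAG ancestor propagation is applied — the mapping is tested as
given, and a pre-propagated map can be supplied.

## Problem sizes used by the test suite

The acceptance-level checks run at sizes chosen to make each property
measurable on a single CPU in minutes: exact likelihood oracles on 3–4
taxon trees with 2–3 codon sites; median-recovery of the generating
per-class dN/dS over 20 replicates of 400 codons (the same study the
acceptance script reproduces, with a 15% tolerance on medians set from
the estimator's sampling error at this size); LRT calibration under the
null over 100 replicates of 200 codons against the 95% binomial
interval around 5%; selection-intensity recovery (k = 0.3, categories
{0.05, 0.3, 1.5} with proportions {0.7, 0.25, 0.05}, 800 codons, 20
replicates, >= 80% detection) and calibration (k = 1, 200 codons, 30
replicates against the binomial interval).

## Known limitations

- Branch lengths are taken from the input tree, not re-estimated per
  model; strongly misspecified branch lengths will bias the omegas.
- The unit-rate-per-branch-class scaling means branch lengths are not
  numerically comparable to Codeml's under a different scaling; ratios
  and tests are unaffected.
- The selection-intensity test fixes three site categories and shares
  them between null and alternative (re-optimized in each); the general
  descriptive and partitioned variants of that test family are out of
  scope.
- Confidence intervals on k are not computed.
- The cleaning filters are deterministic re-implementations of rules
  stated for an external pipeline; where that pipeline's internals are
  unknowable (consensus tie-breaks, sd convention, divergence
  denominator) the choices here are declared and configurable rather
  than claimed to match bit-for-bit.
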