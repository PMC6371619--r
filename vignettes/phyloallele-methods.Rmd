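---
title: "Methods: coalescent allele prediction and genotype phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent allele prediction and genotype phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices
behind it, and what the tests do and do not establish. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The inference problem

A set of experimentally confirmed alleles of one long gene locus is given
as a pre-aligned FASTA. Only a small fraction of columns vary (for a
>21 kb blood-group gene, on the order of 0.3%), and the variant columns
define the allele as a haplotype string. The goal is threefold:

1. estimate the rooted genealogy of the confirmed alleles;
2. enumerate, for every internal node, candidate *ancestral* alleles with
   posterior probabilities — these are predictions of alleles that may
   exist unobserved in the population;
3. use observed + predicted alleles as templates to phase unphased
   diploid genotypes, with a confidence that reflects how much evidence
   supports each template, and a loop that feeds newly confirmed alleles
   back into the catalogue.

## Model and algorithms

**Substitution model.** TN93 with stationary frequencies $\pi$ and
transition/transversion ratios $\kappa_1$ (purine) and $\kappa_2$
(pyrimidine). The generator is scaled to one expected substitution per
site per time unit, and $P(t)$ is evaluated in closed form; tests verify
it against a numerical eigendecomposition of the generator at $10^{-12}$,
and against the JC69 closed form in the degenerate case. Base frequencies
are fixed at their empirical (pseudo-counted) values by default; an
explicit $\pi$ can be supplied. Neither gamma rate heterogeneity nor
partition models are implemented — the target data are single-locus SNP
haplotypes.

**Likelihood.** Felsenstein pruning over site patterns, rescaled per
pattern, with the inner loop in C++ (a pure-R reference implementation of
the same recursion is kept and cross-checked at $3\times 10^{-15}$).
An optional ascertainment correction divides each site's likelihood by
one minus the probability of a constant site, for matrices from which
invariant columns were removed. It is **off by default**: the workflow
this package mirrors analyzes the extracted variant matrix directly, so
reproducing that behaviour takes precedence, but the corrected likelihood
is one flag away. The practical consequence of leaving it off is that
branch lengths (in substitutions per variant site) are inflated by
roughly the inverse variant fraction; node *allele* identities are
affected much less than node heights.

**Tree prior.** Constant-size coalescent over rooted time-trees with
contemporaneous tips; density per interval $-k(k-1)\tau/2N$ and $-\log N$
per coalescence, validated against closed forms for $n = 2, 3$. With no
dating information the mean clock rate is fixed at 1, so heights are in
expected substitutions per site and $N$ shares that unit: absolute time
is not identified and not reported.

**Clock.** Strict by default. The relaxed clock is the discretized
uncorrelated-lognormal variant: each branch carries one of $k$
equal-probability quantile midpoints of a mean-1 lognormal with fixed
$\sigma$ (default: one category per branch). The discretization keeps the
MCMC state finite; $\sigma$ is not sampled. The strict default is used
throughout the tests because the allele-enumeration logic depends on
branch lengths only weakly.

**MCMC.** Metropolis–Hastings with node-height slides, a root-height
scale, a whole-tree scale (Hastings $s^{k}$ for $k$ scaled heights),
narrow and wide subtree exchanges, multiplier scalers for $\kappa_1,
\kappa_2, N$, and (relaxed clock) branch-category reassignment. Proposal
step sizes were fixed once to put acceptance rates in the 0.25–0.6 band.
Priors on $\kappa_1, \kappa_2$ are lognormal(1, 1.25) and on $N$
lognormal(1, 2) — deliberately weak, and exposed as configuration because
the analysis this mirrors did not state its priors. An outgroup, when
present, is constrained to attach at the root (proposals violating the
constraint are rejected), which roots the ingroup. Correctness evidence:
on 4-taxon, 1-site data with fixed scalars, posterior topology-class
frequencies match a prior-predictive importance-sampling oracle within
0.05; with symmetric data the class frequencies are uniform.

**MCC summary.** Among sampled trees, the one maximizing the sum of log
clade supports (equivalently the product of supports; ties to the
earliest sample). Node identity across trees is the *ingroup taxon set*
(clade key); node heights are annotated as the clade's mean height across
the samples containing it, clamped to preserve parent–child order. When
an outgroup hangs at the root, the global root and the ingroup MRCA share
a clade key; the lower node is used consistently.

**Ancestral alleles.** Per posterior sample, one joint stochastic
backtrace: the root state is drawn from its marginal posterior per site
and children are drawn conditionally downward; the node's allele is the
concatenation of its per-site draws. Per MCC clade, draws are tallied
over exactly the samples whose tree contains the clade, so posteriors are
conditional on clade presence — this is also why one allele can be the
best ancestor at two nodes with different posteriors. The joint tally is
the primary estimator; a product-of-per-site-marginals enumerator
(`enumerate_marginal_ancestors()`, floor $10^{-6}$) is provided as a
secondary estimator that ignores across-site dependence induced by
topology uncertainty. Tests verify the backtrace marginals against
exhaustive enumeration and the inside-outside recursion at $3$ SE over
$10^4$ draws. Ties anywhere resolve to the lexicographically smallest
states string, for determinism.

**Catalogue.** Every tallied (allele, clade) pair at or above the
threshold (default export floor 0.10) becomes an entry with
observed/predicted status; a by-states view deduplicates to each
allele's maximum posterior. Letter labels (A, B, …) are assigned by
preorder over MCC nodes with support ≥ 0.5 — cosmetic metadata, not a
contract.

**Phasing.** A pair of templates explains a genotype when the unordered
state pair matches at every non-missing site. The search is linear: each
template forces its complement site-wise, which is looked up (with
missing sites present, an exhaustive pair scan replaces the lookup, since
the complement is then under-determined). Scores are $w(a)\,w(b)$ with
$w = 1$ for observed templates and $w$ = catalogue posterior for
predicted ones — including the product for two predicted templates, which
is the natural extension when no frequency model exists; optional
population frequencies could multiply the weights but none are assumed.
Confidence is the top score over the sum of scores; no minimum reportable
confidence is enforced. Missing genotype sites (`N`) constrain nothing —
an extension beyond the motivating workflow. `flag_novel()` computes
forced complements of compatible templates, ranks candidates by Hamming
distance to the nearest catalogue entry, handles the fully homozygous
case directly, and refuses to guess when every template conflicts at more
than half of the heterozygous sites. `update_catalogue()` inserts or
promotes a confirmed allele idempotently, closing the loop.

## The synthetic-data generator

`make_study_fixture()` emulates the structure of a verified long-gene
allele set: `n` contemporaneous ingroup alleles on a constant-size
coalescent genealogy, one divergent outgroup grafted above the root
(`stem_factor` times the ingroup TMRCA), and TN93 sequences
(default $\pi = (0.27, 0.23, 0.22, 0.28)$, $\kappa_1 = 4$,
$\kappa_2 = 8$ — transition-biased, as typical for genomic SNP sets)
whose per-site rate is calibrated to the realized genealogy length so the
*expected* ingroup variant-site count hits a target (default 48 alleles,
21,406 sites, 72 variants; the realized count is Poisson-distributed
around the target, and the preset contract asserts the 60–90 band at the
default seed). Every ancestral sequence and the true root allele are
recorded. Multiple hits are allowed, matching the inference model; a
`max_one_change` mode conditions each site on at most one mutation event
for clean oracle tests.

What the generator does *not* emulate: population structure and sampling
bias across populations, recombination, gene conversion, sequencing
error, and the empirical haplotype-frequency skew of real cohorts
(a handful of common haplotypes plus rares). Passing recovery tests on
these fixtures therefore shows the estimator is *correct under its own
model*, not that real-data posteriors are calibrated.

## Study designs used by the tests and acceptance script

Problem sizes were chosen as the smallest that leave the scientific
checks meaningful:

* **Replicate recovery** (credible-interval coverage of $\kappa_1 = 4$
  and modal root-allele recovery): 20 replicates of 20 alleles ×
  200 sites with ~12 expected variant sites and `stem_factor = 1.25`,
  chains of 20,000 generations; the *full* 200-column matrix is analyzed.
  Two deliberate features: (i) the full matrix, not the extracted variant
  sites, because without ascertainment correction a variant-only matrix
  of this size inflates branch lengths ~20-fold and smears the root
  draws; (ii) a short outgroup stem and sparse variants, because at 200
  sites a study-like outgroup divergence would mutate the outgroup at a
  substantial fraction of the variant sites and mis-polarize the root —
  an artifact of scale-down, not of the method. Even so, a residual
  share of replicates has an outgroup- or stem-mutated site that makes
  the true root state genuinely unrecoverable; the ≥80% recovery bar
  absorbs it.
* **End-to-end recovery**: 10 replicates of the reduced preset
  (20 alleles, 2,000 sites, ~30 variants, `stem_factor = 2`) through the
  FASTA → extract → infer → tally → catalogue path; the true root allele
  must rank in the top 3 of the *root clade's* entries. Ranking within
  the clade, not globally, is the meaningful check: global ranking is
  dominated by shallow clades whose ancestors are near-certain.
* **Study-scale synthetic run** (acceptance script): the full preset with
  2 chains × 60,000 generations — a scaled-down surrogate of a
  multi-run, tens-of-millions-of-generations analysis, reported with its
  ESS rather than claimed converged.

## Numerical choices and degenerate inputs

* Per-pattern rescaling by the column maximum in the pruning recursion;
  an all-zero column (impossible pattern) propagates to a $-\infty$
  log-likelihood rather than an error.
* Zero-length branches are legal ($P(0) = I$); the UPGMA initial tree
  enforces a minimum parent–child separation so the chain never starts
  on a degenerate height.
* A zero-variant alignment yields an empty matrix with a warning, not an
  error.
* ESS uses Geyer's initial-positive-sequence truncation; a constant
  trace warns and reports the trace length.
* Thresholds: catalogue export ≥ 0.10 by default; node-label support
  floor 0.5; novel-candidate refusal above 50% heterozygous-site
  conflict. Ties always break to the lexicographically smallest string.

## Known limitations

* No recombination: alleles are treated as clonal haplotypes; a
  recombinant allele enters the catalogue as a plain entry and will
  simply fit the tree poorly.
* No ambiguity codes or partial gaps in input alignments.
* The relaxed clock's $\sigma$ is fixed, not sampled, and absolute time
  is not identified.
* Catalogue posteriors are conditional on clade presence and on the MCC
  tree's clade set; alleles ancestral to clades absent from the MCC tree
  are not enumerated.
* Phasing assumes full linkage across the variant sites of the locus and
  no template frequency information.
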