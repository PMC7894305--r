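---
title: "Inferring two-population divergence histories from the joint SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring two-population divergence histories from the joint SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointsfs)
```

# The problem

Closely related marine populations are often partitioned along depth
gradients. Whether such pairs diverged in the face of continuous gene flow,
or passed through episodes of isolation before renewed contact, leaves a
signature in the joint site frequency spectrum (SFS): the matrix of SNP
counts indexed by the derived-allele count in each population. `jointsfs`
implements the full inference chain from a multi-sample genotype VCF to a
ranked set of two-population demographic models: deterministic SNP
filtering, outgroup polarization, hypergeometric projection, a moment-based
engine for expected spectra, Poisson composite-likelihood fitting,
nonparametric SNP bootstrap, and AIC-based model selection.

# The demographic model space

A model describes an ancestral population (optionally with one pre-split
size change, `nuA` for a duration `TA`) that splits into two populations
evolving through 1–3 epochs. Within an epoch everything is constant: sizes
`nu1`, `nu2` relative to the reference size `N_ref`, and migration `m12`
(into population 1) and `m21`, in population-scaled units `2 N_ref m`
(`m` = fraction of a population replaced by immigrants per generation).
Time is measured in units of `2 N_ref` generations. Sizes are constant
within epochs; growth is represented by stepwise changes at epoch
boundaries, which matches the epoch-level statements the model ids encode
("the deep form contracted while the shallow expanded") without adding
per-epoch growth-curve parameters.

Models may also split loci into two classes: a genomic-island class
holding a fraction `P_e` of loci in epoch `e`, inside which both migration
rates are multiplied by a factor `b` in `[0, 1]`. This represents regions
of reduced effective gene flow (linked selection, rearrangements) as a
migration mixture, without modelling selection itself. One `b` is shared
across epochs while `P_e` is free per migration epoch, so the island
fraction can grow or shrink through time, which is exactly the quantity of
interest when contrasting early and recent exchange. The mixture is
applied at epoch boundaries: the state at the end of epoch `e` is
`(1 - P_e) * [state evolved at m] + P_e * [state evolved at b m]`, both
branches starting from the mixed state at the epoch's start. This keeps
the computation linear in the number of epochs; its degenerate limits
(`P = 0`, `b = 1`, or `P = 1, b = 0`) collapse exactly to the corresponding
single-class models, and the test suite pins all three identities.

The shipped catalog (`catalog_list()`) holds exactly 107 models: a
systematic grammar enumeration (1–2 post-split epochs with and without an
ancestral size change, 3 epochs without; every per-epoch migration pattern
in {none, symmetric, asymmetric}; the island mixture wherever at least one
epoch has migration; the triple-isolation structure `e3_nnn` omitted as
redundant with its 1- and 2-epoch analogues) plus eleven names in
circulation in the gene-flow literature (`sc3ielsm1`, `iMi`, `IMisc`, ...),
whose structures are fixed aliases reconstructed from their published
descriptions. Where two names circulate for the same 3-epoch
secondary-contact structure, both are included. `model_grammar_parse()`
documents the grammar; custom models are accepted through
`demographic_model()` or a YAML file in the shipped catalog format.

# The engine

`expected_sfs()` computes the expected unfolded joint SFS per unit
`theta = 4 N_ref mu L` by evolving the sample-spectrum moments directly:

* Drift is exactly closed at the sample order: the expectation of the
  Bernstein-polynomial moments of the population frequency obeys a
  tridiagonal linear system along each population axis.
* Mutation enters the single-derived-copy classes at constant rate
  (infinite sites, no back mutation). The stationary balance of these two
  terms gives the classical `theta / i` spectrum, which the engine
  reproduces to machine precision because the equilibrium is obtained by a
  direct linear solve.
* Migration couples the populations through terms one sample-order higher
  in the donor population. These are closed with an order-raising
  estimator: each raised entry is a weighted sum of nearby entries, exact
  for any underlying density that is locally cubic plus a `1/x` component
  (the quasi-stationary low-frequency shape under mutational influx), with
  the fit augmented by a boundary point mass near fixation, where spectra
  carry (quasi-)fixed mass that no polynomial density represents. These
  basis choices matter: without the atom and `1/x` terms the fixed-derived
  edge and the rare-shared corner of the spectrum are visibly biased
  against coalescent simulations.

Within an epoch the system is linear with constant coefficients, so each
epoch is integrated by Crank–Nicolson steps with one banded LU
factorization reused across steps. Numerical controls live in
`sfs_engine_control()`: the step `dt` (default 0.002 time units; fitting
uses 0.02 for speed), a minimum step count, and `buffer` — the number of
extra alleles per population at which the system is integrated before
exact hypergeometric projection down to the requested sizes (default 2;
oracle-grade comparisons use 6). Spectrum entries are clipped at zero
below a relative tolerance (`neg_tol`), and an error is raised if
negativity exceeds it; likelihood evaluations floor model entries at
1e-300 to avoid infinite logs from roundoff.

Accuracy was validated against independent structured-coalescent
simulations (msprime, branch-mode allele frequency spectra, one million
replicate genealogies per demography) across strict-isolation,
isolation-with-migration, secondary-contact, ancestral-size-change and
island-mixture histories: every unmasked entry agrees within three
Monte-Carlo standard errors at samples of six alleles per population
(the acceptance suite re-runs this check).

# Likelihood, fitting and ranking

Unmasked spectrum entries are treated as independent Poisson counts with
mean `theta * model` (composite likelihood; linkage between SNPs is
ignored, which the SNP bootstrap compensates for at the uncertainty
level). The scale `theta` is profiled analytically
(`theta_hat = sum(data) / sum(model)`), so models are fit per-theta. A
multinomial alternative would condition on the total count; the Poisson
form is the default because it also uses the information in the total.

`fit_model()` maximizes over log-transformed parameters with a bounded
quasi-Newton search from `n_starts` initializations (default 10, the
protocol's "at least 10 runs"). Starts are drawn log-uniformly across the
full parameter bounds rather than only near the bound midpoints: island
and migration surfaces are multimodal, and in calibration runs
midpoint-local starts repeatedly stranded the search on flat migration
ridges several log-likelihood units below the optimum, while full-range
starts found it reliably. Starts are triaged: every start gets a quarter of the
iteration budget, and only the leading few (`n_refine`) continue to the
full budget — the usual successive-halving economy. After the best start
is chosen the search is restarted from the incumbent until the
log-likelihood stops improving (restarting resets the limited-memory
Hessian). The default bounds put the
geometric midpoints at representative magnitudes (times ~0.3, sizes ~1,
scaled migration ~1, island fraction ~1%); bounds are per-model
configurable, and a fit ending on a bound is flagged in the result.

`rank_models()` implements information-theoretic selection: AIC
(`2k - 2 LL`; plain AIC, matching the reported protocol — AICc is a
one-line change at the caller), AIC differences, relative likelihoods
`exp(-dAIC/2)`, Akaike weights, and the evidence ratio of the best model
over each competitor. Evidence ratios are computed in log space, so
magnitudes of `1e40` or `1e300` and beyond are reported exactly through
`log10_evidence_ratio` without floating-point overflow.

`bootstrap_fits()` resamples SNPs (not individuals) with replacement to
the original site count, rebuilds the spectrum and refits — the
nonparametric uncertainty used for date estimates. Five replicates is the
protocol default. `scale_to_natural_units()` converts a fit to
individuals and years via `N_ref = theta_hat / (4 mu L)`: a duration `T`
spans `2 N_ref T gen_time` years, and scaled migration converts to both
the per-generation replacement fraction and immigrants per generation.
The mutation rate (1.02e-9 per site per generation) and generation time
(5 years) used throughout the examples are the octocoral values; the
effective sequence length `L` behind the SNP set is a required user input
because it cannot be recovered from a thinned SNP table.

# The filter chain

`site_filters()` applies, in a fixed and logged order: (1) removal of
SNPs within 30 bp of an indel's reference footprint; (2) restriction to
biallelic SNPs; (3) masking of genotypes with depth < 5 (vcftools
per-genotype `--minDP` semantics — the protocol's depth threshold is
applied per genotype, and the choice is recorded in the report);
(4) site quality >= 30; (5) at least 90% of genotypes called per
population (the vcftools reading of "max-missing < 0.9"; the literal
reading would discard well-genotyped sites); (6) allele balance on reads
pooled over heterozygous genotypes (each allele >= 20%, the vcflib
convention, rather than per-genotype); and (7) an exact two-sided
Hardy–Weinberg test within each population at p < 0.001, dropped if either
population fails. The HWE test sums the probabilities of all heterozygote
configurations no more probable than the observed one (no mid-p), and the
test suite checks it against full enumeration of allele placements for
up to ten diploids. Individuals genotyped at fewer than half the sites
are removed before any site-level rule. `thin_sites()` keeps the first
SNP per scaffold and then the next one at least 1000 bp away (greedy,
position order, deterministic). `polarize()` assigns derived states from
an outgroup allele supplied per site or as an `AA` INFO tag; sites where
the outgroup carries a third state or no state are dropped and counted.

# The synthetic-data generator

`simulate_vcf()` draws independent locus genealogies from a
structured-coalescent simulation of the same model class the engine
integrates (piecewise sizes, per-epoch migration, optional ancestral size
change), places Poisson mutations on lineages, and writes standard VCF
with `GT:DP:AD` fields, an outgroup column, per-site quality, negative
binomial depth (zero-truncated, so depth-missingness is controlled solely
by the missingness knob) and random missingness. The default design
mirrors the motivating study: 27 + 32 diploids. Island loci are a
locus-level class simulated with migration scaled by `b`. The outgroup
carries the true ancestral allele by default (a divergent outgroup with no
shared polymorphism); a polarization error rate knob exists and defaults
to zero. What the generator does not emulate: linkage within loci beyond
shared genealogy, selection, sequencing error in genotype calls, allele-
balance artefacts, or reference bias — so passing recovery tests show
correctness of the inference machinery under the model's own assumptions,
not robustness to those artefacts.

`fixture_vcf()` is a hand-built 15-record VCF (two populations of twelve
diploids plus one deliberately under-sequenced individual) in which every
record passes the whole chain or violates exactly one rule, with a
manifest of expected outcomes; twelve diploids per population is the
smallest size at which the exact HWE test can breach p < 0.001.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run everything at reduced scale
chosen to exercise the mathematics rather than reproduce any published
dataset: oracle comparisons at six alleles per population with 1e6
coalescent replicates; parameter recovery on ~15,000-SNP spectra at 16
alleles per side over ten seeds (twelve alleles proved too coarse: the
island mixture then biases migration-rate estimates along a likelihood
ridge, an identifiability floor rather than an implementation defect) (a secondary-contact history with an
island class — split time and contact-epoch migration rates are the
recovery targets); model-selection power at 8 alleles and ~8,000 SNPs;
and the end-to-end acceptance run simulates a 59-colony cohort at 1,500
loci and projects to 16/20 alleles. At these scales migration rates are
identifiable when the true scaled rates are of order one; strongly
saturated rates (scaled rates well above ~3 with long contact) are
recoverable only as "large", which is a property of the SFS itself rather
than of the implementation.

# Known limitations

* Two populations only; no linkage-aware spectra; no selection terms —
  islands are purely a migration mixture.
* The composite likelihood treats SNPs as independent; standard errors
  must come from the SNP bootstrap, not from the likelihood curvature.
* The migration closure is approximate (exact only for locally
  cubic-plus-`1/x` densities); accuracy improves with the `buffer`
  control and has been validated at the sample sizes above. Extremely
  large scaled migration rates (> ~30) with tiny samples are outside the
  validated envelope.
* The folded-spectrum utilities are diagnostic; the inference path
  assumes polarized data.
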