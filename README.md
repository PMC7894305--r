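# jointsfs

Demographic inference for a pair of diploid populations from the unfolded
joint site frequency spectrum (SFS). The package targets the common
population-genomic question for depth- or habitat-segregated population
pairs: did they diverge with continuous gene flow, or through episodes of
isolation followed by secondary contact — and how much of the genome sits
in "islands" of reduced exchange?

It covers the whole chain from a called multi-sample VCF to ranked
demographic models in natural units:

* **Filtering** — deterministic SNP filters with per-rule logging:
  biallelic SNPs, per-genotype depth, site quality, per-population
  missingness, pooled allele balance, an exact Hardy–Weinberg test within
  each population, indel proximity, physical thinning, and removal of
  under-sequenced individuals.
* **Polarization and spectra** — outgroup-based derived-allele assignment,
  hypergeometric projection to absorb missing data, dadi/moments-format
  SFS files, folding, marginals, nucleotide diversity, Fst.
* **Model catalog** — 107 two-population models: 1–3 epochs, per-epoch
  symmetric/asymmetric/no migration, optional ancestral size change, and a
  genomic-island migration mixture (fraction `P_e` of loci with both
  migration rates scaled by `b`).
* **Engine** — expected joint SFS under any catalog model by direct
  integration of the sample-spectrum moment system: exactly closed drift,
  infinite-sites mutation influx, and migration closed by an order-raising
  estimator with boundary-atom and `1/x` basis terms; Crank–Nicolson steps
  with banded LU factorizations. Validated entry-by-entry against
  million-replicate coalescent simulations.
* **Inference** — Poisson composite likelihood with the scale
  `theta = 4 N_ref mu L` profiled analytically, multi-start bounded
  quasi-Newton fitting on log-parameters, nonparametric SNP bootstrap,
  and AIC ranking with Akaike weights and overflow-safe evidence ratios.
* **Scaling** — conversion of fitted parameters to individuals and years
  via `N_ref = theta_hat / (4 mu L)`, epoch boundaries in years BP,
  migration as replacement fractions and migrants per generation.
* **Synthetic data** — a structured-coalescent simulator writing standard
  VCF with depth/quality/missingness and an outgroup column, plus a
  hand-built fixture VCF that pins every filter rule.

The model, likelihood and time conventions follow the standard
diffusion/moment framework for joint-SFS inference: time in units of
`2 N_ref` generations, sizes relative to `N_ref`, migration in units of
`2 N_ref m`, expected spectra per unit `theta`.

## Worked example

Simulate a 20-colony cohort under secondary contact (isolation, then
renewed symmetric exchange), filter it, build the spectrum, and rank three
competing histories:

```r
library(jointsfs)
model <- demographic_model("e2_ns", c("none", "sym"))
truth <- c(T1 = 0.5, nu1_1 = 1, nu2_1 = 1.2, T2 = 0.1, nu1_2 = 2,
           nu2_2 = 1.5, m2 = 3)
cfg <- sim_config(model, truth, n_dip1 = 10, n_dip2 = 10, n_loci = 800,
                  theta_locus = 0.5, miss_rate = 0.03, seed = 42)
sim <- simulate_vcf(cfg)
res <- filter_pipeline(sim$vcf, sim$populations, sim$outgroup,
                       filter_config(thin_bp = 1))
res$report$site_filter_log
#>                  rule dropped retained
#> 1     indel_proximity       0     2832
#> 2       biallelic_snp       0     2832
#> 3 genotype_depth_mask       0     2832
#> 4        site_quality     174     2658
#> 5     pop_missingness     434     2224
#> 6      allele_balance      18     2206
#> 7           hwe_exact       0     2206

sfs <- build_sfs(res$sites, 14, 14, L_effective = 800 * 500)
fst_sfs(sfs)
#> [1] 0.127

ctl <- fit_control(n_starts = 4, maxit = 45)
fits <- list(
  fit_model(sfs, model, seed = 1, control = ctl),
  fit_model(sfs, demographic_model("e2_nn", c("none", "none")),
            seed = 1, control = ctl),
  fit_model(sfs, demographic_model("e1_s", "sym"), seed = 1, control = ctl))
rank_models(fits)[, c("model", "k", "LL", "AIC", "dAIC", "weight")]
#>   model k        LL      AIC      dAIC       weight
#> 1 e2_ns 7 -327.7012 669.4024   0.00000 1.000000e+00
#> 2  e1_s 4 -348.7320 705.4639  36.06155 1.476839e-08
#> 3 e2_nn 6 -412.9307 837.8615 168.45910 2.627673e-37
```

The true secondary-contact history wins decisively: strict isolation
(`e2_nn`) is 168 AIC units behind and continuous migration (`e1_s`) 36
behind, i.e. an evidence ratio near `7e7` against the best alternative.
Converting the winning fit to natural units with the octocoral mutation
rate (1.02e-9 per site per generation) and a 5-year generation time:

```r
best <- fits[[1]]
scale_to_natural_units(best, mu = 1.02e-9, gen_time = 5, L = 800 * 500)
#> Model 'e2_ns': N_ref = 186294 individuals, split 1112287 years BP
#>   epoch start_years_bp end_years_bp     N1     N2 ... m12_migrants_per_gen
#> 1     1        1112287        92737 241942 247541 ...              0.00
#> 2     2          92737            0 298268 220464 ...              4.14
```

The fitted split time corresponds to a scaled divergence of 0.60 in units
of `2 N_ref` generations — the generating truth was 0.60 — with the
isolation epoch ending and gene flow resuming 93 kyr BP (truth: epoch
boundary at one-sixth of the divergence time).

A thin command-line wrapper over the same functions is installed as
`exec/jointsfs` with subcommands `simulate`, `filter`, `build-sfs`, `fit`,
`select`, `bootstrap` and `report`; every run writes its resolved options
next to its outputs.

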