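---
title: "Harmonizing and analyzing maternal-transfer concentration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing and analyzing maternal-transfer concentration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovotransfer)
```

## The problem

Oviparous reptiles offload part of their accumulated burden of organic
pollutants — PCBs, organochlorine pesticides, flame retardants, PFAS and
others — into their eggs during vitellogenesis. Published measurements of
this maternal transfer are scattered across decades of studies that report
concentrations in different units (ng/g, µg/kg, ppm, ...), on different
measurement bases (wet weight, dry weight, lipid weight), in different
maternal tissues, and with very different treatment of values below the
analytical limit of detection (LOD). Before any cross-study analysis, all of
this has to be put on one scale without destroying information — in
particular without discarding or fabricating censored observations.

`ovotransfer` implements that homogenization as a tested pipeline, together
with the downstream statistics used to describe maternal transfer: log10
offspring:mother partition ratios, ten-fold equilibrium banding,
tissue–tissue concentration correlations, and partition-ratio trends against
the octanol–water partition coefficient (log Kow, the standard lipophilicity
proxy).

## The harmonization model

Every observation is converted to ng/g and expressed on two bases:

* **wet weight**: unit conversion, preceded (for dry-basis data) by
  `conc_wet = conc_dry × (1 − water_fraction)` — the analyte mass is
  unchanged while the reference mass regains the tissue's water. The default
  water content for sea-turtle eggs is 66.7%, the value reported for
  *Chelonia mydas* eggs.
* **lipid weight**: `conc_lw = conc_wet / lipid_fraction`. Lipid
  normalization makes lipophilic burdens comparable across tissues as
  different in composition as adipose tissue (~60% lipid) and blood plasma
  (<1% lipid). The lipid fraction follows a strictly ordered fallback chain:
  the value reported in the study itself, then a literature value for the
  same species and tissue, then a value for a closely related species (via
  an explicit, editable relatedness map), with the chosen source recorded on
  every record. Records with no lipid source at any level stay wet-weight
  only, with a diagnostic.

All factors are exact rational scalings, so round-trips are reproducible to
floating-point precision; the package's invariant checks use a 1e-9 relative
tolerance. The dry→wet step always precedes lipid normalization, and the
applied steps are recorded per record in a `conversion_trace`. Crucially,
the LOD of a censored observation is transformed by the *identical* composed
map as the value, so a quantitatively censored observation remains the
interval `[0, LOD]` on every basis, and the censoring-status multiset is
invariant through harmonization.

Censoring is three-state: `uncensored` (a measured value),
`quant_censored` (below a *known* LOD — still quantitative information), and
`qual_censored` (below an *unknown* LOD — no quantitative information). LOD
and LOQ are deliberately treated as a single threshold. The pipeline never
imputes censored values: they enter counts and audits, never ratios or
correlations.

## Inclusion, exclusion and aggregation rules

Three exclusion rules are applied with total accounting (every input record
ends up in exactly one of the kept or excluded sets, with a reason code):
bile concentrations (bile is a liver product of highly variable
composition); sums of compounds whose members are all reported individually
in the same study (pure duplication — a sum contributing any unreported
member is kept); and records flagged as measured outside the instrument's
calibration range. The calibration flag is an explicit input column: a
reanalysis cannot re-derive instrument calibration, so the decision is data,
not code. Duplicate-sum detection is scoped per study, matching the notion
of "already reported individually" within one publication.

Where a study reports only group-level data, the geometric mean is
preferred, falling back to the arithmetic mean when a geometric mean is not
derivable (any zero member), with the pooled count recorded. Individually
reported data always take priority; a reported group statistic is stored
verbatim with its aggregation label rather than back-converted.

## Molecular descriptors and their provenance

Descriptors (log Kow, molecular weight, complexity, heavy-atom count,
H-bond donors/acceptors, TPSA, formal charge, rotatable bonds) are consumed
from local snapshot tables, never live queries. log Kow follows the policy:
experimental value when available, otherwise the model estimate, otherwise
an explicit override entry (the route for chlorinated paraffins, absent from
the usual model exports); the provenance of the chosen value is always
recorded. Two special cases get their own rules:

* **Coelutions** (compounds inseparable by the analytical method) receive a
  descriptor only if every member yields the same value — exactly for
  integer descriptors, within 1e-6 absolute for real ones, a tolerance we
  fix explicitly because "the same value" needs one. Named override entries
  (e.g. an experimentally derived log Kow for a specific congener pair) take
  precedence.
* **Sums** of compounds never receive descriptors, even when members match:
  a sum aggregates distinct analytes, so no single structure underlies it.

Complexity is treated as an opaque supplied number; which definition the
upstream database used at extraction time is unknowable from here, and
nothing in the pipeline depends on it.

## Transfer statistics

Pairs are formed per (study, mother, compound, maternal tissue, offspring
matrix) through an explicit mother-identifier link. Whether replicate eggs
of a clutch are analyzed individually (`per_egg`) or first collapsed to the
geometric mean of their uncensored values (`clutch_mean`) is a configuration
switch, because published scatterplots rarely state which convention they
use.

The partition ratio is `R = log10(c_offspring / c_mother)`: 0 is the
lipid-normalized equilibrium, ±1 a ten-fold deviation. Only pairs with both
sides uncensored and strictly positive yield a ratio; everything else is
skipped with a recorded reason. The ten-fold band is closed (`|R| ≤ 1`
counts as within), the conservative reading of "within a 10-fold
deviation". Group summaries use type-7 (linear-interpolation) quartiles —
stated explicitly so an independent implementation can match them — with
whiskers at 1.5 × IQR clamped to the most extreme observations inside the
fences.

Tissue correlations are computed over co-measured (same mother, same
compound, both uncensored) log10 lipid-normalized concentrations. Published
summaries of such correlations usually do not name the coefficient, so
Pearson is reported as primary with Spearman alongside; pairs with fewer
than `min_pairs` (default 10) co-measurements are omitted rather than
reported on thin evidence. Ratio–log Kow relations are summarized per group
by the OLS slope with its standard error, plus the Spearman rank
correlation; groups with fewer than five ratios are flagged, and a group
with no log Kow variation gets an explicitly undefined slope rather than a
number.

PFAS are amphiphilic — they bind protein as much as lipid — so they are
analyzed on the wet-weight basis in addition to the lipid basis used for
everything else; protein normalization is out of scope. The PFAS switch
adds tables and never alters non-PFAS output.

## The synthetic-data generator

Real deposited databases are external inputs; every pipeline stage is
instead validated against a seeded generator whose ground truth is known.
Its model:

* mother log10 concentration (lipid basis) `~ Normal(mu_m, sigma_m)`, one
  latent draw per mother × compound, plus a `Normal(0, sigma_t)` deviation
  per maternal tissue — this shared latent is what makes maternal tissues
  strongly correlated, as they are in equilibrium-partitioning physiology;
* offspring: `log10 c_egg = log10 c_mother + alpha + beta·log_kow +
  Normal(0, sigma_e)` per egg;
* each study declares its own unit and basis (wet/dry/lipid, with true
  tissue lipid and water fractions), which the generator encodes into the
  emitted records so harmonization must undo them exactly;
* censoring: each compound's LOD sits at the `q_lod` quantile of the
  record's own lognormal distribution, so the expected censored fraction is
  `q_lod`; a censored record hides its LOD with probability `p_qual`;
* a clutch whose eggs are all uncensored is reported as a pooled geometric
  mean with probability `p_pool`.

The default fixture mirrors the shape of the compiled reptile literature:
two data-rich "flagship" studies with many maternal tissues (a freshwater
turtle and a snake), several species with whole-egg-only data including a
dry-basis sea-turtle study, heterogeneous units across studies, roughly 70%
censoring split about evenly between quantitative and qualitative, and a
compound set spanning PCB congeners, organochlorine pesticides, a
brominated flame retardant and one PFAS (log Kow 4.5–7.4). Defaults
`mu_m = 1.5`, `sigma_m = 0.6` (log10 ng/g lipid), `sigma_t = 0.1`,
`alpha = −0.1`, `beta = 0`, `sigma_e = 0.3`, `q_lod = 0.7`,
`p_qual = 0.5`, `p_pool = 0.2` were chosen once as field-realistic
magnitudes: concentrations spanning ~2–3 orders of magnitude, tissue
correlations near 0.9, ratios mostly within the ten-fold band with mild
retention in the mother.

What the generator does **not** emulate: toxicokinetics over time, embryo
development, inter-compound correlation structure beyond log Kow,
measurement error distinct from biological variation, and reporting
pathologies like digitization error. Passing tests therefore demonstrate
correctness of the pipeline's accounting and estimators under a clean
generative model, not robustness to every artifact of real literature data.

## Validation design and problem sizes

Unit conversion is checked against an independent oracle that derives each
factor from SI prefix exponents rather than a lookup table. Quantile-based
summaries are checked against a from-first-principles order-statistics
oracle. End-to-end checks use these problem sizes, chosen to give tight
Monte-Carlo error while keeping the default suite fast: transfer-offset and
slope recovery use one study of 200 mothers × 2 eggs × 7 PCB congeners
(2,800 ratios; the median's Monte-Carlo error is ~0.005, well inside the
±0.05 recovery band), with censoring and pooling off so every pair
contributes; censoring-rate recovery uses the full default fixture
(~3,500 records).

One subtlety in the censoring-recovery check: with the default shared
maternal latent, censoring indicators are *clustered* (a high mother drags
all her tissues and eggs over the LOD together), so the binomial variance
formula understates the spread of the observed fraction even though it is
unbiased. The recovery scenario therefore sets `sigma_m = 0` and carries
all variation in the independent tissue- and egg-level terms, which makes
censoring events genuinely independent Bernoulli draws — the regime in
which a binomial-bounds check is statistically well-posed.

## Degenerate inputs and numerical choices

* Unknown tissue or unit tokens quarantine the row with a diagnostic;
  nothing is coerced or silently dropped.
* A measured value together with a below-LOD flag is an error, not a guess.
* Qualitatively censored records carry no numeric fields at all after
  harmonization; their censoring state survives untouched.
* `water_fraction ≥ 1`, `lipid_fraction ∉ (0, 1]` are hard errors.
* Geometric means of sets containing zero fall back to the arithmetic mean
  with a diagnostic.
* All pipeline randomness flows through one seed; generation restores the
  caller's RNG state.

## Known limitations

* Censored values are audited, never modeled (no substitution, MLE or
  Kaplan–Meier estimation under censoring — deliberately out of scope).
* The species-relatedness fallback is only as good as the supplied map;
  the shipped default covers the handful of species in the synthetic
  fixture.
* Whether a literature lipid fraction was measured on a wet or dry basis is
  not always recoverable from sources; the pipeline interprets lipid
  fractions on the same basis as the concentration at the moment of
  normalization, which is the convention implied by normalizing after
  dry→wet conversion.
* No mixed-effects or phylogenetic modeling of ratios; the summaries here
  are descriptive.

## A worked run

```{r, eval = FALSE}
dir <- tempfile()
sim <- run_simulate(synthetic_config(seed = 1), out_dir = dir)
cfg <- pipeline_config(
  study_tables = sim$paths$study_tables,
  lipid_table = sim$paths$lipid, water_table = sim$paths$water,
  property_table = sim$paths$property, relatedness = sim$paths$relatedness,
  out_dir = file.path(dir, "out"), seed = 1)
res <- run_analyze(cfg)
res$tissue_correlation_summary
```
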