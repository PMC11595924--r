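---
title: "Methods: PEG-6000 drought screening statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PEG-6000 drought screening statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegscreen)
```

This vignette documents the statistical model behind `pegscreen`, the
parameters of every stage, what the synthetic-data generator does and does
not emulate, and the design decisions baked into the defaults.

## Study design and data model

A screen is a long table with one row per measurement:
`accession` × `treatment` × `replicate` × `trait` × `value`. Treatments are
`T0` (0 % PEG-6000, the control), `T1` (7.5 %) and `T2` (15 %);
`study_table()` also accepts the PEG percentages directly. Twelve traits are
known to `trait_descriptors()`:

* morphological: GP (germination, %), RL and SL (root/shoot length, cm),
  FW (fresh weight, mg), DW (dry weight, g);
* biochemical: PC (proline, µg/g), SSC (soluble sugars, mg/g), TPC (total
  phenolics, mg GAE/g), AC (ascorbate, µg/g), GPA (glycine betaine, µmol/g),
  CAT (catalase, U/g), LP (lipid peroxidation, nmol MDA/g).

LP is the only trait where *lower* is better; everything else is
higher-is-better. GP is validated to `[0, 100]` and, when produced by the
generator, lives on the grid `100 * k / seeds_per_dish`.

The design is assumed **balanced**: every accession × treatment cell has the
same number of replicates. `two_way_anova()` enforces this and refuses
unbalanced input rather than silently switching to a different
sums-of-squares type.

## ANOVA

`two_way_anova()` computes the classical balanced factorial decomposition
from cell means: accession, PEG level, their interaction, error and total.
The implementation is closed-form rather than a wrapper, so the test suite
can verify exact additivity (`SS_A + SS_B + SS_AB + SS_E = SS_T` to a
relative 1e-9) and compare every stratum against `stats::aov` as an
independent oracle. `one_way_anova()` covers the completely randomised
designs used for class comparisons.

Degenerate inputs (zero within-group variance) are not errors: the fit is
returned with `F = Inf, p = 0` (or `NaN` when the between-group variation is
also zero) and flagged via the `degenerate` attribute, because constant
columns do occur in noise-free simulations and toy examples. A sum of
squares counts as zero when it is below `1e-12 * max(SS_total, 1)`.

Note that the one-way and two-way fits meet only conceptually: a two-way
table restricted to a single treatment level is not a valid input for
`two_way_anova()` (the treatment and interaction strata would have zero
degrees of freedom), so the package deliberately rejects it; the analysis of
a single level is `one_way_anova()` on that slice.

## Duncan's multiple range test

`duncan_letters()` implements Duncan's *new* multiple range test. For means
sorted in decreasing order, the least significant range for a span of `p`
means is

```
LSR_p = q(1 - (1 - alpha)^(p - 1); p, df_error) * sqrt(MSE / n_h)
```

where `q` is the studentized-range quantile (`stats::qtukey`, spot-checked
against published tables to two decimals in the tests) and `n_h` the
harmonic mean of the group sizes. The stepwise procedure is *protected*:
ranges are examined from the widest span downwards, and once a range is
declared non-significant every pair inside it is fixed as non-significant,
regardless of its own raw range test. Compact letters are the maximal
intervals of the resulting non-significance relation.

The protection rule admits an equivalent closure formulation — a pair is
non-significant iff some enclosing pair fails its raw range test — and the
acceptance tests exploit this: a brute-force oracle built on the closure
form must agree with the sweep implementation on 500 random instances.

Default `alpha = 0.01`, matching common practice in germplasm screening
reports; `MSE = 0` inputs take a degenerate path that groups exactly equal
means.

## Tolerance indices, ranking and classification

For a trait with control mean `Y_p` and stress mean `Y_s` per accession, the
stress tolerance index is `STI = (Y_p * Y_s) / Ybar_p^2` with `Ybar_p` the
grand control mean (`compute_sti()`). The default `sti_traits` are GP and
the derived seedling growth SG = RL + SL (computed per replicate, then
averaged); the accession's STI is the mean over those traits
(`aggregate_sti()`), and the combined index is the plain mean of the `T1`
and `T2` indices (`combined_sti()`).

The average rank (AR) is the mean of the accession's mid-rank positions over
the `ranked_traits` — by default all traits except LP, i.e. eleven traits,
so tie-free ARs are multiples of 1/11. Orientation is per trait (LP
lower-is-better when explicitly ranked) and can be overridden in
`ranking_config()`.

Three design decisions deserve explicit statement:

* **Final ordering policy.** Within a single stress level the final order is
  STI descending (ties: AR ascending, then accession id); for the combined
  screen it is AR ascending (ties: STI descending, then id). Both policies
  are explicit in `ranking_config()$final_order_policy` and can be swapped.
* **Combined scope averages values, not ranks.** The combined rank table
  ranks the mean of each accession's `T1` and `T2` trait means, rather than
  averaging the two per-scope rank vectors. Ranking averaged values keeps
  the AR granularity property (multiples of 1/11 on tie-free data) and is
  invariant to per-scope rescaling of a trait.
* **Classification is contiguous.** `classify()` slices the final ranking
  into `n_groups` contiguous classes of near-equal size, remainder going to
  the best classes first (64 accessions → 22 / 21 / 21 as high / moderate /
  low). Contiguity makes the classes reproducible and order-faithful, at the
  cost of ignoring gap structure in the index values.

## Biomarker identification

`group_trait_stats()` compares tolerance classes on the accession means of
one trait under one stress treatment: a one-way ANOVA across classes plus
Duncan letters on the class means (harmonic-mean group size). A trait is
declared a biomarker by `identify_biomarkers()` only when the class effect is
significant (`p <= alpha`, default 0.01) under **every** stress treatment —
a conjunction rule chosen over pooling because a marker that separates
classes at 7.5 % PEG but not at 15 % is not robust enough to select on.
Traits are reported ordered by their worst-case p-value.

## The synthetic-data generator

`generate_study()` emulates the *statistical shape* of a PEG screen, not its
biology. For accession `i` with planted tolerance score `tol_i ∈ [0, 1]` and
dose `s` (0, 0.5, 1 for `T0`/`T1`/`T2`), the cell mean of a declining trait
is

```
mu * g_i * (1 - d * s * (1 - e * tol_i))
```

and of an accumulating trait (all biochemical traits plus DW, which rises
under osmotic stress)

```
mu * g_i * (1 + u * s * (1 + e * link_i))
```

where `g_i ~ lognormal(-sdlog^2/2, sdlog)` is a mean-one genotype effect
drawn per accession × trait, `e` is the trait's `tolerance_signal`
(default 1), and `link_i = tol_i` except for LP, where `link_i = 1 - tol_i`
(tolerant accessions accumulate less damage). The dose slopes `d`, `u` are
solved at generation time from each trait's `stress_ratio` (full-stress
grand mean over baseline) so that the expected grand mean at `s = 1` hits
`baseline * stress_ratio` *whatever* the tolerance settings — this keeps the
marginal trait levels realistic even when `tolerance_signal` is zeroed for
recovery experiments. Replicate noise is binomial for GP
(`100 * Binom(seeds_per_dish, p) / seeds_per_dish`) and truncated
`Normal(mean, cv * mean)` for everything else.

What it does **not** emulate: trait–trait correlations beyond the shared
tolerance score and genotype effect, replicate (dish) random effects,
nonlinear dose response, measurement censoring, and any genetic structure
among accessions (scores are evenly spaced by default, best accession last).

### Default parameters and calibration

`default_paper_like_config()` fixes a 64-accession, 5-replicate,
25-seeds-per-dish screen — a deliberately chosen size typical of germplasm
panels and comfortably within test-time budgets. Baselines and stress ratios
per trait are realistic field magnitudes (e.g. GP 90.1 % falling to ~80 % at
full stress; proline 854 µg/g nearly tripling). The noise defaults
(`genotype_sdlog = 0.01`, `noise_cv = 0.03`, `tolerance_effect = 1`) were
calibrated *at design time* with a small power study so that the default
screen is informative: the combined ranking recovers the planted top-3 in
its top-5 in well over 90 % of runs and correlates with the planted scores
at |Spearman| > 0.99. Larger spreads (sdlog 0.04, cv 0.05) drown the
tolerance signal for traits whose stress ratio is close to 1 (GP in
particular, which also carries irreducible binomial noise) and make the
default screen a poor showcase; users wanting a harder problem can simply
raise them.

## Numerical choices

* Studentized-range quantiles come from `stats::qtukey` rather than a
  hand-rolled bisection; values are pinned against published tables.
* All ranking uses `ties.method = "average"` (mid-ranks).
* Report CSVs round to two decimals at emission only; every in-memory object
  keeps full precision.
* Derived seeds everywhere stay below 2^31; the full pipeline and the
  acceptance script are byte-for-byte reproducible under a fixed seed.

## Limitations

* Only balanced designs are supported in the factorial ANOVA.
* DMRT controls the per-comparison protected error rate, not the
  family-wise rate; that is inherent to Duncan's procedure.
* STI presumes positive control means; traits where stress *improves*
  performance make STI > 1 and should be interpreted accordingly.
* The biomarker conjunction rule has no multiplicity correction across
  traits; with seven biochemical candidates at `alpha = 0.01` the expected
  number of false positives is small but not zero.
* The generator's independence assumptions (above) mean simulation-based
  power estimates transfer to real screens only approximately.
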