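---
title: "Models and methods behind spermFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spermFISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermFISH)
```

## The segregation model

A der(13;14) Robertsonian translocation fuses the long arms of
chromosomes 13 and 14. In carrier spermatogenesis the derivative
chromosome and the two normal homologues form a trivalent whose meiosis-I
partition determines the gamete genotype. `enumerateGametes()` encodes
the four modes; the key structural fact is that the derivative carries
one 13q and one 14q probe-target copy, so the two complementary gametes
of any mode always sum to two copies of each target. The two balanced
alternate products, {13, 14} and {der}, are observationally identical
(one signal per test probe plus one control signal) and the model makes
no attempt to distinguish them.

The package keeps adjacent-13 and adjacent-14 (the classical adjacent I /
adjacent II distinction) as separate internal states but reports their
sum as a single "adjacent" class, matching how such studies tabulate
results. Their relative rates are unconstrained by any published
frequency; the simulator exposes both and defaults them to equal
probability.

## Signal patterns, probe failure, and the classifier

`expectedPatternDistribution()` gives the exact distribution of observed
`(13q, 14q, control)` signal counts on the tri-color slide: the gamete
genotype mixture (each mode's probability split evenly between its two
complementary gametes, plus diploid nuclei at genotype (2,2,2) and
"others" emitted as a triploid-like (3,3,3)) is marginalized over
independent per-copy hybridization failure — each probe-target copy is
seen with probability $1-f$ for its probe's failure rate $f$, so observed
counts are binomial thinnings of true copy numbers. The test suite checks
this closed form to $10^{-12}$ against a brute-force enumeration of every
gamete × failure-mask combination.

The failure model exists because it is the simplest mechanism that
inflates apparent nullisomy: a haploid-normal nucleus whose test probe
fails is scored as nullisomic. The observed asymmetry
(nullisomy > disomy on most slides) is *consistent with* such a
mechanism, but the package does not assert its cause; the default
per-copy rate of 0.2% is a placeholder, not a published value — no
hybridization-failure or unscorable-cell rates were reported.

`classifyCell()` implements the standard scoring rules (test count
against control count: 0/1 nullisomy, 2/1 disomy, 2/2 diploidy, 3/1
trisomy, …). Three decisions were genuinely open:

- **Nuclei with no control signal are unscorable** and excluded from all
  denominators. The scoring criteria require strong fluorescence signals
  but state no explicit exclusion rule; excluding control-negative
  nuclei is the only reading under which "nullisomy" (0 test, 1 control)
  is well defined.
- **(0,0,1) nuclei are scored as 3:0 double-nullisomy products**, not as
  double test-probe failure, following the published scoring; with the
  default failure rates, double failure contributes
  $\sim f^2 \approx 4\times10^{-6}$ and is negligible next to the
  0.5–1.5% double-nullisomy signal.
- **Panels whose ploidy control is the X+Y centromere pair** treat the
  summed X+Y count as the control count (one in any haploid nucleus, two
  in a diploid one). On the sex-chromosome panel itself, XX/YY/XY disomy
  subtypes are tallied separately, and (1,1,**2**) is diploidy while
  (1,1,**1**) is XY disomy.

The study design mentions 20 hybridization rounds for 22 nontranslocated
chromosomes without stating the packing; panels are configurable (JSON
via `readPanelConfig()`), and the default uses one panel per autosome
plus one X/Y panel.

## Frequency conventions

All frequencies are percentages of scorable nuclei, carried at full
precision; rounding to the 2-decimal report precision happens only when
tables are rendered. Two identities hold exactly on every output and are
asserted across the suite: aneuploidy = nullisomy + disomy and total =
aneuploidy + diploidy + others.

Per-carrier cumulative nullisomy/disomy/aneuploidy are **sums** of
per-chromosome frequencies (a rate per genome, which is why values exceed
single-slide percentages), whereas cumulative diploidy and "others" are
**pooled-count ratios** — a diploid nucleus is a whole-cell event visible
on every slide, so dividing pooled diploid counts by the pooled
denominator avoids counting the same biology 22 times. When the
translocated chromosomes are included, the tri-color slide contributes
both its chromosome-13 and chromosome-14 frequency rows to the sums but
its cells only once to the pooled denominator (the reading under which
the published cumulative diploidy values are internally consistent).

The cohort SD convention was fixed by recomputation from the packaged
per-carrier table: the population (divisor-$n$) SD reproduces the printed
SD row (6.00 for the chromosome-13 total, 8.10 for alternate, …); the
sample convention does not. `summarizeCohort()` therefore defaults to the
population SD and exposes a `sd = "sample"` switch. One printed SD (the
adjacent column) matches neither convention and is treated as a
typographical artifact of the source table; it is not asserted anywhere.

`diploidFraction3to0()` quantifies the tri-color design's payoff: on a
dual-color panel, diploid sperm and 3:0 double-disomy gametes are the
same pattern, and the fraction diploidy/(diploidy + 3:0) of such
"3:0-like" nuclei — about 0.16 at the cohort means — is what the control
probe reclassifies.

## Statistics

Standard tests delegate to `stats` (`t.test`, `wilcox.test`,
`kruskal.test`, `glm`); the two post-hoc procedures with no
implementation in the dependency stack are authored here:

- **Student–Newman–Keuls** (`anovaSNK()`): group means are ordered and
  each pair referred to the studentized-range distribution with the
  pair's stretch as range parameter, `sqrt(MSE/2 (1/n_i + 1/n_j))` as
  standard error, and the stepwise blocking rule (no pair inside a
  retained range is declared significant). Critical values come from
  `ptukey`/`qtukey`, R's numerically integrated studentized-range
  distribution — well within the ±0.001 accuracy target, and validated
  against the pooled two-sample t in the two-group degeneracy
  ($q = \sqrt2\,t$) and against a Tukey HSD oracle on shifted-mean data.
- **Steel–Dwass** (`kruskalSteelDwass()`): each pair is re-ranked in
  isolation; the tie-corrected standardized rank-sum statistic is
  referred to the studentized range with infinite degrees of freedom for
  the family-adjusted p. Ties use midranks. Raw pairwise p-values are
  exact (full enumeration of group assignments) up to a configurable
  pair size (default total $n \le 12$), where they coincide with the
  exact Wilcoxon tail; larger pairs use the normal approximation.

The per-chromosome carrier-versus-control stars are produced, by
default, by the pooled two-proportion z test — the test with the most
power at ~10,000 pooled cells per chromosome, and the publication never
states which test produced its stars — while per-subject Welch t and
Mann–Whitney results are also emitted, each labeled, so no single guess
is baked in. `glmSeverity()` fits abnormal counts as binomial with
severity group and chromosome as additive factors (IRLS via
`stats::glm`) and reports Bonferroni-multiplied Wald contrasts between
severity groups — the analysis that compares semen-severity groups after
controlling for chromosome.

Degenerate inputs are signaled, not silently absorbed: constant paired
differences, zero within-group variance with separated means, fewer than
two subjects for an SD, and zero 3:0-like denominators all raise classed
conditions (`spermFISH_degenerate_error` etc.) that the CLI maps to
distinct exit codes. The one deliberate exception: identical paired
vectors return $t = 0, p = 1$ (no evidence) rather than an error, since
every difference is exactly zero.

## The synthetic cohort: what it emulates, and what not

`simulateCohort()` reproduces the published design as its stated world:
10 carriers (one severe oligozoospermic, three oligoasthenoteratozoospermic,
six teratozoospermic) and 10 normozoospermic donors, ~1,000 nuclei per
slide, 22 slides per carrier (tri-color + 20 autosomes + sex) and 23 per
donor. Defaults are fixed once from the published quantities:

- carrier segregation vector = cohort means (alternate 74.37%, adjacent
  23.42% split equally, 3:0 1.63%, tri-slide diploidy 0.31%, others
  0.26%, normalized to 1);
- carrier per-chromosome nullisomy/disomy rates from the per-chromosome
  results where printed (chromosomes 1–12; 15, 18, 21, 22 and the sex
  chromosomes from the text); chromosomes 16, 17, 19 and 20 were never
  printed and are fixed at values consistent with the stated size-group
  ordering — these four are non-published choices;
- severity presets (nullisomy 1.49 / 0.83 / 0.47%, diploidy 0.74 / 0.77 /
  0.51%) rescale each carrier's per-chromosome rates to its group mean;
- sex-chromosome disomy split by meiotic origin: meiosis-I
  nondisjunction yields XY (0.31%), meiosis-II yields XX or YY (0.16%
  each);
- donor per-chromosome rates (unpublished) spread the donors' cumulative
  values uniformly over 22 chromosomes (disomy 3.21%/22, nullisomy
  7.08%/22), diploidy 0.36%;
- diploidy is modeled as two detection-level rates (0.31% on the
  tri-color slide, 0.59% on nontranslocated slides) rather than one
  biological rate, because the generator's job is to emulate the
  observed per-panel data, and the two slide types plainly detect
  diploidy at different rates.

Draws are i.i.d. per nucleus given the profile. Real data are not: the
generator has no within-slide spatial structure, no scoring-operator
drift, no between-slide hybridization-quality variation, no
subject-level random effects beyond the severity presets, and fixed
rather than varying nuclei counts. A green round-trip test therefore
establishes that the classifier and aggregation pipeline are correct and
that the statistics behave at the study's scale — not that the
biological rates themselves are estimated without confounding. In
particular, published per-subject values and p-values for the
nontranslocated comparisons cannot be reproduced numerically (the raw
per-cell data were never deposited); those claims are covered by
property-based recovery tests on the synthetic world instead.

Determinism is part of the contract: one master seed, one RNG stream,
byte-identical output — verified in the suite.

## Known limitations

- The "others" category on the tri-color slide is emitted as a single
  triploid-like pattern; the real composition of such nuclei is unknown
  and unmodeled.
- Adjacent-13 versus adjacent-14 rates, and the four never-published
  per-chromosome defaults, are modeling choices, flagged above.
- The SNK procedure is known to be anti-conservative relative to Tukey
  HSD; it is provided because it is the named procedure, and the Tukey
  comparison in the tests documents the relationship rather than hiding
  it.
- No crossover/interference modeling, no sperm-viability selection, no
  semen-parameter modeling (severity is a label that switches rate
  presets), and no image analysis — inputs are signal counts.
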