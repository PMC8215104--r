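---
title: "Methods: gene-diet interaction analysis with gxdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-diet interaction analysis with gxdiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxdiet)
```

## The scientific problem

Candidate-gene nutrition studies ask whether a polymorphism modifies the
association between habitual diet and cardiometabolic phenotypes. The
concrete setting this package implements is a cross-sectional cohort of
apparently healthy obese adults (BMI ≥ 30, ages 20–50), genotyped at
FADS2 rs174583 by PCR-RFLP and phenotyped for lipids, glycemia, blood
pressure, insulin resistance and mental health, with habitual diet
summarized by two a priori diet-quality indices: the Fung DASH score and
the alcohol-free Trichopoulou Mediterranean Diet Score (MDS). The
inferential question is whether genotype and diet-score tertile interact
on continuous risk factors, assessed per sex by ANCOVA, alongside
odds-ratio models for genotype against binary risk flags.

## Cohort screening

`apply_eligibility()` retains a subject iff age lies in the closed
interval [20, 50] years, BMI = weight/(height/100)² ≥ 30 kg/m², and
reported energy intake lies in the closed interval [800, 4200] kcal/day
(implausible totals are treated as mis-reporting). Endpoints are
retained because the exclusion is phrased as being *outside* the range.
Screening problems are exclusions, never errors; the first violated rule
per subject is logged (incomplete dietary data take precedence, then
age, BMI, energy, and finally named exclusion-flag columns), and the
partition invariant `retained + excluded = input` is enforced by
construction. Missing values in analysis-specific fields exclude a
subject from that analysis only (complete-case per analysis).

## Diet-quality scores

Both indices rest on the same equal-frequency quantile machinery
(`quantile_ranks()`): within each sex, subjects are ranked into *k*
groups by `ceiling(k · rank / n)` with minimum ranks for ties. Tied
values therefore share the lowest qualifying group, and a constant
stratum collapses into group 1. This single rule powers quintiles
(DASH), median splits (MDS) and tertiles, and is verified in the test
suite against an independent sort-and-bucket oracle.

**DASH.** Eight components: five emphasized food groups — fruits,
vegetables, whole grains, low-fat dairy, and nuts+legumes merged into
one component — score their sex-specific quintile rank (1–5); three
discouraged components — sodium (mg/day), red/processed meat, sweetened
beverages — are reverse-scored (6 − rank). The merge of nuts and legumes
is the only composition consistent with an eight-component index scoring
8–40 built from the six emphasized foods plus three discouraged
components. Quintiles are computed after eligibility filtering, i.e.
within the analyzed population.

**MDS.** Six protective components (vegetables, legumes, fruits+nuts,
cereals, fish/seafood, MUFA:SFA ratio) score 1 at or above the
sex-specific median; two non-protective components (meat = red +
processed + other meat, dairy) score 1 strictly below it. At-median
values belong to the "≥" side. Alcohol is omitted, so totals range 0–8.
A subject with zero SFA has an undefined fat-quality ratio and is left
unscored rather than silently imputed.

Tertiles (`assign_tertiles()`) use the same rank rule with k = 3,
reporting the 33.3rd/66.7th percentiles per stratum as cut points.

## Derived phenotypes

All formulas operate in conventional clinical units: lipids and glucose
in mg/dl, insulin in µU/ml, blood pressure in mmHg.

- Friedewald LDL-C = TC − HDL − TG/5, enforced only for TG < 400 mg/dl
  (standard validity bound; configurable to return missing instead of
  erroring).
- AIP = log₁₀(TG/HDL); HOMA-IR = glucose·insulin/405 (mass-unit
  constant); QUICKI = 1/(log₁₀ insulin + log₁₀ glucose). The HOMA
  constant and log base are arguments, since conventions vary across
  laboratories.
- Metabolic syndrome follows NCEP ATP III: ≥ 3 of {waist > 102/88 cm
  (M/F), BP ≥ 130/85 (either component at its bound), TG ≥ 150,
  HDL < 40/50 (M/F), glucose ≥ 100}. An alternative ruleset
  (`"atp3_wc88"`: waist > 88 and HDL < 50 for everyone, glucose ≥ 110)
  is available by name because both variants circulate in the applied
  literature.
- The eight binary risk flags use inclusive cuts for ≥-type criteria
  (TC ≥ 220, LDL ≥ 160, TG ≥ 150, BP ≥ 130/85, glucose ≥ 100) and
  strict cuts for the insulin-resistance flags (HOMA-IR > 2.6,
  QUICKI < 0.33). The low-QUICKI threshold defaults to 0.33 — the
  conventional value on the index's own scale — and is configurable,
  since printed thresholds for this quantity are occasionally garbled
  in the literature (e.g. "38", which is not a value QUICKI can take).
- DASS-21 subscales are twice the sum of their seven 0–3 items (even,
  0–42), banded by the Lovibond cut-offs, which ship as an editable
  list. SES sums the education, occupation and house-ownership scales
  (family size is recorded but not summed, keeping the three-scale
  total) and categorizes at empirical tertiles by default; explicit cut
  points may be supplied.

## Genotyping

TauI RFLP of the 572-bp FADS2 amplicon: the C allele is cleaved into
192 + 380 bp (their sum is the amplicon length, asserted as a library
constant), the T allele runs uncut. `call_genotype()` matches each
observed band to the nearest expected length within a tolerance
(default ±10 bp, emulating agarose gel resolution) and accepts exactly
the three canonical patterns; anything else is uncallable rather than
guessed. Cohort statistics use `f(T) = p(TT) + p(CT)/2`; the minor
allele is determined empirically (T at this locus). The exact
Hardy-Weinberg test conditions on allele counts and enumerates the
heterozygote-count distribution via the standard recurrence; it is a QC
aid, not part of the primary analysis chain.

## Inference

Odds-ratio models use CC as the reference genotype. Binary risk flags
are fitted by binary logistic regression with genotype dummies —
formally the two-level special case of a multinomial model — and the
3-level genotype against a continuous diet score by `nnet::multinom`.
Both report Wald 95% CIs; quasi-separation is flagged, not silently
printed. Three nested adjustment sets are fixed by `model_spec()`:
crude; model 1 = age + physical activity + SES; model 2 = model 1 +
waist circumference. Physical activity and SES enter as unordered
categorical covariates with indicator coding; reference levels follow
R's default alphabetical factor ordering, an arbitrary but deterministic
choice that does not affect the genotype contrasts.

The interaction model is the general linear model
`y ~ genotype + tertile + genotype:tertile + covariates`, fitted
separately per sex, with the interaction tested by the partial F-test on
the 4-df block (computed directly from the two model deviances so that a
numerically zero interaction sum of squares yields F = 0 rather than a
blank). Tertile enters as a categorical factor — matching an analysis
whose interaction plots have a tertile axis — though nothing prevents
fitting the continuous score instead by passing it as a covariate.
Adjusted cell means ± SE are estimated marginal means at covariate means
(via **emmeans**), which reproduce what SPSS-style GLM procedures
report; with no covariates and balanced cells they reduce exactly to raw
cell means, and they are invariant to affine recoding of covariates
(both properties are tested). Empty cells are flagged; the interaction
is still tested on the remaining estimable block when rank permits.
Post-hoc comparisons are unadjusted LSD contrasts of adjusted means
within genotype across tertiles by default — the permissive convention
common in this literature — with Bonferroni available by flag. The
significance threshold is 0.05 throughout and no multiple-testing
correction is applied by default, matching field practice; skewed
responses are analyzed untransformed by default (an optional log
transform can be applied upstream).

## The synthetic-cohort generator

`simulate_cohort()` emulates the *analyzed* (post-screening) cohort of
such a study: n = 347 by default, 58.2% male, genotype mix CC/CT/TT =
37.8/51.9/10.3% (or Hardy-Weinberg proportions for a given MAF).
Food-group intakes are independent log-normals whose medians and
log-scale SDs are anchored to realistic cohort marginals (fruits median
444 g/day, cereals 523 g/day, ...), with sex-specific location factors
(1.08/0.90) chosen to preserve the pooled median. Energy is a
partial-attribution linear function of the intake components plus
Gaussian noise, calibrated to a 3043 kcal/day mean, and truncated to the
eligibility window — the generator models subjects who already passed
screening, so the default cohort screens with zero exclusions. A
printed-cohort energy SD (~1078 kcal/day) cannot coexist with a
fully-eligible cohort, and eligibility takes precedence here by design.

Biomarkers are Gaussian around anchored means (TG 119.97 ± 58.46, TC
188.43 ± 33.73, sex-specific HDL pooling to 44.97, glucose 91.5 ± 10,
SBP 115.64 ± 16.44, DBP 76.33 ± 12.32), floored at physiological minima;
insulin is log-normal (median 13.1 µU/ml). Blood pressure is generated
as a latent value plus two noisy readings (SD 4 mmHg) so the
duplicate-averaging step has something real to do.

Planted effects are expressed in units of the response's **marginal SD**
under the null — the scale in which epidemiological effect sizes are
quoted. Standardized age and waist circumference each carry 10% of the
marginal response variance by default (mild, realistic confounding for
lipid/BP outcomes), and the noise absorbs the remainder, so the marginal
SD stays at its configured value. Because the ANCOVA adjusts age and WC
out, the residual scale against which an interaction is tested is
slightly smaller than the marginal scale; at these defaults a 0.8-SD
shift in the CT × T2 cell is detected at n = 350 with power ≈ 0.87,
whereas the same shift measured against pure noise SD with no covariate
variance would sit near 0.79. Binary outcomes are drawn directly from
logistic models (`p0` at CC, per-genotype log odds), which makes
odds-ratio recovery exact in expectation; the default anchors a TT-vs-CC
OR of 3.58 on a planted high-TG flag. Genotypes are randomized against
everything else, as in nature.

What the generator does **not** emulate: correlation between food
groups (available only through explicit configuration), item-level FFQ
structure, measurement error in the FFQ, population stratification
beyond the genotype mix, skewness of TG beyond a floor (a log-normal TG
option would be a one-line configuration), or any real linkage between
diet and biomarkers other than the planted effects. Passing calibration
and recovery tests on these cohorts therefore demonstrates correctness
of the *statistical machinery*, not validity of any substantive claim
about real populations.

## Numerical choices and problem sizes

- Quantile ties: minimum rank, hence ties share the lowest group — the
  only convention under which a constant stratum is well-defined.
- Sample skewness uses the moment estimator m₃/m₂^1.5; a constant
  variable is assigned skewness 0 so it routes to the mean (SD) report.
  The routing threshold is |skewness| > 1.
- The HWE test includes the observed configuration with a 1 + 1e-9
  relative tolerance when summing no-more-likely configurations, the
  standard guard against floating-point exclusion of ties.
- Calibration suites run 1000 null replicates at n = 350 (interaction
  type-I error and OR CI coverage), power 500 replicates, and OR
  recovery 15 replicates of n = 5000 averaged on the log scale; these
  sizes give Monte-Carlo SEs of ~0.7% on rates and ~3% on the recovered
  OR, small relative to the tolerances they are compared against.
- All randomness derives from a single user seed; sub-seeds are drawn
  from it, so every simulation is reproducible end to end.

## Known limitations

The package analyzes one variant at a time (no haplotypes, no
genome-wide machinery); interactions are planted and tested on the
tertile scale, so effects smooth in the continuous score lose power;
adjusted means require the covariates to act linearly; and the
cross-sectional design the pipeline mirrors cannot, of course, support
causal claims — the package reproduces an analysis style, including its
conventions (no multiplicity correction, LSD post-hocs) where those are
part of the style.
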