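---
title: "Scoring and validating a self-management barrier screener"
author: "semas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating a self-management barrier screener}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semas)
```

## The instrument and its scoring model

SeMaS is a 27-item screener for patient-level barriers to chronic-disease
self-management. Seven psychosocial characteristics are measured by small
item sets — self-efficacy (2 items, each scored 0–3), coping (2 items per
style: problem solving P, expressing emotions E, looking for distraction D),
depression (3 items), anxiety (4 items), locus of control (one internal and
one external item), social support (6 subitems scored 0/1/2) and perceived
burden of disease (a single 0–10 visual analogue scale) — plus three
guidance items (computer skills, group functioning, willingness to
self-monitor) that steer the *type* of support and are recorded verbatim,
never categorised.

Scoring is entirely table-driven. An instrument definition (YAML, schema
versioned) declares response scales as ordered code–score levels, constructs
as item sets with a missing-data policy and a category rule, and global
settings (coping style mapping, locus tie-break). The packaged default
encodes the screener's published rules; everything downstream consumes only
the validated definition, so variants (translations, adjusted cut-offs) are
config changes, not code changes.

Three scale details deserve note. The coping scale has five frequency
options but only four distinct scores: the added option "often" scores the
same as "very often/continuously" (a declared *collapse*; the loader rejects
duplicate scores on scales that do not declare one). The social-support
scale maps "no", "completely false" and "somewhat false" all to 0, "somewhat
true" to 1 and "completely true" to 2, so the 6 subitems span 0–12. The
burden VAS accepts one decimal place and is rounded half-up before banding,
so band edges behave like the printed integer intervals.

### Categorisation

Each characteristic maps to **none / minor / major barrier**:

* *banded*: closed integer intervals partitioning the attainable range —
  self-efficacy 4–6 none / 2–3 minor / 0–1 major; social support 3–12 none /
  2 minor / 0–1 major.
* *u-shaped* (burden): 0–2 minor, 3–7 none, 8–10 minor — a low burden can
  sap motivation for change, a high burden can impair capacity; neither is
  ever "major".
* *style dominance* (coping): the style with the highest sum dominates. A
  single dominant problem-solving style is no barrier; a dominant E or D
  style maps to minor (configurable), and ties — multiple styles — map to
  minor. If any style is not scorable the construct is not scorable:
  dominance cannot be established from partial information. This is the
  conservative reading; the alternative (dominance among scorable styles)
  would silently change meaning with missingness.
* *dichotomy* (locus): internal when the internal item's score is at least
  the external item's. The tie-break to internal is a documented default
  (configurable): a tie gives no positive evidence of an external
  orientation, and only the external orientation is treated as a (minor)
  barrier.
* *external table* (anxiety, depression): these subscales belong to a
  validated source questionnaire whose published cut-offs are not
  redistributed here. The packaged bands (depression 0–2/3–5/6–12, anxiety
  0–3/4–7/8–16) are placeholders marked `authoritative: false`; they
  partition the attainable ranges sensibly for simulation work but must be
  replaced for clinical use. We considered hard-failing without user cut-offs
  but that would make every example and test carry boilerplate; the explicit
  non-authoritative flag is the compromise.

Missing data: any missing item voids its construct (`not_scorable`), except
social support, where a missing subitem means "not applicable" and scores 0 —
unless all six are missing. Not-scorable characteristics are excluded from
the per-respondent barrier count and flagged separately.

The item inventory follows the 6-subitem reading of social support (the
tested criterion form adds a neighbour-support subitem to the 5-item scale)
and the 6-item tested coping set, which is what makes the total 27
(2+6+3+4+2+6+1 scored + 3 guidance).

## The graphic profile

The profile renderer places each characteristic's score at its normalized
position `(sum − min)/(max − min)` on a fixed-width track whose zones come
from the category bands; the category column is taken verbatim from the
scoring engine (the renderer never re-bands, so the two can never disagree).
The locus row shows the internal-minus-external difference rescaled to the
track; the coping row shows the dominant style's sum. Row order (burden,
self-efficacy, locus, anxiety, depression, coping, social support) is a
fixed default chosen for stable, diffable output; text output is
deterministic byte-for-byte and golden-file tested, SVG is the canonical
graphic format.

## Validation statistics

* **Internal consistency**: Cronbach's alpha on complete cases,
  `α = k/(k−1)·(1 − Σσᵢ²/σ²_total)` with n−1 variances. Degenerate inputs
  (one item, <2 complete cases, zero total variance) return an undefined
  value with a reason, never a number. For the locus pair alpha is computed
  on the two items as scored; because they are deliberately opposite-keyed,
  near-zero or negative values are expected and informative.
* **Criterion validity**: each characteristic's barrier flag is compared
  with a flag derived from the full-length criterion instrument by a
  mandatory, user-supplied rule set (the shipped rules are illustrative —
  published norms for the source instruments are not redistributed).
  PPV = tp/(tp+fp), NPV = tn/(tn+fn); respondents not scorable on either
  side are excluded and counted. Zero denominators yield undefined values
  with reasons. Burden and social support have no criterion rule and report
  "not applicable".
* **Correlations**: sum scores on both sides, pairwise complete. Normality
  of each vector is checked with Shapiro–Wilk at α = 0.05 (the standard
  choice, well powered near n ≈ 200; configurable); Pearson's r when both
  pass, otherwise Spearman's rho with average ranks for ties. The locus
  "sum" is the internal-minus-external difference, the quantity the
  dichotomy actually uses.
* **Convergent construct validity**: characteristics are dichotomised
  (1 = no barrier, 0 = minor/major), screened one at a time by one-way
  ANOVA on the PAM-13 score (retention at p < 0.05 — the conventional
  level; the screen threshold is a parameter), then entered together in a
  forced-entry OLS regression. The 1 = barrier-free coding makes a positive
  β read as the PAM-13 point advantage of unimpeded respondents.
  Standardised β is `β·sd(x)/sd(y)`. Complete cases listwise for the
  regression, pairwise elsewhere, and no multiple-testing correction — all
  mirroring standard practice for this design. Rank-deficient designs fail
  naming the collinear predictors.

## The synthetic cohort generator

The generator exists so the full pipeline is testable without patient data.
It emulates: **correlated psychosocial traits** (multivariate normal, unit
variances; defaults: depression–anxiety 0.6, self-efficacy negatively
related to distress and burden, positively to internal locus, support and
problem-solving coping — all modest and verified positive definite);
**graded Likert responses** — item value `λ·θ + ε`, `ε ~ N(0,1)`, cut at
equal-probability thresholds shifted by a per-construct offset (ordinal
probit / graded-threshold model, chosen because alpha then has the
Spearman–Brown closed form `2r/(1+r)`, `r = λ²/(λ²+1)`, usable as an
independent test oracle); a **criterion channel** that reuses the realised
per-item latents plus independent `N(0, σ_crit)` noise, so `σ_crit = 0`
makes the criterion agree with the screener exactly (the identity check)
and increasing it degrades PPV/NPV smoothly; a **PAM-13 channel**
`intercept + Σ coeffᵢ·[barrier-free]ᵢ + N(0, σ_PAM)` clamped to 0–100, with
the published regression coefficients as default generating values
(intercept 34.50; self-efficacy 16.43, social support 6.64, locus 2.99,
burden 3.51, anxiety 0.84, depression 0.04) and σ_PAM = 12, which puts the
model r² in the 0.25–0.35 range seen for this design; and **item-level
missingness**, independent per item, default 1% with 6% on coping items
(coping had by far the most missing data in field use).

Default item discriminations (λ 1.6 for self-efficacy and depression, 1.3
coping, 1.2 support, 0.9 anxiety, 1.0 locus) give construct alphas in the
0.5–0.9 range the instrument reports. The truth channel stores the latent
traits and the barrier flags obtained by scoring the complete
(pre-missingness) responses; it is consumed only by tests, and with zero
missingness scoring recovers it exactly.

One global seed drives five derived substreams (traits, screener items,
criterion noise, PAM, missingness), so cohorts are byte-reproducible and
changing one channel's parameters does not perturb the others' draws.

**Prevalence calibration.** Barrier prevalences vary widely in field use
(anxiety barriers ~5%, coping barriers common). `calibrate_prevalence`
bisects on a construct's shared threshold offset until the simulated
prevalence (n = 10 000 per evaluation, common random numbers) hits a
target. Only banded sum-score rules are calibratable — there prevalence is
monotone in the offset, which bisection requires; dominance, dichotomy and
u-shaped rules are rejected with an informative error. The reference
scenario (`default_scenario_config`) is a 204-respondent cohort — the size
of a typical primary-care validation sample — calibrated to self-efficacy
0.25, depression 0.12, anxiety 0.05, social support 0.10: the qualitative
pattern (anxiety rare, coping common by construction), documented as
illustrative rather than a reproduction of any particular cohort.

## What the tests do and do not show

Property tests cover: exhaustive-enumeration agreement of every
categorisation rule with straight-line re-implementations of the banding
text over all attainable response combinations; alpha against the
covariance-trace closed form (10×k random matrices, 1e-12) and against the
Spearman–Brown prediction on n = 5000 two-item constructs — the latter on a
21-level fine-grained scale, because coarse 4–5-level categorisation
attenuates observed correlations by several hundredths and the closed form
applies to the latent model; PPV/NPV self-consistency and exactness on the
noiseless channel; ANOVA-screen type-I error within 3 points of 5% over
1000 null replicates at n = 204; and regression recovery of generating PAM
coefficients within 2 standard errors on seeded n = 1000 cohorts. Problem
sizes (5000 for reliability and correlation checks, 10 000 for calibration,
1000 replicates for the screen) were chosen so Monte-Carlo error sits well
inside each tolerance while the suite stays fast.

Passing these tests shows the machinery is correct under the generator's
assumptions — normal traits, ordinal-probit items, independent missingness.
Real questionnaire data differ in known ways: traits are not exactly
normal, missingness is not independent of the trait (respondents skip items
that feel inapplicable), items within a construct are not equally
discriminating, and criterion instruments are longer and differently keyed
rather than noisy copies of the screener. The published headline values
(specific PPV/NPV percentages, alphas, β's, r²) were computed on an
undeposited patient cohort and are therefore *not* reproduction targets;
the synthetic channel reproduces their structure, not their values.

## Numerical and design choices

* Closed integer bands; VAS rounded half-up (`floor(x + 0.5)`), so 2.5 → 3
  (none) and 7.5 → 8 (minor).
* Lenient input mode (default) logs illegal codes as issues and treats them
  as missing; `strict = TRUE` aborts — validation runs should be strict,
  field scoring tolerant.
* CSV I/O is UTF-8, comma-delimited, period decimal; comma decimals are
  rejected with a clear error rather than silently misparsed. Reports format
  ratios to 3 decimals, percentages to 1, half-up, and are byte-stable.
* Every output directory gets a manifest (command, MD5 input digests,
  instrument version, seed, package version, timestamp).
* The command-line layer is a thin wrapper over exported functions; all
  logic is library code.

## Known limitations

Placeholder anxiety/depression cut-offs (see above); no test–retest or
longitudinal change support; the criterion channel shares the screener's
item structure rather than emulating the full-length originals; no
copula/non-normal trait options; PAM-13 is consumed as a precomputed score
(its licensed scoring is out of scope, and the optional raw-sum rescale is
deliberately not provided to avoid confusion with the official scoring).
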