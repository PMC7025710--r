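---
title: "Methods: a five-variable discriminant tool for GADA-positive adult-onset diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-variable discriminant tool for GADA-positive adult-onset diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadadiscrim)
```

## The clinical problem

Glutamic acid decarboxylase antibody (GADA) testing is the most sensitive
way to recognize adult-onset autoimmune diabetes, but it is costly and not
routinely available in primary care, especially where autoimmune diabetes
is rare. A cheap pre-screen can be built from measurements every newly
diagnosed diabetic patient already has: age at onset, BMI, HbA1c, and the
lipid profile. GADA-positive patients tend to be younger and leaner, with
higher HbA1c and HDL-C and lower triglycerides than type 2 patients, so a
linear discriminant over these routine variables can flag who is worth
sending to the antibody test.

`gadadiscrim` implements the full derivation pipeline for such a tool and
ships the published coefficient set ready to apply.

## The statistical procedure

**Step 1 — screening and cutpoints.** Continuous variables are compared
between groups with the pooled-variance Student *t* test
(`pooled_t_test()`); categorical variables with the Pearson chi-square
test without continuity correction (`pearson_chi2()`), or the two-sided
Fisher exact test for rare exposures (`fisher_exact()`, point-probability
rule). Significant continuous variables are screened for normality with a
Kolmogorov–Smirnov statistic against a normal with sample-estimated
parameters (`ks_normality()`); because the parameters are estimated, the
default p value uses the Lilliefors correction (the Dallal–Wilkinson /
Stephens approximation), with the uncorrected asymptotic p behind a flag.
Each significant lab then gets an empirical ROC curve (`empirical_roc()`,
thresholds at observed values only) and the cutpoint closest to the
upper-left corner, minimizing
$d = \sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2}$
(`min_distance_cutoff()`). Both $d$ and $d^2$ are reported because
published "minimum distance" columns match the squared form. Ties are
broken toward higher sensitivity, then lower threshold.

**Step 2 — discriminant analysis.** Records are encoded as seven dummies
(`encode_indicators()`): age bins $[20,30)$, $[30,50)$, $[50,\infty)$ and
BMI bins $(0,23)$, $[23,25)$, $[25,\infty)$ — the oldest/heaviest bin is
the reference level — plus TG $\ge$ 98 mg/dL, HbA1c $\ge$ 8.6 %, and
HDL-C $\ge$ 46 mg/dL. For two groups the canonical discriminant direction
has the closed form $w \propto S_w^{-1}(\mu_1 - \mu_2)$, where $S_w$ is
the pooled within-group covariance on $n - 2$ degrees of freedom
(`fit_canonical_lda()`). Weights are normalized to unit pooled
within-group score variance; standardized coefficients are the weights
times the pooled within-group SDs; structure-matrix loadings are the
pooled within-group correlations between each predictor and the score.
The eigenvalue of $S_w^{-1}S_b$, Wilks' $\Lambda = 1/(1+\lambda)$
(with Bartlett's chi-square test), and the canonical correlation
$r = \sqrt{\lambda/(1+\lambda)}$ all come from the same decomposition.
Variables whose absolute loading does not strictly exceed 0.3 are dropped
— as whole clinical families, so the two age dummies stand or fall
together — and the retained set is refitted (`two_stage_fit()`).
Classification uses Fisher's per-group linear functions
$f_g(x) = \mu_g' S_w^{-1} x - \tfrac12 \mu_g' S_w^{-1}\mu_g +
\log \pi_g$; a record goes to the group with the larger score
(`fisher_classify()`), an exact tie to T2DM.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided significance gate into the ROC stage |
| `loading_threshold` | 0.3 | strict absolute-loading retention bound |
| `priors` | `"equal"` | Fisher-constant offsets $\log \pi_g$; `"proportional"` uses group sizes |
| cutoffs | 98 / 8.6 / 46 | TG (mg/dL) / HbA1c (%) / HDL-C (mg/dL) indicator cutpoints |

Equal priors are the default because that is the convention of the SPSS
workflow the published coefficients came from; the choice moves only the
constants, by $\log(\pi_1/\pi_2)$ on the score difference.

## The synthetic cohort generator

No patient-level data are distributed, so `generate_cohort()` fabricates
cohorts whose *marginal* summaries emulate the published ones:
152 GADA+ and 358 T2DM records, with every mean/SD, age/BMI bin
proportion and binary prevalence taken from the printed group summaries
(`default_config()`).

Design choices, made once:

* **Joint dependence is not identified by marginals.** A latent Gaussian
  copula couples the eight continuous variables; the default correlations
  (TG↔HDL −0.4, BMI↔TG +0.3, BMI↔HDL −0.3, others 0) are physiologic
  assumptions, fully overridable, and deliberately exclude the grouping
  variable so planted effects stay controlled.
* **Triglycerides are lognormal**, moment-matched analytically
  ($\sigma^2 = \ln(1 + (s/m)^2)$, $\mu = \ln m - \sigma^2/2$), since a
  normal with the printed SD would be badly skew-inconsistent and TG was
  treated as non-normal in the source workflow.
* **Truncation floors** (age ≥ 20 by eligibility, HbA1c ≥ 4, labs > 0 by
  physiology) would bias the moments where the floor carves off visible
  mass (about 8 % of a Normal(37.6, 12.6) lies below age 20). The parent
  parameters are therefore *moment-solved* so the truncated distribution
  itself has the target mean and SD.
* **One normal cannot match both printed moments and printed bin
  proportions** for age and BMI. Two modes make the approximation
  explicit: `MOMENT_MATCH` targets mean/SD; `BIN_CALIBRATED` draws the
  age/BMI bin from the printed proportions first and the value
  conditionally within the bin (via the same copula uniform, preserving
  monotone dependence), so bin frequencies match in expectation.
* Binaries (gender, smoking, statins, fibrates) are independent Bernoulli
  draws at the printed prevalences.

A green test on synthetic data therefore establishes that the *pipeline*
recovers planted structure — marginal effects of the published size, a
planted discriminant direction, a planted cutpoint — not that it would
reproduce the original cohort's joint behavior. In particular the
published resubstitution accuracy (87.1 %) depends on the unobserved joint
distribution of the real cohort and is intentionally not a test target;
it is reproduced only as arithmetic on the published confusion counts.

## Numerical conventions and edge cases

* Bin boundaries are half-open and boundary values go up: BMI exactly 23
  is "23–25", age exactly 30 is "30–50"; lab indicators use inclusive
  $\ge$. Source tables are ambiguous here ("30–49" vs "30–50 years");
  the half-open reading avoids gaps and is applied uniformly.
* The TG indicator is coded TG ≥ 98 even though the case-side ROC rule is
  TG < 98; the negative discriminant coefficient absorbs orientation.
* Chi-square without Yates correction and the pooled (not Welch) *t* are
  deliberate: they reproduce the published p values from the printed
  summaries.
* The AUC is the rank-based Mann–Whitney estimate with ties counted one
  half; its 95 % CI uses the Hanley–McNeil standard error. The source
  does not state its CI method, so printed CIs are not asserted anywhere.
* ROC direction is inferred from the sign of the case-minus-control mean
  difference. On data shaped like the published summaries this makes GPT
  a case-low variable; the published table prints the GPT rule as "≥ 22",
  which is inconsistent with its own group means and is treated as a
  reporting artifact.
* Degenerate inputs: identical groups yield eigenvalue 0 and $\Lambda=1$;
  a singular pooled covariance raises an error naming the collinear
  columns; Fisher-exact on a table with an empty margin returns p = 1.
* Complete-case handling: rows violating record invariants (age at onset
  < 20, non-positive labs) are rejected with row-indexed diagnostics;
  rows with missing analysis fields are dropped and counted.

## Known limitations

* Single-center, single-ethnicity derivation context: the shipped
  coefficients should not be assumed portable across populations.
* The generator emulates marginals plus an assumed copula; real
  within-group dependence (e.g., HbA1c–lipid coupling under treatment) is
  not modeled, and statin/fibrate use is independent of lipids here.
* Only two-group canonical analysis is supported (no multi-group, no
  stepwise entry, no quadratic discriminant) — matching the scope of the
  procedure it implements.
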