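---
title: "Methods: quantification, concordance and response prediction in pcrconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, concordance and response prediction in pcrconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrconcord)
```

## Scope and model

`pcrconcord` compares three read-outs of the breast-cancer biomarkers ER,
PR and Ki-67 — mRNA by RT-qPCR (genes ESR1, PGR, MKI67, with ERBB2 carried
through quantification but outside the concordance trio), visual IHC
scoring (vIHC) and digital image analysis (qIHC) — and evaluates how well
each proliferation read-out predicts pathological complete response (pCR,
ypT0 ypN0) after neoadjuvant chemotherapy. The package has five stages:
synthetic cohort generation, Cq quantification, dichotomization,
concordance statistics, and ROC-based response prediction, orchestrated by
`run_pipeline()`.

## Relative quantification

Raw data are per-well quantification cycles over 40 amplification cycles.
For each sample and gene the triplicate median is taken; with two detected
wells their mean (which is the median), with one that value, with none the
gene is missing. Undetected wells (no amplification within 40 cycles) are
*excluded* from the median rather than imputed at 40: imputation would bias
upward-censored genes toward apparent expression.

Expression is reported on the 40-minus-ΔΔCq scale,

$$40\text{-}\Delta\Delta Cq(g)_S = 40 - \big((Cq[g]_S - \overline{Cq}[REF]_S)
 - (Cq[g]_{pc} - \overline{Cq}[REF]_{pc})\big),$$

where $\overline{Cq}[REF]$ is the unweighted arithmetic mean of the B2M and
CALM2 median Cqs and $pc$ is the per-run calibrator. Three exact algebraic
properties follow and are enforced by tests: adding a constant to all of a
sample's Cqs changes nothing (RNA input cancels); a per-run per-gene offset
shared by sample and calibrator wells cancels (inter-run correction);
lowering a target median by $\delta$ raises its value by exactly $\delta$.

### Quality control

Vendor validity criteria for this kind of assay are not public, so the
package ships its own operationalization, all thresholds configurable via
`qc_rules()`: mean reference Cq at most 32 cycles (more would indicate too
little RNA), replicate spread (max−min of used wells) at most 1 cycle, and
at least 2 detected replicates per gene. A sample failing any rule is
excluded with a recorded reason, and attrition is reconciled in the run log
(`n_input = n_analyzed + n_excluded`).

## Dichotomization

Hormone receptors by IHC are positive when the Remmele immunoreactive
score (IRS = intensity 0–3 × percentage category 0–4) exceeds 3 **or**
percent positive nuclei exceed 1% — both comparisons strict, so a sample at
exactly IRS 3 and 1% is negative. Ki-67/MKI67 is split high/low at
per-assay cutoffs; the packaged defaults are the ROC-derived values 37.31
(40-ΔΔCq), 13.2% (qIHC) and 3.5% (vIHC). For externally supplied cutoffs
classification is inclusive (`value ≥ cutoff` → high), matching the
detect-all-responders intent: a responder sitting exactly at the cutoff is
never excluded. Cutoffs derived internally by the ROC search are midpoints
between adjacent observed values, so observed data never tie with them.
mRNA positivity cutoffs for ESR1/PGR have no package default — no public
reference value exists — and must be supplied by the analyst; the demo and
acceptance runs use 34.0 and 31.0, chosen once to sit at the same marginal
quantile as the simulated protein positivity rates. The same IRS/percent
rule is applied to both IHC scoring methods, since a single rule is the
standard pathology convention.

## Concordance

Statuses from two methods are cross-classified into a 2×2 table
(complete-case per pair, with the number of dropped samples reported —
mirroring the attrition a paired three-method comparison necessarily has).
PPA $=100a/(a+c)$, NPA $=100d/(b+d)$, OPA $=100(a+d)/n$; a metric with an
empty denominator is reported missing, not 0 or 100. Continuous agreement
uses the tie-corrected Spearman coefficient (Pearson on mid-ranks) with an
exact permutation p-value for $n \le 9$ and the $t$ approximation above
that. Contingency tables are tested with the Fisher exact test
(probability-mass two-sided convention for 2×2, Freeman–Halton for larger
tables); a zero margin yields p = 1 and a degeneracy flag.

## Response prediction

ROC curves use the high-is-positive orientation (test-positive iff value ≥
threshold) over midpoint thresholds plus sentinels below the minimum and
above the maximum, so the operating points (sens 1, spec 0) and (sens 0,
spec 1) always exist. AUC is computed through the Mann-Whitney identity
with ties counted one half, and its p-value against 0.5 through the
tie-corrected normal approximation of U. The clinical cutoff search fixes
one axis — by default sensitivity at 100%, i.e. no responder may be missed
— and maximizes the other; ties are broken toward the larger cutoff (the
more conservative high-expression threshold). Fixing specificity instead is
available via `fixed_axis = "specificity"`, since both conventions appear
in practice. Group-level differences are confirmed with the Mann-Whitney
test: exact by full enumeration when $n_1+n_2 \le 16$ without ties,
otherwise a tie- and continuity-corrected normal approximation.

## The synthetic cohort generator

No patient-level data are distributable, so the generator emulates the
joint structure such a study observes; it is first-class, tested code, and
its defaults are the packaged study conditions.

* **Copula.** Per marker, the three measurement layers (mRNA, qIHC, vIHC)
  share a Gaussian copula. Target Spearman correlations — defaults
  0.82/0.85/0.88 for ER, 0.86/0.88/0.90 for PR, 0.50/0.56/0.80 for Ki-67 —
  are converted to latent Pearson correlations by $2\sin(\pi\rho/6)$, so
  any monotone marginal transform preserves the targets exactly in
  distribution. A non-positive-semi-definite specification is rejected
  naming the marker.
* **Marginals.** mRNA is Gaussian on the 40-ΔΔCq scale (MKI67 mean 37.0,
  SD 2.0, putting the median at the observed 37.01-range; ESR1 36.0/2.5,
  PGR 33.0/3.0). Protein is a logistic transform of the latent score
  scaled to [0, 100]; Ki-67 locations put the qIHC/vIHC medians at
  23.4%/35.0%, and the wide hormone-receptor logit scales (6.5–7) give the
  strongly bimodal percent distributions real ER/PR staining shows, with
  roughly 20% ER-negative and 26% PR-negative tumors. IRS is intensity
  (sampled conditionally on percent) times the Remmele percentage category
  (0; <10; 10–50; 51–80; >80).
* **Outcome.** pCR follows a logistic model on the *latent* MKI67 mRNA
  score: slope 1.3 per SD, intercept solved numerically so the marginal
  prevalence is 12/83 ≈ 14.5%. Because the protein layers see that latent
  score only through their 0.5-ish correlation, mRNA is by construction
  the stronger predictor — the qualitative contrast the analysis is about —
  and slope 1.3 yields AUC ≈ 0.8 for mRNA.
* **Plates.** Target wells are built by inverting the quantification
  formula around the sample's true reference Cqs, plus per-run per-gene
  offsets (SD 0.3 cycles) shared with calibrator wells, a per-sample
  global shift (SD 1 cycle, emulating RNA input), and replicate noise
  (SD 0.2 cycles). Wells past 40 cycles are emitted as undetected. With
  all noise at zero the plates round-trip through quantification to the
  true expression exactly.
* **Failures.** Assays fail independently of biology at rate 18/101
  (configurable), implemented as a +10-cycle shift of all the sample's
  wells: the reference mean then exceeds the QC ceiling, as an
  insufficient-RNA failure would.
* **RNG.** One master seed; each purpose (latents, runs, noise, outcome, …)
  draws under a fixed labeled offset of it, so enlarging one stage never
  perturbs another.

### What the generator does not emulate

Marginals are unimodal per layer (no explicit tumor-subtype mixture);
intensity is a stochastic monotone function of percent rather than a
stain-chemistry model; assay failure is independent of biology by default;
HER2/ERBB2 is simulated independently and not linked to outcome. Passing
tests therefore demonstrate the *statistical machinery* — quantification
algebra, agreement identities, exact tests, constrained cutoff search — and
the designed-in qualitative mRNA-vs-protein contrast, not clinical
performance on real tissue.

## Numerical choices

Problem sizes in the test suite were chosen to make sampling error
negligible relative to the assertion bands: copula fidelity is checked at
n = 5000 (±0.04 on each pairwise Spearman), prevalence and categorical
frequencies within 3 binomial SEs, the logistic slope within ±15%, and the
mRNA-beats-protein specificity contrast over 200 replicates of an n = 101
cohort. Oracle comparisons use full enumeration (all 2×2 tables to n = 30
for Fisher; all rank assignments for small Mann-Whitney; all pair counts
for AUC; a complete threshold scan for the constrained cutoff).
Floating-point tolerances: 1e−12 for formula transcription, 1e−9 for
round-trip recovery. Report precision follows field convention:
percentages to 1 decimal, correlations to 2, expression values to 2.

## Known limitations

The QC thresholds are the package's own operationalization, not a vendor's
validated criteria. The exact Spearman permutation p is limited to n ≤ 9
(9! enumerations); above that the t approximation is used, which is
slightly anti-conservative at n ≈ 10–15. The Freeman–Halton test delegates
to the network algorithm in `stats::fisher.test`, which can be slow for
large dense r×c tables. Constrained-cutoff results at 100% sensitivity are
driven by the minimum responder value and are accordingly variable in
small cohorts; the package reports achieved rates rather than confidence
bands, which are out of scope.
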