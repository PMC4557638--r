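---
title: "Reclassifying deaths of undetermined intent: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reclassifying deaths of undetermined intent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euireclass)
```

## The problem

External-cause deaths that medical examiners cannot (or will not) attribute
to a definite intent are coded to ICD-10 Y10–Y34, "event of undetermined
intent" (EUI). Where this category is heavily used, official mortality from
non-transport accidents (NTA), suicide (SUI) and homicide (HOM) is
under-enumerated, and differentially so: qualitative evidence typically
points at hidden homicides and suicides. `euireclass` implements an
indirect statistical correction that treats the problem as imputation of a
missing categorical outcome from the rich covariates a death record already
carries.

Transport accidents (V codes) and the tiny neglect/maltreatment group
(Y06–Y07) are excluded from the three-cause problem: transport deaths have
distinctive covariate patterns (and, in practice, near-automatic forensic
investigation), and a separate binary discriminator
(`fit_transport_discriminator()`) is provided to verify on any dataset that
EUIs are rarely transport-like.

## The classification model

For a death record $n$ with indicator-encoded covariates $x^n$,

$$\Pr(n, \mathrm{cause}=i) \;=\;
\frac{e^{\sum_k B_{ik} x^n_k}}{\sum_j e^{\sum_k B_{jk} x^n_k}},
\qquad i \in \{\mathrm{NTA}, \mathrm{SUI}, \mathrm{HOM}\},$$

a multinomial logit with homicide as the base outcome ($B_{3k}=0$; the
choice is exposed as an argument because predicted probabilities are
invariant to it, which the tests verify). The three fitted probabilities
are the *estimated classification probabilities* (ECPs); they sum to 1, so
the maximum is always at least 1/3.

The ten covariates are all categorical: identity-known flag, age group
(0–14 … 65+, *unknown*), calendar year, post-holiday/Monday flag, season
(winter / summer / spring–autumn), region (nine levels by default),
urban/rural, the 19-category nature-of-injury grouping, alcohol
intoxication, and an eight-level place of occurrence. Ill-defined values
("unknown" age, "unspecified" place) are ordinary levels, never missing
markers: indeterminacy itself is diagnostic, and nothing is imputed on
input. Year is categorical rather than continuous because period effects
over the covered era are not monotone.

**Encoding.** One-hot with the reference level omitted plus an intercept.
The reference level of each variable defaults to its most frequent level in
the training data, which keeps the intercept's information content high and
the design well-conditioned; the encoding map is stored with the model so
the design is reproducible record-for-record.

**Class weights.** The three causes have very different sizes, and the
unweighted MLE buys overall accuracy by sacrificing the rarest class
(homicide). Fitting uses case weights $w_c = N/(3 N_c)$, which equalize the
weighted class totals while keeping the weighted sample size equal to the
raw one. The source method states the balancing intent but not a formula;
this normalization is our choice, made so that likelihood magnitudes and
standard errors stay on the raw-sample scale. A consequence worth stating
plainly: with unequal weights the observed-information standard errors are
*not* sampling standard errors (no sandwich estimator is used, by design —
the robustness check below is the method's own error model). The
parameter-recovery test therefore checks SE calibration in an equal-mix
world where the weights are ≈ 1.

**Fitting.** Deterministic Newton iteration with analytic gradient and
Hessian, step-halving to guarantee the weighted log-likelihood never
decreases, and convergence declared at gradient max-norm < 1e-6 or relative
log-likelihood change < 1e-10. The design matrix is rank-checked up front
(collinear columns are named in the error). Quasi-complete separation —
expected whenever a rare injury category has a zero cell for some cause —
is detected by coefficient magnitude (|B| > 12) and reported as a warning,
not an error: the fit is still the MLE on the observed support, and the
affected coefficients carry appropriately enormous standard errors.

## Thresholded reclassification and the ECP₀ grid

Each EUI record is assigned the argmax cause of its ECP vector if that
maximum is ≥ ECP₀ (`assign_cause()`, comparison deliberately `>=`). The
canonical grid is {0, 0.5, 0.6, 0.7, 0.75, 0.8, 0.85, 0.9}: 0 is the
no-constraint case where every record is assigned, 1 would be an absolute
constraint. Raising ECP₀ trades coverage for accuracy; the unclassified
count is non-decreasing in ECP₀ (a tested invariant). Exact ties at the
maximum are broken by the fixed cause order NTA < SUI < HOM and counted;
ties have probability ~0 under continuous scores but do occur with coarse
categorical designs, and the source is silent on them, so the rule is ours
and is logged.

## Evaluation on the training set

At each ECP₀ the model is scored on the deaths with known causes, giving
the matrix $D = \lVert d_{ij}\rVert$ of predicted (i) by actual (j) counts
with marginals $D^P_i = \sum_j d_{ij}$ and $D^A_j = \sum_i d_{ij}$. Two
summaries drive interpretation: the share of agreement
$\sum_i d_{ii} / \sum_{ij} d_{ij}$ (overall and per actual cause) and the
relative error $(D^P_i - D^A_i)/D^A_i$, which measures population-level
bias of the classifier itself. The class-balanced model over-predicts the
rare class; this is visible, quantified, and is precisely the motivation
for the adjustment step.

## The population-level adjustment

Row-normalizing $D$ gives $P_{ij} = d_{ij}/D^P_i$: the probability that a
record *predicted* as cause $i$ is *actually* cause $j$. On the training
set the identity $D^A_j = \sum_i P_{ij} D^P_i$ holds exactly. Under the
explicit assumption that EUIs share the misclassification behaviour of
known-cause deaths, the same matrix redistributes the EUI assignments:

$$U^{Adj}_j = \sum_i P_{ij}\, U_i .$$

(The source prints the right-hand subscript as $U_j$; we read it as $U_i$ —
the only reading under which mass is conserved,
$\sum_j U^{Adj}_j = \sum_i U_i$, and under which the training identity is
mirrored. The same typo appears in the printed training identity with
$D^P_j$.) The pipeline forms $U_i$ at ECP₀ = 0 for this step, because the
adjustment is meant to cover the *entire* EUI set, including records whose
maximum ECP is low; rows of $P$ with zero predicted marginal are flagged
and may not carry EUI mass.

When does the assumption hold? Exactly when the cause mix among EUIs equals
the training mix, or when the classifier is error-free. If one cause is
masked into the EUI pool disproportionately (hidden homicides), $P$
transfers imperfectly and the adjustment under-corrects that cause — a
structural sensitivity of the method, not an implementation artifact. The
test suite demonstrates both regimes (see below).

## Comparators

Two alternative redistributions are implemented for sensitivity analysis:
the demographic default (within each sex–age stratum, split EUIs
proportionally to known-cause counts; empty strata fall back to the
sex-level margin) and fuzzy proportional sharing (each EUI contributes its
ECP vector, $\mathrm{total}_i = \sum_n p_i(n)$). `multinomial_pmf()`
supports the combinatorial argument for thresholding: even an ECP vector of
(0.8, 0.1, 0.1) implies that the composition "8 accidents, 1 suicide, 1
homicide in ten draws" has probability only ≈ 0.151, so individual-level
certainty is limited and population-level machinery is doing real work.

## Bootstrap robustness

`perturb_coefficients()` draws $\tilde B_{ik} = B_{ik} + SE_{ik}\,\gamma$
with $\gamma \sim N(0,1)$ independently per coefficient and replicate (the
source is ambiguous between per-coefficient and per-vector noise; the
per-coefficient reading is the standard parametric bootstrap and is our
documented choice). Correlations between estimates are ignored — only SEs
enter, as specified. `stability_analysis()` (default 250 replicates)
reports the share of record–replicate pairs whose argmax cause matches the
unperturbed prediction and the smallest observed max-ECP above which every
record was stable in all replicates. With separation-inflated SEs in the
model this threshold can sit very high — an honest reflection of
coefficient uncertainty on sparse cells.

## Rates

`sdr()` computes $\sum_a w_a (d_a/p_a) \times 100{,}000$. The bundled
standard is the classic European standard population aggregated to the
seven known-age bands of the record schema (0–14: 0.22; 15–24, 25–34,
35–44, 45–54: 0.14 each; 55–64, 65+: 0.11 each) — the source does not state
its vintage, so the classic standard is bundled and any
`standard_population()` can be swapped in. Deaths of unknown age are
redistributed proportionally to known-age deaths within the stratum before
rate computation (standard vital-statistics practice; the source is
silent). `adjusted_series()` outputs, per sex × year × cause, the official
SDR, the EUI-contribution SDR, their sum, and the EUI share of the adjusted
rate. For age-specific EUI contributions the pipeline realizes the
adjustment at record level: an EUI predicted as cause $i$ contributes
$P_{ij}$ of a death to cause $j$ while keeping its own age/year/sex, which
aggregates exactly to $U^{Adj}$ within each sex.

## The synthetic stated world

`default_russia_like_config()` fixes the generator's defaults once:

* **True cause mix** ∝ (1481, 541, 379) ≈ (0.617, 0.225, 0.158) — the
  relative magnitudes of the three known causes in the motivating
  application.
* **Masking** (probability that a true-cause death is observed as EUI):
  (0.125, 0.115, 0.30) for (NTA, SUI, HOM). This keeps the reported
  qualitative pattern — homicides masked ~2.5× more often — while putting
  the expected EUI share of all deaths at
  $\sum_c \pi_c m_c \approx 0.15$, the stated design parameter.
* **Covariates** are drawn independently given the true cause, with
  sharply cause-specific injury distributions (asphyxiation dominates
  suicide; open wound of thorax and intracranial injury concentrate in
  homicide; poisonings, hypothermia and drowning in accidents) and milder
  contrasts on place, alcohol, identity and demographics. Conditional
  independence is a deliberate simplification with a useful consequence:
  the true posterior is *exactly* a main-effects multinomial logit, so
  `implied_coefficients()` provides closed-form ground truth for
  parameter-recovery tests.

Three masking scenarios stress different regimes: `masking_uniform()`
(probability depends only on cause; with a scalar, the same for every
cause), `masking_covariate()` (odds multipliers on selected levels, e.g.
unknown identity — breaks the closed form and the ignorable-masking
property), and `masking_hidden_homicide()` (elevated homicide masking).

**What a green test does and does not establish.** The generator's world
has conditionally independent covariates, no interactions, no coding drift
over time, and masking that (in the uniform scenarios) is ignorable given
cause. Real registries violate all of these; in particular the
equal-masking recovery result shows the adjustment machinery is *correct*,
not that its transferability assumption holds in any real population. With
the default cause-tilted masking the recovery test is expected to be
conservative for homicide, and under `masking_hidden_homicide()` the tests
assert that recovery *degrades* — the method's stated sensitivity, kept
visible on purpose. The generator's classifier accuracy (~0.85–0.93
depending on threshold) emerges from the chosen distributions; it was fixed
once, before the acceptance checks were run, and is not tuned.

Interpretive choice recorded here: the acceptance criterion phrase
"uniform-per-cause masking" is implemented as the scalar-uniform scenario
(same probability for every cause), because that is the world in which the
adjustment's assumption provably holds and against which the
hidden-homicide scenario is the intended contrast.

## Numerical and degenerate-input policy

* ECP vectors are normalized by a max-shifted softmax; rows sum to 1 within
  1e-9 even for extreme scores.
* Misclassification rows with $D^P_i = 0$ are flagged `undefined`, never
  silently zeroed; adjustment refuses to push mass through them.
* Zero EUIs: the pipeline logs the fact and skips the adjustment stage.
* A cause absent from the training data is an error (weights undefined).
* Zero population with nonzero deaths is an error in `sdr()`.
* Model serialization writes doubles as `%.17g` strings inside JSON, so a
  reloaded model is bit-identical (plain JSON numbers are not).

## Known limitations

* The "about 1.12 million covariate combinations" figure reported for the
  original configuration does not follow from the documented level counts
  (which give ≈ 6.3M); the exact original level structure is ambiguous and
  no attempt is made to force agreement.
* The age bands are coarser than standard ESP bands; SDRs computed on them
  are internally consistent but not comparable to published ESP-banded
  rates.
* Per-ICD-item reclassification of EUI subtypes (e.g. Y30 into falls) is
  out of scope: aggregate categories are used precisely because single-item
  coding is the unreliable layer.
* The registry data behind the original application are confidential; none
  of its published tables are reproduced here, and no test asserts them.
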