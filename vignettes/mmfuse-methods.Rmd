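---
title: "Late-fusion multimodal survival modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Late-fusion multimodal survival modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmfuse)
```

## The problem

Patients with late-stage high-grade serous ovarian cancer are characterized
by several weakly prognostic, partially observed data sources: quantitative
texture features from contrast-enhanced CT (radiomics), morphometric
features from H&E whole-slide images (histopathology), clinical covariates,
and a rule-based homologous recombination deficiency (HRD) status from
genomic evidence. No single modality orders patients well; the question is
whether their risk signals are complementary, and how to combine them when
many patients are missing one or more modalities.

`mmfuse` implements a late-fusion answer: each modality gets its own Cox
proportional hazards submodel, trained on *all* patients with that modality
available; a small second-stage Cox model then integrates the per-modality
risk scores, trained only on the intersection of complete cases. Because the
second stage fits one coefficient per modality, it tolerates a small
intersection set while the submodels exploit the full unimodal samples.

## Feature selection cascade

For each candidate feature the package fits a univariate Cox model (Efron
tie handling, no regularization). A model that fails to converge — monotone
likelihood, singularity, iteration exhaustion — is refitted with an L2
penalty of strength 0.2; if that also fails, the feature is assigned log
hazard ratio 0 and p-value 1 so it can never be selected. For
histopathology, the relative specimen size can be included as a nuisance
covariate in every univariate model, because several tissue-level features
are partially determined by how much tissue was sampled.

Features whose *scaled interquartile range* falls below 0.1 are removed:
the feature is min–max scaled to $[0,1]$ on the training data and the IQR
of the scaled values is computed with linear-interpolation quantiles. The
scaling makes the 0.1 threshold unit-free. Min–max scaling (rather than
z-scoring or division by the range without centering) is a deliberate
interpretation: it is the only variant under which a constant feature is
well-defined (scaled IQR 0) and the threshold commensurable across
features; the choice is isolated in `scaled_iqr()`.

For the largest feature space (radiomics) the surviving p-values receive a
Benjamini–Hochberg correction at level $q = \alpha = 0.05$; smaller spaces
use the raw $\alpha$ threshold ("significant with 95% confidence").

Significant candidates, ordered by ascending p-value (ties broken
lexicographically by name for determinism), then enter a greedy
multivariable pruning pass: each candidate is tentatively appended to the
signature, the multivariable Cox model is refitted, and the candidate is
kept only if the Wald p-value of the *newly added* covariate is below
$\alpha$. Reading the acceptance rule as "the most recently added
coefficient is significant" is the only interpretation under which the slot
index advances exactly when the new candidate earns its place; a rejected
candidate's slot is overwritten by the next one. The pass prunes
multicollinearity structurally: an exact copy of an accepted feature can
never be significant given the original. Multivariable fits use the same
unregularized-then-L2(0.2) fallback ladder as the univariate screen — the
final-model penalty of 0.5 is reserved for fitted submodels, not selection.

Modalities with fewer than 10 observed events refuse to run the cascade and
raise a diagnostic; Cox models below that event count are too unstable for
selection to mean anything.

## Final models and risk scores

Unimodal submodels and the fusion stage maximize the Efron partial
likelihood penalized by $\tfrac{c}{2}\lVert\beta\rVert^2$ with $c = 0.5$
and no L1 term. Because this penalty is scale-sensitive, submodel features
are z-scored on the training data before fitting (the scaling is stored and
inverted at prediction); the alternative — penalizing raw-scale
coefficients — would make the effective shrinkage an accident of feature
units. Second-stage inputs are *not* re-standardized: they are already on
the log-hazard scale, which keeps the fusion coefficients interpretable as
relative modality weights.

Risk scores follow the *negative log partial hazard* convention: higher
score, lower predicted hazard. This makes an informative model concordant
(c > 0.5) under the concordance index's usual orientation. One subtlety:
the assembled per-modality score table used by the fusion stage is
*risk*-oriented (log partial hazard; and the genomic column is the
rule-based risk, proficient = 1, deficient = 0, ambiguous = missing), so
informative modalities receive *positive* second-stage coefficients;
predictions then revert to the protective convention. The genomic modality
has no fitted submodel at all — its risk is fully determined by the HRD
call.

The clinical record is encoded totally: residual disease ≤ 1 cm (including
complete gross resection) maps to 1, age is scaled by the training range
and clipped to $[0,1]$ at test time, and stage and treatment are one-hot
encoded *including* their unknown categories, so unseen or missing values
can never error. In `clinical_mode = "fixed"` the pipeline uses the
two-feature clinical signature (residual disease status and PARP-inhibitor
receipt); in `"select"` mode the generic cascade chooses.

## HRD rule engine

Two rule sets map genomic evidence to {HRD, HRP, ambiguous}. Under the
panel-sequencing rules, high-confidence dominant SBS3 or at least one
significant variant or deep deletion in the HRD-DDR genes gives HRD, unless
a subtype-exception marker (CCNE1 amplification or CDK12 SNV, evidence of
the foldback-inversion or tandem-duplicator subgroups) co-occurs, in which
case the conflict yields ambiguous. Low-confidence signature evidence is
never used. Unsequenced patients are ambiguous; sequenced patients without
HRD evidence are HRP; send-out panels are HRP unless the provider flagged a
significant variant. The exome/array rules use significant SNVs or deep
deletions in the HRD-DDR genes, the analogous conflict clause (which, read
literally, requires an HRD-DDR *SNV*, so a deep deletion alongside a CDK12
SNV still calls HRD), and an SBS3-frequency criterion with a strict
threshold: frequency greater than 15%.

Design notes. (1) The default HRD-DDR panel deliberately *excludes* CDK12
and CCNE1: those two genes mark the exception subgroups, and placing them
in the evidence set would let a single event both assert and contradict
deficiency. The panel is configurable for users with their own gene list.
(2) Large-scale state transition thresholds are not part of the call.
(3) The rule sets are chosen by an explicit `ruleset` argument, never
auto-detected. (4) When high-confidence SBS3 co-occurs with an exception
marker the call is ambiguous with the conflict recorded in the rationale
trace — the evidence genuinely points both ways, and guessing a precedence
would silently re-classify those patients.

Every call carries a machine-readable rationale (the ordered list of fired
rules), and the whole engine is verified against independently transcribed
truth tables over all evidence combinations.

## Histopathological embedding

The interpretable embedding is computed from a tissue label map (indexed
image over {tumor, stroma, necrosis, fat, background}) and a nucleus table.
Per tissue class the package reports region properties — area, area
fraction, major/minor axis length of the ellipse with equal second central
moments, eccentricity, solidity, perimeter — for both the union of the
class and its largest connected component (8-connectivity by default,
configurable). Composition features add all pairwise class area ratios
(missing, not infinite, when the denominator class is absent) and the
entropy of tumor and stroma. Nuclei are assigned the tissue parent at their
centroid pixel (no interpolation; background-parent nuclei are excluded),
then aggregated by parent × cell type × measurement into means, variances
and deciles; lymphocyte fractions per parent complete the picture.

Interpretive choices, flagged as such:

* **Entropy** has no published formula; it is implemented as the Shannon
  entropy (bits) of the class-occupancy histogram pooled over fixed 64 px
  square patches that intersect the target class — the same tile scale used
  for tissue-type classification. A map whose tumor-intersecting patches
  are half tumor, half stroma has tumor entropy exactly 1 bit.
* **Relative specimen size** is implemented as the foreground fraction of
  the grid (whether it should instead be a physical area is not
  determinable); since it is used as a *control* covariate, any monotone
  reparameterization is nearly equivalent.
* **Percentiles** use linear interpolation between order statistics
  everywhere.
* The full published feature registry is not enumerable from text; the
  registry here is the documented cross-product above, versioned, with the
  two published signature members (mean tumor nuclear area, stroma major
  axis length) guaranteed present.

All features are unit-aware: areas scale with (µm/px)², lengths with
µm/px, and dimensionless features are invariant — a property the tests
verify, along with 90° rotation invariance and agreement with a brute-force
pixel-moment oracle.

## Evaluation battery

Harrell's c is computed over comparable pairs (the earlier patient has an
observed event and a strictly smaller time), with score ties counted 0.5.
Confidence intervals come from 100 patient-level bootstrap resamples
(percentile method); the description of the published interval procedure
("leave-one-out bootstrapping") is internally contradictory, so the
percentile bootstrap is the default and a jackknife mode is provided.
Significance uses a one-sided permutation test of scores against fixed
outcomes with the add-one estimator $p = (1 + \#\{c_{perm} \ge c_{obs}\}) /
(n_{perm} + 1)$, which can never return 0 and is therefore conservative;
whether the original test permuted scores or outcome pairs is not stated,
and one-sided score permutation is the documented choice here.

Risk groups are formed by scanning percentile thresholds 0.33–0.66 in steps
of 0.01 on *training* scores, keeping the split that minimizes the training
log-rank p-value (ties broken toward 0.5, then the lower percentile, for
determinism; degenerate splits are skipped, and splits with zero log-rank
information count as p = 1). The winning threshold is frozen as a
risk-score cut and applied unchanged to test data — the search cannot even
receive test outcomes. Kaplan–Meier curves are product-limit steps;
fraction-surviving queries interpolate linearly between step corners.
Cross-modal ordering agreement uses Kendall's tau-b on within-modality risk
quantiles over complete pairs. The association between fused scores and the
ordinal chemotherapy response score uses a one-sided Mann–Whitney U-test,
computed by exact enumeration of label assignments (midranks for ties) when
the combined sample is at most 20, and the tie-corrected normal
approximation otherwise.

## The synthetic cohort generator

The generator is first-class, tested code: it is the instrument on which
every downstream claim is demonstrated, so its defaults *are* the study
conditions. A default cohort has 444 patients (40 of whom form the held-out
test set, sampled from full-information patients), a 600-feature
radiomic-like block and a 216-feature histopathology-like block, modality
availability 251/404 (CT) and 243/404 (H&E), an HRD label known for 337/404
with deficiency prevalence 119/337, and an OS censoring target of 132/404 —
the observed cohort accounting rates. Event times follow a Weibull baseline
(default shape 1, i.e. exponential, scale 60 months for OS) multiplied by
`exp(linear predictor)`; censoring is an independent exponential whose rate
is solved by root finding so the expected censored fraction hits the
target, keeping censoring non-informative as the Cox model assumes.

The true linear predictor sums: one planted radiomic feature at log HR 0.5
(mirroring a single-texture-feature imaging signature), two planted
histopathology features at log HR 0.3 each (mirroring a two-feature
morphometric signature), a protective HRD effect of −0.45 (chosen by a
closed-form calibration so that the binary label alone orders patients at
c ≈ 0.55 at the simulated prevalence), and weak clinical effects (residual
disease −0.25, PARP inhibitor −0.15, matching a clinical model that barely
beats chance). The same closed form — for a standard normal feature with
coefficient $\beta$ under proportional hazards, the population concordance
is $E[\mathrm{logit}^{-1}(\beta\,|\Delta x|)]$ with $\Delta x \sim
N(0,2)$ — places a single planted feature with $\beta = 0.4$ at c ≈ 0.61
and the fusion of two such independent signals at c ≈ 0.65, which is how
the fusion-complementarity experiments construct unimodal models in the
0.58–0.62 band.

Decoy features are equicorrelated Gaussian blocks (default correlation 0.5,
block size 10), which is what gives the multivariable pruning pass real
work. Near-constant features — a sparse unit spike on 10% of patients plus
tiny jitter, guaranteeing a scaled IQR far below 0.1 under any realistic
patient subset — occupy 26% of each block, so the default radiomic block
shrinks to ≈ 444 features after filtering. The ordinal response score is a
3-level proportional-odds draw on −(linear predictor), observed for 15% of
patients. Cross-modality correlation of planted features is exposed as a
configuration knob (default 0: independent), since the joint distribution
of modality signals is exactly what the cross-modal concordance analysis
interrogates and should not be hard-wired.

What the generator does **not** emulate: real radiomic features are not
Gaussian and their correlation structure is not block-equicorrelated; real
nuclear morphometry has heavy tails; modality availability in practice is
not independent of outcome; and the HRD label here is a direct Bernoulli
draw rather than the output of the rule engine on simulated variants.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative behavior of the design (complementarity, missing-data
benefits), not clinical performance on real data.

## Numerical choices

* Cox fits: `survival::coxph` with Efron ties, convergence tolerance
  1e-11; the L2 penalty enters as `ridge(..., scale = FALSE)` so the
  maximized objective is exactly $\log PL(\beta) - \tfrac{c}{2}
  \lVert\beta\rVert^2$ on the (already standardized) inputs. Degenerate
  features (zero variance or non-finite values) are defaulted without
  fitting: no rung of the ladder can identify them.
* Final models (submodels, fusion) treat nonconvergence as an *error*; only
  the screening ladder is allowed to default.
* Quantiles use the linear-interpolation convention (`type = 7`)
  everywhere: IQR filtering, percentile features, risk-group thresholds,
  bootstrap CIs.
* Determinism: one master seed expands into fixed named substreams per
  pipeline stage (`substream_seed()`), so changing the evaluation settings
  does not perturb the split, and a fixed configuration reproduces the
  report bundle byte for byte.
* Problem sizes in the test suite are chosen to finish in minutes while
  keeping Monte-Carlo margins honest: oracle equivalences run on hundreds
  of small instances (n ≤ 50), calibration on 1000 null cohorts of n = 60
  with 200 permutations, and the missing-data experiments on 20 seeds at
  the full 444-patient, 600/216-feature scale.

## Known limitations

* No time-varying covariates, stratified baselines or competing risks; no
  L1/elastic-net selection; no early or intermediate fusion; no imputation
  of missing modality scores (deliberately — no robust cross-modal
  association exists to support it).
* The permutation and bootstrap procedures treat patients as exchangeable;
  clustered sampling (multi-site cohorts) is not modelled.
* The histopathology module consumes label maps and nucleus tables;
  everything upstream of them (tile classification, nucleus segmentation,
  stain handling) is out of scope.
* The exact-enumeration Mann–Whitney path is limited to combined n ≤ 20 by
  the binomial explosion of label assignments; beyond that the tie-corrected
  normal approximation is used.
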