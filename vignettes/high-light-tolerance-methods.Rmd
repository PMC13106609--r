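---
title: "Methods: multi-trait evaluation of high-light tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait evaluation of high-light tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliotol)
```

# The problem

Seedlings of forage crops grown in alpine regions routinely experience
irradiance far above their light saturation point. Excess excitation energy
damages photosystem II, depresses net photosynthesis and constrains biomass
accumulation, but genotypes differ widely in how well they hold up. A
germplasm screen therefore grows a panel of accessions under a control light
level and a high-light stress level, measures a battery of morphological and
physiological traits, and asks two questions: *which accessions are
tolerant?* and *which traits drive biomass formation under stress?*

`heliotol` implements the full analysis chain for such a screen on nine
traits: plant height (cm), stem diameter (mm), leaf thickness (mm),
aboveground fresh and dry weight (g), SPAD chlorophyll index, net
photosynthetic rate (µmol m⁻² s⁻¹), free proline (µg/g) and Rubisco
activity (nmol/min/g). Under stress, all of these decline except proline,
which rises (osmoprotective accumulation), and dry weight, which barely
moves over a short stress window.

# Tolerance coefficients and the decision matrix

The unit of analysis is the genotype mean over biological replicates. For
genotype $g$ and trait $t$ the **high-light tolerance coefficient** is

$$ x_{gt} = \frac{\bar{y}_{gt}^{\,\text{stress}}}{\bar{y}_{gt}^{\,\text{control}}}, $$

a dimensionless stability ratio (near 1 = unaffected). The $n \times 9$
matrix of these ratios is the decision matrix of the comprehensive
evaluation; it must be complete, and control means must be strictly
positive. By default an incomplete matrix is an error; `on_incomplete =
"drop"` removes affected genotypes everywhere (TOPSIS cannot use partial
rows).

# Entropy weighting and TOPSIS

Trait weights are objective, not elicited. Each criterion column is min–max
normalised (cost criteria reversed), converted to proportions $p_{ij}$, and
scored by Shannon entropy $e_j = -\tfrac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$
(with $0\ln 0 := 0$, the exact limit — no epsilon shift). The weight is
$w_j = (1-e_j)/\sum_k (1-e_k)$: criteria on which genotypes hardly differ
carry no information and get near-zero weight; a perfectly constant
criterion gets exactly zero with a warning.

The TOPSIS stage uses the standard entropy–TOPSIS pairing: **vector**
normalisation $r_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$ for the distance
computation (the min–max normalisation is only for the entropy stage; the
pairing is stated so results are reproducible bit for bit). With weighted
values $v_{ij} = w_j r_{ij}$, the positive ideal takes each benefit
column's maximum (cost columns' minimum) and the negative ideal the
reverse; Euclidean distances $D^+_i, D^-_i$ to the two ideals give the
closeness coefficient

$$ CI_i = \frac{D^-_i}{D^+_i + D^-_i} \in [0, 1], $$

higher = closer to the ideal genotype. Ties share the minimum
(competition) rank. If all alternatives coincide, $CI$ is defined as 0.5
with a warning.

**Criterion directions.** All nine tolerance coefficients are treated as
benefit criteria by default: a higher stress/control ratio means greater
stability. Proline is the genuinely ambiguous case — its ratio rises with
stress response intensity, and its total effect on biomass is negative —
so the direction is a per-trait argument rather than a constant. The
latent-tolerance recovery tests run with `proline = "cost"`, which is the
coding under which a tolerant genotype (stable growth, low proline surge)
is rewarded on every criterion.

# Tolerance levels

CI values are clustered by agglomerative hierarchical clustering on
Euclidean distance in one dimension, cut at $k = 4$ ($k$ is fixed by
design, not chosen by an index: the screen's deliverable is four named
tolerance levels). Clusters are then labelled I (highest mean CI,
"extremely tolerant") through IV ("highly sensitive").

**Linkage.** On the packaged reference table of 48 published CI values,
complete and average linkage both reproduce the published partition sizes
(1/27/11/9); Ward linkage does not (it splits the large tolerant group
instead of isolating the single top genotype). The package default is
therefore **complete** linkage, with `"ward"` and `"average"` available —
the II/III boundary (0.571 vs 0.550) is the linkage-sensitive cut, and a
user comparing linkages will see exactly that boundary move. Clustering is
performed on the sorted values so the partition is invariant to input
order even with tied CI values.

# Associations

Pearson correlations are computed over genotype means, by default pooling
the control and stress tables (one row per genotype × treatment, capturing
both inter-genotype and stress-induced co-variation); per-treatment modes
are available. P-values use the t transform of $r$.

The Mantel stage tests each single trait's genotype distance matrix
against the two hub responses of the trait network — aboveground fresh
weight and net photosynthetic rate. Distances are Euclidean on
z-standardised values (units removed; a single trait reduces to
|difference| of z-scores). The statistic is the Pearson correlation of the
lower-triangle entries; the null permutes rows and columns of the second
matrix simultaneously, one-sided (greater), with
$p = (1 + \#\{r_\pi \ge r\})/(B+1)$ — never below $1/(B+1)$. An exact mode
enumerates all $n!$ relabelings for small panels and is tested against
that enumeration. Edge strengths are classed weak ($r<0.2$), moderate
($0.2 \le r < 0.4$) and strong ($r \ge 0.4$).

# Permutation importance

Predictors of aboveground fresh weight are ranked by out-of-bag (OOB)
permutation importance. The tree ensemble is an ordinary bootstrap
regression forest (`randomForest`, 500 trees, `mtry = ⌈p/3⌉` by default);
the importance statistic is computed in this package from the per-tree OOB
predictions:

$$ \text{imp}_j = \frac{1}{B}\sum_b 100\cdot
   \frac{\text{MSE}^{\text{oob}}_b(X^{(j)}) - \text{MSE}^{\text{oob}}_b(X)}
        {\text{MSE}^{\text{oob}}_b(X)} , $$

where $X^{(j)}$ permutes column $j$ once per forest under the seed. This
is the mean percent increase in OOB MSE; a predictor the trees never use
(e.g. a constant) scores exactly 0, and the ranking is invariant to affine
rescaling of predictors. Significance comes from a response-permutation
null: the whole forest-plus-importance computation is repeated on
permutations of the response, $p_j = (1+\#\{\text{null} \ge
\text{imp}_j\})/(n_{\text{null}}+1)$, with $n_{\text{null}} \ge 19$
enforced. Note the permutation floor: with 99 nulls the smallest
attainable p is 0.01, so the "highly significant" star threshold is
$p \le 0.01$.

The fit-mode question — tolerance coefficients, stress-only means or
pooled means as features — is an argument of the surrounding code, with
pooled genotype × treatment means the default.

# Piecewise structural equation model

The causal analysis is a piecewise SEM: one OLS regression per endogenous
node on its declared parents, fit on z-standardised columns so every
coefficient is a standardized path coefficient (single-parent case: the
Pearson correlation). The diagram is data, not code — a plain-text edge
list — and the packaged default has light intensity (LI), a genotype score
(G) and their interaction (LIxG) driving five intermediates (proline FPC,
height PH, leaf thickness LT, SPAD, stem diameter SD), with the
intermediates plus LI and G feeding aboveground fresh weight (AFW).

Model fit is Shipley's d-separation test. The basis set contains every
non-adjacent node pair conditioned on the union of the pair's parents
(pairs of two exogenous nodes excluded); each claim is tested by the
t-test on the partial coefficient of the claimed-independent variable, and
the claim p-values combine into Fisher's
$C = -2\sum_i \ln p_i \sim \chi^2_{2k}$. A large model p-value means the
declared structure is consistent with the data. Effects on AFW decompose
exactly: direct = the edge coefficient into AFW, indirect = the sum over
all directed paths of length ≥ 2 of products of edge coefficients
(enumerated exactly; the DAG is small), total = direct + indirect.

Two modelling choices deserve flagging. First, the numeric coding of the
exogenous block is a documented stand-in: LI is a standardized two-level
indicator, G a standardized per-genotype score (the generator's latent
tolerance scalar for synthetic data; user-supplied for real data), LIxG
their re-standardized product. Second, whether proline acts on AFW
directly or only via intermediates cannot be settled from summary
descriptions of such screens; the default includes the direct edge. The
default diagram's basis set has 11 claims (df = 22); denser diagrams with
mediation edges among the intermediates — which published screens likely
used, given fit statistics reported on 6 df — can be supplied as edge
lists without touching code.

# The synthetic cohort generator

No raw replicate table is distributed with screens of this kind, so the
package ships a generator whose defaults *are* the study conditions: 48
genotypes × 2 light levels × 3 replicates, control grand means and
inter-genotype SDs calibrated to the reference screen's descriptive
statistics, and per-trait stress factors equal to the published
stress/control grand-mean ratios (photosynthesis ≈ 0.59, proline ≈ 1.35,
dry weight ≈ 0.86).

Structure the generator does emulate:

* **Correlated genotype effects** via a single latent "vigor" factor
  (loadings: structural traits, SPAD, Rubisco, biomass positive; proline
  negative), so the correlation matrix is positive semidefinite by
  construction and height–proline correlations come out negative.
* **A genotype tolerance gradient**: one latent scalar per genotype
  multiplies the stress factor by $e^{\gamma\,\text{tol}}$ (sign flipped
  for proline). This is the ground truth the TOPSIS/clustering stages must
  recover, and it is exposed as an attribute for exactly that test.
* **Positivity**: strictly positive, high-CV traits (proline, both
  weights, Rubisco) are lognormal on the genotype level, matched to the
  target mean and SD; the rest are normal. All values are floored at 2% of
  the control mean (keeps every control mean strictly positive so the
  tolerance ratio is always defined); truncation events are counted and
  stay below 1% of records under defaults.
* **Reproducibility**: one master seed; each genotype consumes its own
  sub-stream (the g-th draw of a seeded `sample.int`), so genotype g's
  data are identical whether 5 or 500 genotypes are simulated.

Free choices the screen does not pin down: replicate-level residual noise
is set to 10% of each genotype × treatment expected value (screens of this
kind report no replicate variance; 10% is a typical assay-level CV), and
the tolerance-effect scale defaults to 0.1.

What the generator does **not** emulate: genotype × trait interactions
beyond the single tolerance axis, spatial/temporal block effects,
measurement censoring, and any non-Gaussian replicate error. Passing
recovery tests on synthetic cohorts therefore shows the pipeline detects
the kind of gradient the screen presumes — not that any particular real
panel has one.

# Numerical choices and problem sizes

* Internal computation is at full precision; only report layers round (2
  decimals, matching screen-table conventions).
* Entropy: $0\ln 0 := 0$; constant criteria get weight 0 (warning) or an
  error if *all* are constant.
* TOPSIS degenerate case $D^+ + D^- = 0$: CI defined 0.5 with warning.
* Tied cluster means in level labelling: broken by maximum CI, warning.
* Collinear SEM parents are reported via the design-matrix condition
  number.
* Test-suite problem sizes are chosen for tight oracles at interactive
  runtimes: exact Mantel enumeration at $n=5$ (120 permutations), null
  calibration at $B=999$ over 120 datasets, SEM d-sep calibration at 500
  replicates of $n=200$, coefficient recovery averaged over 20 replicates
  of $n=500$, forests of 40–200 trees.

# Limitations

* The entropy–TOPSIS score is a ranking device, not a genetic parameter;
  CI values are comparable within a screen, not across screens.
* The four-level partition is descriptive; the linkage sensitivity at the
  II/III boundary is real and documented above rather than hidden.
* The SEM's exogenous coding (G, LIxG) is a stand-in; path coefficients
  involving those nodes depend on the chosen genotype score.
* Permutation importance inherits the known bias of impurity-based
  forests toward correlated predictor groups; interpret ranks, not
  magnitudes.
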