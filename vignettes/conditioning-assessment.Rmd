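---
title: "Assessing UPLC-MS system conditioning after blank injections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing UPLC-MS system conditioning after blank injections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blankqc)
```

## The problem

Extraction blanks are indispensable in untargeted LC-MS metabolomics: they
reveal background features and carry-over that would otherwise contaminate
every downstream model. But a blank is also an aggressive injection — it
carries no sample matrix, so it strips the column of the adsorbed material
that defines its steady operating state. The samples injected right after a
blank are measured by a *deconditioned* system: peak areas rise or dip,
retention times shift, peak widths change, and the effect fades over the
following injections as the matrix re-equilibrates the column. How many
injections that takes depends on the matrix (protein-precipitated plasma
deconditions far more than urine), on the metabolite's chemistry
(late-eluting lipophilic compounds are hit hardest), and on how many blanks
were injected consecutively.

`blankqc` quantifies this process from a peak table (areas, retention
times, peak widths, detection status per feature and injection) acquired
under a cyclic design: a leading block of conditioning QCs, then repeated
cycles of either three consecutive blanks ("intense" deconditioning) or a
single blank ("mild"), each followed by eight replicate sample injections.

## The analysis pipeline

### Within-batch drift correction (QC-SVRC)

Long injection sequences drift. Before any comparison across positions in
the batch, each feature's intensity is corrected by quality-control-based
support vector regression: an ε-insensitive SVR with RBF kernel
$k(t, t') = e^{-\gamma (t - t')^2}$ is fitted to the reference injections'
intensities over run order $t$ and the predicted trend is divided out,

$$\mathrm{corrected}(f, i) = \mathrm{area}(f, i) \cdot
  \frac{\mathrm{median}(\mathrm{ref}_f)}{\mathrm{trend}_f(i)}.$$

The *reference set* is the leading QC block plus the last sample injected
before each blank group — those samples see a fully conditioned system and
play the role of QCs. The number of pre-blank samples used is configurable
(`j`, default 1); taking only the last one minimises contamination of the
reference by residual deconditioning.

Hyperparameters follow the selection scheme standard for this correction:

* **C** (penalty) is fixed at the median reference intensity of the
  feature — no search;
* **ε** (tube half-width) is searched over 3–10% of that median, the
  expected instrumental precision band;
* **γ** is searched log-uniformly over $[1, 10^5]$ (per squared run-order
  unit).

$(\varepsilon, \gamma)$ minimise the leave-one-out RMSECV on the reference
set; ties go to the smaller γ (smoother trend), then the larger ε (flatter
fit) — the conservative direction. The correction is multiplicative (the
drift acts on ionisation efficiency, a gain) and anchored to the reference
median, which keeps corrected intensities on the original scale. The trend
is clipped below at $10^{-6} \times$ median before division so gap-filled
near-zero predictions cannot explode a corrected value.

Two numerical notes. First, when every reference point fits inside the
ε-tube, libsvm returns a model with no support vectors; the solution is
then the flat function $-\rho$, which the package uses directly. Second,
because the ε-insensitive loss exerts *no* force on residuals inside the
tube, the fitted trend tracks the true drift only to within the tube width
— after correction, a noise-free drifting feature is constant to roughly
ε/median (3–10%), not to machine precision. The tests assert exactly this
contract (training residuals ≤ ε; trend within twice the tube width of a
generating line between training points).

### Blank-based screening

After correction, each feature is classified using the blanks:

* **informative** iff (i) min(sample)/max(blank) > 9, (ii) more than 90% of
  the biological replicates exceed 9 × max(blank), and (iii) the corrected
  reference RSD is below 20%. All three inequalities are strict: a ratio of
  exactly 9 or coverage of exactly 90% fails. A feature absent from every
  blank has ratio ∞ and passes (i).
* **carry-over +k** (k = 1, 2, 3): over a 3-blank cycle, detected in blanks
  1..k and in post-blank samples k+1..8, and *not* detected in the
  remaining blanks or the first k post-blank samples. The rule is stated on
  pre-gap-filling detection status, so the package accepts an explicit
  detection matrix; without one, detection falls back to
  `area > threshold` (default 0), which is the post-fill approximation.
  By default the pattern must hold in *every* complete intense cycle
  (`match_fraction = 1`); the tolerance is configurable because cross-cycle
  aggregation is the one point the rule leaves open. Mild (1-blank) cycles
  cannot express the pattern and are ignored for carry-over labelling.
* **contaminant**: detected in at least one blank and one sample without
  the sequential pattern; **excluded** otherwise.

Precedence is informative → carry-over → contaminant → excluded, so a
feature that passes the clean-up conditions is retained regardless of its
blank behaviour.

### Guided-PCA δ and the conditioning curve

The core question — *is the system back to steady state n injections after
a blank?* — is answered by comparing the pooled samples at post-blank
position $n$ with the position-8 reference set. On the column-centered
area matrix $X$ of the two sets, the δ statistic is

$$\delta = \frac{\operatorname{var}(X v_g)}{\operatorname{var}(X v_1)},$$

where $v_1$ is the first right singular vector of $X$ (the ordinary PC1
direction) and $v_g$ is the first right singular vector of $Y^{\mathsf T}X$
with $Y$ the samples × 2 group-indicator matrix scaled to unit columns
(the guided direction). Since PC1 maximises projected variance over unit
vectors, $\delta \in (0, 1]$; δ near 1 means the group split *is* the
dominant variance direction. The indicator scaling (unit columns) is one
of several equivalent conventions; it does not affect the bound and is the
one used throughout.

Significance comes from a permutation test: labels are permuted uniformly
$m$ times and

$$p = \frac{\#\{\hat\delta < \hat\delta_p\}}{m}$$

with a strict inequality and no add-one correction, exactly the counting
definition — so $p$ has resolution $1/m$ and can be 0. A conservative
$(\#+1)/(m+1)$ mode is available but off by default. $m = 1000$ is the
conventional choice; the package's tests and acceptance script use
$m = 200$, which resolves the 0.05 level to 10 permutation counts while
keeping hundreds of curve evaluations tractable.

Alongside δ, per-feature Welch t-tests (unequal variances,
Welch–Satterthwaite df) compare area, retention time and peak width between
the two sets; p-values are BH-adjusted *within each metric and position*
(the narrowest consistent family) and features with adjusted p < 0.05 are
counted. Area is compared on corrected values; RT and width are never
drift-corrected. The permutation permutes the pooled labels of the two
sets freely; preserving cycle structure would be an alternative, but with
replicate injections of one pooled sample the exchangeability assumption
holds as is.

### Blank PCA and profile clustering

Two complementary views: a PCA of the blank injections restricted to
non-informative features (carry-over features load on the component that
separates first-position blanks from later ones), and hierarchical
clustering of the per-position mean intensity profiles of informative
features using $d = 1 - r$ (Pearson) with average linkage, cut at $k = 2$.
Correlation distance makes the clustering invariant to per-feature scale
and offset, so the "row-wise z-scoring" of displayed profiles is cosmetic;
the profiles are cycle-averaged relative positions (blanks, then samples
1..8) rather than the full injection order — averaging suppresses residual
drift and is the default. Cluster 1 is the larger cluster by convention
(ties broken toward lower mean RT). Linkage is configurable; average
linkage is the customary pairing with correlation distances.

## The synthetic batch generator

Real raw data for this design require full peak-picking infrastructure, so
the package ships a generator that emulates the statistical structure the
analysis assumes, with planted ground truth for every stage:

* baseline areas log-uniform over four decades; smooth multiplicative
  within-batch drift (random spline, default peak amplitude 10%);
  multiplicative log-normal noise, mean one, default RSD 5% — matching the
  2.6–4.8% injection-standard precision typical of a plasma batch;
* deconditioning responses as piecewise-linear position factors:
  cluster 1 jumps to $1 + 0.15$ immediately after the blank and decays to 1
  by position 5; cluster 2 rises to $1 + 0.5$ at position 3 and returns to
  1 at position 7 (the "maximum 3–4 injections after the blank, recovery
  after 6–7" kinetics). The literature reports only profile
  shapes, not magnitudes; the defaults are set once at values that make the
  effect comparable to tens of percent, as observed for late-eluting
  lipids, and are configurable. Mild (1-blank) cycles attenuate the
  deviation by 0.5;
* cluster-2 features elute late (RT > 4.5 min), cluster-1 early — the
  chromatographic localisation the clustering stage should rediscover;
  cluster-2 features also get a post-blank RT shift (default 0.04 min,
  the order of a LysoPC shift) and width shift, decaying with the same
  recovery position;
* informative features have zero area and `detected = FALSE` in blanks
  (an extraction blank carries no matrix), so clean-up condition (i) holds
  by construction; contaminants appear in blanks at sample-comparable
  level; carry-over +k features follow their detection pattern exactly,
  with blank intensity decaying over consecutive blanks.

One seed drives everything; per-feature sub-seeds make each feature's
draws self-contained. What the generator does *not* emulate: peak-shape
physics, correlated features (co-eluting adducts/isotopes), between-batch
effects, missingness from real gap-filling, or biological variation
(batches are replicate injections of one pool). Passing tests therefore
demonstrate that the statistical machinery recovers planted structure
under the stated noise model — not that any particular real matrix needs a
particular number of conditioning injections.

## Problem sizes and defaults

The simulations used by the tests and the acceptance script run at desk
scale, chosen once: ~70–200 features, 8 intense + 4–8 mild cycles, 10
leading QCs (≈130–170 injections), $m = 200$ permutations, and SVRC grids
of 2×4 to 4×10 (ε × γ) nodes — each grid node costs one leave-one-out pass
over ~20–30 reference points, which is where virtually all compute goes.
The full default grid (8 × 26) is recommended for real batches. Thresholds
(blank ratio 9, coverage 90%, QC RSD 20%, FDR 0.05) are the published
screening constants and are strict inequalities throughout.

## Known limitations

* δ is reported with its permutation p; no δ cut-off is enforced (values
  like "δ > 0.8" are descriptive, not decision rules).
* The correction recovers drift only to within the ε tube (see above); it
  is a precision improvement, not an interpolator.
* Carry-over patterning needs complete 3-blank cycles and pre-fill
  detection to be fully faithful; with thresholded post-fill areas the
  patterns blur at low intensities.
* Between-batch normalisation is out of scope — each batch is corrected
  and assessed independently.
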