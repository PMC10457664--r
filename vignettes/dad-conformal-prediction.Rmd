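---
title: "Dynamic applicability domain conformal prediction for binding affinity"
author: "dadcp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic applicability domain conformal prediction for binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Models of compound–target binding affinity (pKd/pKi, the negative log10 of
the dissociation or inhibition constant) are usually judged by average
accuracy, but a screening decision is made one prediction at a time. A
conformal predictor turns a point model into *prediction regions*: for a
chosen confidence level $1-\delta$ it emits an interval that is guaranteed,
under exchangeability, to contain the true affinity with probability at
least $1-\delta$. The classical inductive conformal predictor (ICP)
calibrates once on a fixed held-out set, which has two drawbacks for
interaction data: regions have the same width for every test pair, and the
calibration set reflects the global training distribution even when the
tested pair sits at the edge of the model's applicability domain.

`dadcp` implements a *dynamic* calibration strategy: the calibration set is
re-assembled for every tested pair from its own compound–target
neighbourhood, so regions reflect how well the model performs *locally*,
and the predictor can abstain when the local evidence cannot support the
requested confidence.

## The method

Let $Z = \{(x_i, y_i)\}$ be the training interactions, $x_i = (c_i, t_i)$ a
compound–target pair. For a test pair $x = (c, t)$:

1. Rank training compounds by Tanimoto similarity of their Morgan
   fingerprints to $c$ and keep the $k$ nearest; rank training targets by
   normalized Smith–Waterman similarity to $t$ and keep the $q$ nearest
   (ties break by ascending identifier, so ranking is deterministic).
2. The dynamic calibration set $Z_c$ consists of every *measured* training
   pair whose compound is among the $k$ and whose target is among the $q$.
3. Two calibration score variants are available, both aligned to $Z_c$:
   - **NN**: $\alpha_i = |y_i - \bar{y}_{Z_c}|$, the spread of local labels
     around their mean;
   - **CV**: $\alpha_i = |y_i - \hat{y}_i^{cv}|$, the pair's residual
     against the mean of repeated (10 × 10-fold) out-of-fold
     cross-validation predictions, computed once for the whole training
     set.
4. Putative test scores are $\alpha_i^x = |y_i - \hat{y}_x|$ for each
   calibration label, where $\hat{y}_x$ comes from the single model trained
   on all training pairs.
5. The region half-width is $\alpha_\delta^{\min}$, the smallest
   calibration score that dominates at least a $1-\delta$ fraction of the
   putative scores ($\#\{i: \alpha_i^x \le \alpha\}/N_{Z_c} \ge 1-\delta$,
   inclusive at ties). The emitted region is
   $\Gamma_x^\delta = \hat{y}_x \pm \alpha_\delta^{\min}$.
6. If $Z_c$ is smaller than `min_calibration_size`, or no calibration score
   dominates enough putative scores, the predictor **abstains** for that
   pair and level. Abstention is reported per (pair, confidence): a pair
   can be covered at 75% and abstain at 99%.

Because the candidate half-width must be an observed local calibration
score *and* must cover a $1-\delta$ share of local labels around
$\hat{y}_x$, the construction needs no normalization step, and on
exchangeable data it errs on the conservative side (observed confidence at
or above the nominal level) except for the extreme-quantile effect
discussed under *Numerical choices*.

## Reference conformal regressors

For comparison the package ships four fixed-calibration ICP regressors,
differing only in the normalizer applied to the absolute residual score:

| method        | half-width at level $1-\delta$                       |
|---------------|------------------------------------------------------|
| `shafer`      | $\alpha_\delta$ (constant across test pairs)         |
| `error_model` | $\alpha_\delta \cdot e^{\mu(x)}$                     |
| `knn_dist`    | $\alpha_\delta \cdot (\gamma + \lambda_x^k)$         |
| `knn_std`     | $\alpha_\delta \cdot (\gamma + \xi_x^k)$             |

$\alpha_\delta$ is the $\lceil (1-\delta)(n+1) \rceil$-th smallest
calibration score. $\mu(x)$ is a second regressor (same family as the
point model) trained on proper-training features to predict
$\ln(|\text{residual}| + \beta)$, $\beta = 0.01$, so the normalizer
$e^{\mu}$ is strictly positive. $\lambda_x^k$ is the mean distance of $x$
to its $k$ nearest proper-training pairs and $\xi_x^k$ the standard
deviation of those neighbours' labels, each divided by the median of the
same statistic over the proper-training pairs (a unit-median, outlier-robust
normalization; the mean is available as an option). The sensitivity
parameter $\gamma$ can be tuned on a held-out validation split with
`tune_gamma()`: among values valid at every level whose mean error rate
does not exceed the mean of the maximal permissible rates, the one with the
narrowest median region wins.

These baselines were formulated for single-entity QSAR; adapting them to
pairs requires a pair distance. We combine the two similarities
multiplicatively, $d(x, z) = 1 - s_{comp}(c_x, c_z)\, s_{targ}(t_x, t_z)$,
so that $d = 0$ exactly when both entities match. This adaptation is a
design choice of this package.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 250 | compound neighbours bounding $Z_c$ |
| `q` | 25 | target neighbours bounding $Z_c$ |
| `min_calibration_size` | 10 | abstain below this $N_{Z_c}$ |
| confidence grid | 75–99% | levels at which regions are emitted |
| CV geometry | 10 × 10 | repeats × folds for the CV scores |
| calibration split | min(4000, 20%) | baseline calibration pairs |
| baseline kNN `k` | 25 | neighbours for $\lambda$/$\xi$ |
| `gamma` | 0 | kNN normalizer sensitivity |
| fingerprint | radius 2, 2048 bits | Morgan/Tanimoto representation |
| alignment | BLOSUM62, gap 10/4 | Smith–Waterman parameters |

`k` and `q` should scale with the entity counts: with only dozens of
compounds or targets, `k = 25` and `q = 10` are more appropriate, and both
are clamped to the available counts (with a warning) when set too large.
The affine-gap convention is `gap_open + (L - 1) * gap_extend` for a gap of
length `L`, matching the protein-alignment library convention the defaults
were taken from; target similarity is self-normalized,
$s(a,b) = \mathrm{SW}(a,b)/\sqrt{\mathrm{SW}(a,a)\,\mathrm{SW}(b,b)}$, with
a raw-score mode also exposed through `smith_waterman_score()`.

## The synthetic landscape

Real kinase-inhibitor data cannot be redistributed with the package, so
every test runs on a generated landscape (`synth_generate()`) that carries
the statistical structure the method exploits:

- **clustered chemistry** — each compound cluster owns a disjoint block of
  always-set fingerprint bits (24 of 256 by default) over a background of
  independent bits at rate 0.08, making within-cluster Tanimoto similarity
  stochastically dominate between-cluster similarity;
- **protein families** — one random ancestor sequence per family
  (60 residues by default), members derived by independent per-site
  substitution at rate 0.15, so alignment similarity tracks family
  membership; no indels are introduced, which keeps the test oracle cheap
  and is a deliberate simplification;
- **a learnable surface** — affinities follow a rank-4 bilinear form
  $y = 6 + u_c^\top v_t/\sqrt{d} + \varepsilon$ with group-level latent
  vectors, member-level jitter, and Gaussian assay noise
  ($\sigma = 0.6$ log units by default, the order of inter-assay
  variability in public binding databases).

Cold-start difficulty is created by `shift_holdout()`: whole compound
clusters and/or target families are removed from training, producing the
usual four scenarios (S1 seen entities, S2 unseen compounds, S3 unseen
targets, S4 both unseen). `scenario_split()` offers the same construction
for user data, with either random entity holdout or single-linkage
cluster holdout at a configurable similarity threshold (default 0.7).

What the generator does *not* emulate: real medicinal-chemistry structure
(no SMILES are produced), kinome phylogeny, heteroscedastic or censored
assay noise, and the long-tailed bioactivity distributions of public
databases. Passing validity tests on this landscape therefore demonstrates
the correctness and calibration behaviour of the conformal machinery under
controlled exchangeability and shift — not performance on any particular
public benchmark.

## Study sizes

The package's own validity studies use ten replicate landscapes of
125 compounds × 48 targets with 5/6 of the grid measured — 3000 training
pairs, a 500-pair calibration split for the fixed-calibration baseline and
2000 seen-pair test interactions per replicate — with `k = 25`, `q = 10`.
These sizes give dynamic calibration sets of ~125 pairs, large enough for
the 99% level to be meaningful while keeping a full study run in minutes.

## Numerical choices

- **Tie handling**: similarity ties rank by ascending id; score comparisons
  are inclusive (`<=`), which can only enlarge the dominated fraction and
  never widens a region.
- **Quantile conventions**: the fixed-calibration baselines use
  $\lceil (1-\delta)(n+1) \rceil$ (finite-sample valid, possibly slightly
  conservative); the dynamic rule uses the $N_{Z_c}$-denominator
  construction described above, which has *no* $+1$ correction. At extreme
  levels this costs up to roughly $1/N_{Z_c}$ of error budget: with
  $N_{Z_c} \approx 125$, the CV variant's 99% error rate can run a few
  tenths of a percent above nominal on exchangeable data, while remaining
  conservative at every other level; the NN variant buys back conservatism
  through abstention.
- **Degenerate cases**: an empty $Z_c$ abstains; two all-zero fingerprints
  have Tanimoto similarity 1 by convention (warned); a calibration set too
  small for $\lceil (1-\delta)(n+1) \rceil$ yields an infinite baseline
  region flagged as such; an all-zero residual vector degenerates the error
  model to the constant $\ln \beta$; a zero median in the kNN normalizers
  is an error rather than a silent division by zero.
- **Seeds**: one master seed per fitting function expands deterministically
  into child seeds for fold assignment, model fitting and splitting; rerun
  with the same seed is bit-identical.

## Open design decisions

- Cross-validation folds partition *pairs*, not entities (the literal
  reading of per-training-sample scores); entity-level folds can be
  simulated by evaluating on entity-held-out scenarios instead.
- Duplicate measurements of a pair are averaged (`aggregate_duplicates`),
  the least-surprising reconciliation when Kd- and Ki-derived values
  coexist; the aggregator is a function argument.
- A test pair that also occurs in training (the seen-pair scenario) stays
  in its own calibration set by default; `exclude_self = TRUE` is available
  for leakage-sensitive analyses.
- The point prediction always comes from the full-data model, not from CV
  means: CV predictions exist for training pairs only, and using them for
  the region centre would make seen and unseen pairs incomparable.
- No normalizer is applied to the dynamic scores: the local calibration set
  already carries the locality information, and width-shrinking
  normalization trades the method's conservative behaviour for
  overconfidence in shifted scenarios.
- `gamma` tuning requires a held-out validation split; tuning on test
  labels would leak the quantity being certified.

## Limitations

Dynamic calibration needs *measured* local neighbours: sparse corners of
the interaction space produce small calibration sets and frequent
abstention (this is by design — a region the data cannot support is not
emitted). Runtime is dominated by the repeated cross-validation pass over
the training set and, for large entity collections, by the all-pairs
similarity matrices, which can be cached to disk. Regions are symmetric by
construction; asymmetric or quantile-shaped regions are out of scope.
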