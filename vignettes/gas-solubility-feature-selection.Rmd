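---
title: "Gas-solubility and Aquila wrapper feature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas-solubility and Aquila wrapper feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, the numerical
conventions, and the design choices that were genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The problem

Given an encoded table of patient attributes (rows = patients, columns =
numeric features derived from history, clinical examination, laboratory
and radiology items) and a four-state discharge outcome
(mortality / morbidity / the same / improved), find a small feature subset
on which a classifier predicts the outcome well. The package treats this
as *wrapper* feature selection: the quality of a subset is measured by
actually fitting a classifier on it, not by a filter statistic.

## 2. The wrapper objective

A candidate solution is a continuous vector $X \in [lb, ub]^D$. It is
binarized by a strict threshold, $BX_j = 1 \iff X_j > 0.5$, and scored by

$$\mathrm{Fit}(BX) = \lambda\,\gamma(BX) + (1-\lambda)\,\frac{|BX|}{D},$$

minimized, where $\gamma$ is the misclassification rate of the subset
classifier trained on the masked 80% training half and evaluated on the
masked 20% holdout, and $|BX|/D$ the selected fraction.

Open points resolved here:

* **$\gamma$ is the 80/20 holdout error.** No other error notion is
  constructed by the pipeline, so the holdout split that the wrapper
  already maintains defines $\gamma$. The split is stratified by outcome
  class and deterministic given the seed.
* **$\lambda = 0.99$ by default** (configurable). This is the standard
  weighting in the wrapper-selection literature for objectives of exactly
  this form: classification error dominates, and the size term only breaks
  ties between subsets of equal error.
* **All-zero masks are never fitted.** They receive the penalty
  $1 + \lambda$, strictly worse than any feasible value (since
  $\gamma \le 1$ and the size term is $\le 1 - \lambda$), which keeps the
  objective total without training degenerate classifiers.
* **Domain range vs threshold.** The run configuration fixes the search
  box at $[-1, 1]$ while the binarization threshold is $0.5$; only the top
  quarter of the range selects a feature, so random initial positions
  select each feature with probability $1/4$. Both values are honored as
  configured defaults; `fitness_spec(domain_range = c(0, 1))` restores the
  symmetric alternative.
* **Fitness caching.** Many positions binarize to the same mask; fitness
  is cached by the mask bits. This is purely an optimization — the
  classifier fit dominates the cost — with no semantic effect.

## 3. The HGSO engine

Agents are gas particles. The population is partitioned into contiguous,
near-equal clusters ("gas types"; default 2 — the smallest count that
exercises the clustering machinery, since no canonical value exists), each
with a Henry coefficient $H_j$, per-agent partial pressures $P_{ij}$ and a
Van't Hoff constant $C_j$, initialized as $l_1 u$, $l_2 u$, $l_3 u$ with
fresh uniforms $u$ and $l_1 = 5\cdot10^{-2}$, $l_2 = 100$,
$l_3 = 1\cdot10^{-2}$.

Per iteration $t$ of the budget $T$:

1. temperature $T(t) = \exp(-t/T)$;
2. interaction ability
   $\gamma_i = \beta \exp\!\big(-(F_{best}+\epsilon)/(F_i+\epsilon)\big)$;
3. position update
   $X_i \leftarrow X_i + F r \gamma_i (X_{c(i),best} - X_i)
   + F r \alpha (S_i X_{best} - X_i)$, clamped to the box, where $F=\pm1$
   is a per-agent direction flag and $r$ a fresh uniform;
4. Henry update
   $H_j \leftarrow H_j \exp\!\big(-C_j(1/T(t) - 1/T^\theta)\big)$ with
   $T^\theta = 298.15$, then solubility $S_{ij} = K H_j P_{ij}$;
5. escape: $N_w = \lfloor N(u(c_2-c_1)+c_1)\rfloor$ worst agents
   ($c_1 = 0.1$, $c_2 = 0.2$) are re-drawn uniformly in the box and
   re-evaluated;
6. cluster and swarm bests are refreshed (elitist memory).

Design choices where the formulation is silent:

* **$K = \alpha = \beta = 1$, $\epsilon = 0.05$** — the identity-scale
  choices of the original gas-solubility formulation; all configurable for
  sensitivity runs.
* **Direction flag** $F$ is drawn uniformly $\pm 1$ per agent per
  iteration — the simplest unbiased reading of "direction flag that
  offers diversity".
* **A single fresh $r$** multiplies both attraction terms, exactly as the
  update rule is printed with one $r$.
* **Parenthesization of the swarm-best term**: the rule is printed with
  the solubility multiplying $X_{best}$ alone,
  $\alpha(S_{ij} X_{best} - X_{ij})$, not the whole difference. It is
  implemented as printed; note that when $S_{ij} \ne 1$ the term does not
  vanish even at $X_{ij} = X_{best}$.
* **$N_w$ rounding**: floor, with $N_w \ge 1$ enforced for $N \ge 10$ so
  the escape mechanism never silently disappears in realistically sized
  swarms; ties on worst fitness are broken by lowest agent index.
* **Clamping, not reflection,** at the box bounds — the simplest contract
  that keeps every position feasible after every operation.
* **Partial pressures are constant after initialization**; no update step
  for $P_{ij}$ exists in the loop, so none is invented.
* **Minimization convention** throughout (the wrapper fitness combines
  error and subset size); wrap an objective with `function(x) -f(x)` to
  maximize.

### Diversity diagnostics

$\mathrm{Div}_j = \frac1N \sum_i |\mathrm{median}(x_j) - x_{ij}|$ and
$\mathrm{Div}_t$ is the **average over the $D$ dimensions**. (The printed
formula carries a $1/N$ in front of the dimension sum, but the surrounding
text defines the quantity as the average of the $D$ dimensions; the $1/N$
is a typo and $1/D$ is implemented. The median over an even number of
agents is the midpoint of the two central values.) Exploration% is
$100\,\mathrm{Div}_t/\mathrm{Div}_{max}$ over the run, Exploitation% its
complement; the two sum to 100 by construction, and an all-zero diversity
series (a fully collapsed swarm) raises an explicit error rather than
dividing by zero.

## 4. The Aquila layer and the hybrid

AQO switches from exploration to exploitation when $t \le \frac23 T$ fails
(the boundary iteration is exploration). The four behaviour update rules
are not specified in the clinical formulation; they are taken from the
canonical Aquila optimizer — expanded exploration toward the
best-so-far/mean, narrowed exploration with a Lévy flight around a random
peer and a spiral term, expanded exploitation with bound-scaled
adjustment ($\alpha = \delta = 0.1$), and swooping with the quality
function $QF(t) = t^{(2u-1)/(1-T)^2}$ — with every coefficient exposed in
`aqo_params()`. Proposals are accepted greedily per agent.

**Coupling.** How the two optimizers combine is never operationalized in
the source formulation — sequential, nested, and AQO-only-for-binarization
readings are all consistent with its text. The package implements the
three defensible strategies behind one switch: `"hgso"`, `"aqo"`, and the
default-for-the-headline-pipeline `"hybrid"` — AQO explores for the first
half of the budget, then its final swarm seeds the HGSO population
(because AQO's greedy acceptance keeps each agent at its personal best,
the hand-off can never lose the incumbent best).

## 5. Classifiers

All learners sit behind one `gs_fit()` / `gs_predict()` contract returning
per-class probability rows that sum to one, with the label always the
row-wise argmax (ties broken by class order). Defaults: k-NN with $k=5$;
random forest with 100 bagged trees, gini splits, per-node
$\mathrm{mtry} = \lfloor\sqrt p\rfloor$; C4.5-style tree with gain-ratio
splits and no effective depth cap; one hidden layer of 64 tanh units
trained full-batch with Adam, weight decay $10^{-4}$ and early stopping;
SVM with an RBF kernel ($\mathrm{gamma} = 1/p$) realized by 200 random
Fourier features and one-vs-rest squared-hinge linear models fitted by
BFGS, probabilities as the softmax of the one-vs-rest margins.

The surrounding environment provides no tree / forest / SVM / MLP
packages, so these learners are implemented in-package (the tree in C++);
they are conventional textbook versions, fully seeded, not re-tuned
per-dataset — hyperparameter search is out of scope.

**RF-SVM double classifier.** The combination rule behind the name is
unspecified; soft voting (elementwise mean of the two probability
vectors, argmax with class-order tie-break) is the minimal interpretation
and the default. A stacking mode (RF out-of-fold probabilities as SVM
inputs) is available behind `combine = "stack"` because the name admits
that reading too.

## 6. Metrics and model comparison

Accuracy, recall, precision and F-measure follow the standard binary
formulas; the four-class task uses **unweighted macro one-vs-rest
averaging** (the outcome is described as balanced, where macro and
weighted averaging approximately coincide); accuracy is trace/total;
sensitivity is reported as its own field but *is* macro recall — no
distinct formula exists for it. Zero-denominator ratios return 0 with a
`degenerate` flag instead of raising, keeping batch evaluation total.

The Wilcoxon signed-rank test drops zero differences, midranks ties, and
uses the smaller signed-rank sum as the statistic. The two-sided p-value
is **exact for $n \le 20$** — the null distribution of the rank sum is
built by subset-sum convolution over doubled midranks, equivalent to
enumerating all $2^n$ sign patterns — and a normal approximation with
continuity and tie correction beyond. The repeated-comparison protocol
defaults to 30 runs of 10 solutions and 100 iterations.

## 7. The synthetic generator: what it emulates, and what not

The generator reproduces the *shape* of a private neurosurgical extract:
four outcome classes with counts 800/700/850/650 (3000 records), 37
encoded features tagged by domain group (history / clinical / lab /
radiology), a mix of informative and pure-noise columns, some binary
flags, and all columns min-max mapped into the configured domain range.

Informative structure: for each informative column the four classes sit at
centred, equally spaced levels with consecutive gap `effect_size` (in
units of the within-class SD, fixed at 1), and the class-to-level
assignment is freshly permuted per column. This realizes "standardized
mean separation = effect_size" with an identifiable, auditable ground
truth (`informative_mask`, `class_centroids`) so wrapper recovery is
measurable. Noise columns are class-independent Gaussians with SD
`noise_scale`; a quarter of them (default) are dichotomized at the latent
median into radiology-style 0/1 flags — thresholding a class-independent
latent keeps the truth well defined. Defaults: 12 informative + 25 noise
(= the 37-attribute schema), `effect_size = 2` — a separation at which a
k-NN on the informative subspace is clearly better than on the noise
subspace yet single columns are far from individually decisive, which is
the regime wrapper selection is for.

What it does **not** emulate: clinical correlations (e.g. coma-scale
physiology vs outcome), feature dependence structure, missingness,
measurement noise heterogeneity, or any distributional facts about the
real features (none are published). A green recovery test therefore
establishes that the selector finds planted low-dimensional Gaussian
signal under class-independent noise — not that it would rank real
clinical attributes correctly.

Relatedly, the cohort size is a free parameter: the source reports both
1160 patients and 3000 records without reconciling them; the generator
takes the per-class counts as inputs and defaults to the published
800/700/850/650.

## 8. Numerical conventions and degenerate inputs

* Splits: train size $= \mathrm{round}(f n)$ per stratum (half-up); the
  fraction-$f$ and fraction-$(1{-}f)$ splits under one seed are exact
  complements by construction (train rows come from the front of the
  seeded permutation for $f \ge 0.5$, from the back otherwise).
* Encoding: constant columns under min-max map to the range midpoint
  (divide-by-zero guard that preserves column count); unseen categories
  error in strict mode; missing cells are rejected unless imputation
  (median / mode) is requested.
* CSVs are written with 17 significant digits so read-back reproduces
  doubles bit-for-bit.
* Per-cell seeds in the experiment grid are derived from the base seed by
  an XOR-based map kept inside the 32-bit integer range; generated data is
  seeded by the *run id* only, so all models of one run see the same
  records and stay paired for the signed-rank comparison.
* Report SDs are population SDs (divide by $n$), declared in the manifest.
* `results.csv` withholds the wall-time column (kept in memory) so a
  re-run under the same configuration is byte-identical.
* The undefined run-table field "Lsa Epoch" is carried as an opaque
  config passthrough (`extra`) and never interpreted.

## 9. Known limitations

* The wrapper evaluates against a single fixed holdout, not
  cross-validation; with small cohorts the selected mask inherits holdout
  noise.
* The SVM's probabilities are margin softmaxes, not calibrated
  probabilities; the soft-voting ensemble inherits this.
* The random-Fourier-feature SVM is an approximation to the exact RBF
  kernel; at 200 features it is adequate for tens of input dimensions but
  not a drop-in for exact kernel machines on high-dimensional problems.
* No parallel evaluation, no constraint handling beyond box bounds, no
  benchmark-suite comparison against other metaheuristics, and no
  reproduction of the published accuracy tables — those were computed on a
  private hospital dataset with no public accession.
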