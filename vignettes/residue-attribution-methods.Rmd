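---
title: "Residue-level attribution for protein sequence models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level attribution for protein sequence models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protexplain)
```

# The problem

A protein language model maps a length-$n$ amino-acid sequence to an
$n \times e$ matrix of per-residue embedding vectors; a windowed
interaction-site predictor maps the $2w+1$ embedding vectors centred on a
residue to a propensity in $(0,1)$. Both are opaque. Feature attribution
assigns every input element an importance score for one scalar output, and
this package implements the full evaluation stack around that idea: nine
attribution operators, the algebra that aggregates element-level scores into
residue-on-residue influence, and the statistics that decide whether those
influence patterns track known biochemistry.

Two facts shape the design. First, attribution is taken with respect to the
embedding-layer *output activations*, never the discrete letters: the look-up
layer has no gradient, and the continuous activations are the first
differentiable surface. Second, the element-level embedding tensor $E$ has
$n^2 e^2$ entries — terabytes at $e \approx 10^3$ — so everything downstream
of the per-scalar attribution maps can be computed in a streaming fashion
without materializing $E$.

# Models under explanation

Full-scale pretrained models are out of scope; the package ships desk-scale
stand-ins exposing the same differentiable contract, plus an adapter route
(`linear_handle()`, or any list implementing `forward`, `scalar_forward`,
`scalar_gradient`, optionally `deeplift_attr`) so a real model can be plugged
in.

The **toy embedder** is a two-layer rectifier network. Position mixing uses
fixed weights $\exp(-\lambda\,|i-j|)$, so $\lambda$ (dimensionless, default 1)
controls how far influence reaches along the chain; $\lambda = 10$ makes the
model effectively local, $\lambda = 0$ removes locality. The **window
predictor** is a one-hidden-layer rectifier network with a sigmoidal head,
so outputs are strictly inside $(0,1)$. Defaults are $e = 8$, hidden width
16, and half-window $w = 4$ — a window of 9 residues, a realistic size for
sliding-window site predictors; the published system's $w$ is not stated, so
$w$ is a parameter everywhere and never hard-coded. At these sizes the full
$E$ for $n = 44$ has $\sim 10^5$ entries: the algebra is size-independent and
desk-scale testing exercises every code path.

Rectifiers are used throughout (not smooth activations) because two of the
nine operators — deconvolution and guided backpropagation — are *defined* by
modified rectifier backward rules: deconvolution back-propagates only the
positive part of the upstream signal regardless of the forward activation;
guided backpropagation additionally zeroes positions whose forward
pre-activation is non-positive. On a purely linear model all rules coincide,
and requesting a modified rule for a rectifier-free model is a contract
error.

**Planted structure.** An optional property sensitivity multiplies the
contribution of residue $j$ by $\exp(\beta\, z_p(\text{letter}_j))$, where
$z_p$ is the standardized value of one numerical property (hydrophobicity,
molecular mass, van der Waals volume, dipole moment). With $\beta = 1$ the
downstream Kendall test recovers the planted property with p-values around
$10^{-6}$; with $\beta = 0$ the pooled false-positive rate of the numerical
tests sits at the nominal $\alpha$ (the familywise rate over 4-8 correlated
tests per replicate is naturally higher, roughly 15-25%, which is why the
null-calibration test asserts the pooled per-test rate, not a familywise
one).

# The attribution operators

All nine operators act on one scalar output at a time. Hyperparameters are
not prescribed by any published source, so the defaults follow common
practice and are recorded in `attribution_config()`: all-zero baselines for
every reference-based method (the activation of an absent token), 50
midpoint steps for integrated gradients, 200 Monte-Carlo samples for
LIME/KernelSHAP and 50 for GradientSHAP, LIME kernel width
$0.75\sqrt{d}$, ridge $10^{-3}$, and an explicit integer seed for every
stochastic method (bit-reproducible outputs).

Design choices worth stating:

- **DeepLIFT** implements the rescale rule only: each nonlinearity
  propagates $(h - h_0)/(z - z_0)$, falling back to the local gradient when
  $|z - z_0| < 10^{-9}$. Summation-to-delta then holds exactly for rectifier
  networks (checked to $10^{-6}$ over 20 seeded nets).
- **Integrated gradients** uses the midpoint Riemann rule. Completeness is a
  limit statement: on rectifier nets the kink error at 512 steps is usually
  below $10^{-3}$ but can reach $10^{-2}$; by 4096 steps every test net is
  inside $10^{-3}$.
- **KernelSHAP** solves the Shapley-kernel weighted least squares with the
  efficiency constraint enforced exactly via its KKT system. All $2^d$
  coalitions are enumerated when $2^d \le 4096$ (the result then *is* the
  exact Shapley vector); otherwise a budgeted stratified scheme completes
  paired coalition-size strata outright and samples the remaining sizes
  antithetically from the kernel law — at $d = 13$ with a 2000-evaluation
  budget this stays within ~1% of brute-force Shapley values.
- **LIME** uses one feature per input element (matching the element-level
  definition of $E$), binary masks to the baseline, proximity weights
  $\exp(-m/\text{width}^2)$ for $m$ masked elements, and an unpenalized
  intercept. With full mask enumeration and zero ridge it recovers additive
  models exactly.

# Aggregation algebra

With $E[i,k,j,\ell]$ the effect of input element $(j,\ell)$ on output element
$(i,k)$:

$$XE[i,j] = \sum_{k=1}^{e}\sum_{\ell=1}^{e} E[i,k,j,\ell], \qquad
T[i,k,j] = \sum_{\ell=1}^{e} E[i,k,j,\ell],$$

and for the predictor tensor $P[i,k,\ell]$ over each residue's
$(2w+1) \times e$ window:

$$XP[i,j] = \sum_{k=1}^{2w+1}\sum_{\ell=1}^{e}
  P[i,k,\ell]\; T[i+k-(w+1),\, \ell,\, j].$$

The $i+k-(w+1)$ offset is the single most error-prone index expression in
the pipeline; it is honoured exactly in 1-based form, property-tested at both
sequence ends, and window positions outside $[1, n]$ contribute zero by
default (consistent with zero-padded prediction windows; an `"error"`
boundary policy is available). Sums are raw signed sums — no absolute value,
no normalization — and downstream consumers pick their transform. Streamed
and materialized paths accumulate in the same $(k,\ell)$-ascending order and
are bit-identical; for saliency, $XP$ equals the gradient of the composed
model by the chain rule, which the suite verifies against central finite
differences to $10^{-8}$.

# Statistical evaluation

**Unit of observation.** Mann–Whitney tests run on *pooled per-residue
scores* across all proteins, not on per-amino-acid means: published p-values
down to $10^{-236}$ are only reachable with residue-level sample sizes,
whereas the Kendall tests are explicitly defined on the 20-vector of
per-amino-acid mean scores (alphabetical letter order everywhere). Scores are
row means (target role: influence received) and column means (source role:
influence exerted). The signed transform is the default for property tests
(the formulas are plain sums); the absolute transform is the default for
distance profiles (which plot decaying magnitudes) and is what the planted
sensitivity analyses use, since gain-planting scales magnitudes, not signs.

**Tests.** Mann–Whitney U uses midranks, exact enumeration when
$n_1 n_2 \le 200$ without ties, and the tie-corrected normal approximation
otherwise; Kendall's $\tau$-b uses the tie-corrected normal approximation.
Both sit inside $[0.04, 0.06]$ null rejection at $\alpha = 0.05$ over 5000
replicates. The acidity/basicity test compares only D/E against H/K/R
residues; aromaticity compares F/Y/W against the rest; interactivity needs
per-residue labels and is marked *not evaluable* (never silently passed)
when labels are absent — as they are for the packaged manifest, whose
published interaction annotations derive from an external dataset that is
not redistributed. No multiple-testing correction is applied anywhere
($\alpha = 0.05$ throughout), matching the published protocol.

**Pass-count summaries.** `summarize_pass_counts()`,
`crosstab_embedding_vs_prediction()` and `exclusive_pass_analysis()`
recompute the published headline tables from any complete result grid. The
exclusivity fraction is reported under two denominators because the published
percentages are mutually inconsistent: the categorical figure matches
exactly-one / full-grid, while the numerical and overall figures match
exactly-one / union-of-passed. Both are first-class outputs
(`pct_of_grid`, `pct_of_union`); integer percentages round half away from
zero.

**Separability.** The real-vs-random check pairs every attribution matrix
with a moment-matched Gaussian matrix (same dimensions, mean, SD), resamples
all matrices bilinearly to a fixed $32 \times 32$ grid (the published
protocol does not state how variable-size matrices were featurized),
standardizes on the training split, and trains a soft-margin RBF-kernel SVM
(C-SVC dual solved with `quadprog`; $\gamma$ = 1/(d·var), C = 1) on a seeded
80% split. Structured toy-model matrices separate perfectly (100% held-out
accuracy); random-vs-random sits at chance.

# Explanation infidelity

$$\mathrm{INFD}(\Phi, f, x) = \mathbb{E}_{I \sim \mu_I}
  \left[\left(I^{\top}\Phi - (f(x) - f(x - I))\right)^2\right]$$

with $I$ i.i.d. Gaussian, mean 0, $\sigma = 0.01$ in raw activation units
(whether the published $\sigma$ was relative to activation scale is unstated;
raw units are assumed). The Monte-Carlo sample count is also unstated;
default 100, recorded in the spec object. Draws are common random numbers —
prefix-stable in the sample count and a pure function of the seed and input
dimension — so per-scalar recomputation is bit-identical to the batched
path, and enlarging the sample refines rather than replaces an estimate.
Convergence diagnostics should use imperfect explanations: for an
exact-gradient map the residual is zero except when a perturbation crosses a
rectifier kink, a rare-event regime no fixed sample size estimates stably.

$\mathrm{INFD}_E$ is the plain mean of the $n \times e$ per-element matrix
$I^E$. The prediction-mode aggregate scores the per-residue predictor
attributions $P[i,:,:]$ (the published text says the formula was applied to
$T[i,:,:]$, but $T$ is not an attribution of the predictor function — scoring
it against the predictor would be type-inconsistent, so the per-residue maps
are scored and the reading is recorded here). Interior residues, covered by
all $2w+1$ windows, enter the weighted sum $S$ with weight $2w+1$; terminal
residues $i$ and $n-i+1$ ($i \le w$) with weight $w+i$. The published
denominator $(n-2w)(2w+1) + w(3w+1)$ annotates a sum whose algebraic value is
$w(3w+1)/2$; both variants are implemented
(`denominator = "as_printed"` / `"consistent"`) and the as-printed one is the
default — the package never silently corrects its source. The published
hand-checkable case ($n=5$, $w=1$, constant $I^E = a$, $I^P = b$) gives
$S = 13(a+b)$, denominator 13, $\mathrm{INFD}_P = a + b$, which the suite
asserts. Mixed-case symbols in the printed formula are read as typos for
$I^E$ and $I^P$.

# Synthetic data: what it does and does not establish

`generate_synthetic_proteins()` draws residues uniformly over the 20-letter
alphabet (optionally composition-biased) and labels i.i.d. Bernoulli(0.3) —
roughly the site density of curated interaction-site datasets; lengths
default to the published 30–44 range. Synthetic sequences have no real
composition bias, no autocorrelated interaction stretches, and no
evolutionary structure, and the toy models have no learned biology. A green
test therefore establishes that the *machinery* is correct — operators
satisfy their axioms, the algebra composes, planted signal is recovered at
the stated power, null calibration holds — not that any real embedding
encodes any property. Claims about real models enter only through the
transcribed p-value fixtures, and the package reproduces the published
summaries of those fixtures exactly.

# Numerical choices and degenerate inputs

- Pass rule is strict ($p < \alpha$); nine published rows print $p = 1.000$
  exactly, so "all tests pass" requires $\alpha > 1$, not $\alpha = 1$.
- Constant score vectors or property columns make Kendall's $\tau$
  undefined; such tests are marked not evaluable rather than erroring a
  whole run. Empty categories behave the same way.
- The LIME surrogate errors on a singular weighted design (after ridge);
  KernelSHAP errors on degenerate coalition samples.
- Per grid cell, pipeline failures are caught and recorded in the run
  manifest without aborting the run; outputs embed the master seed and a
  hash of the scientific configuration, and reruns are byte-identical.
- Serialization is plain text (TSV/JSON) throughout, including toy-model
  parameters and infidelity records.

# Known limitations

- Toy models are rectifier networks with fixed position-mixing weights, not
  transformers; attention-related phenomena are out of reach by design.
- The interaction labels of the 34 published test chains are not included
  (external dataset); interactivity tests on that manifest are not
  evaluable, while synthetic corpora always carry labels.
- Exact Mann–Whitney p-values are limited to small untied samples; both
  tests otherwise rely on tie-corrected normal approximations, adequate at
  the corpus sizes used here.
- The SVM separability check is a sanity floor, not a benchmark: perfect
  accuracy says attribution matrices are far from moment-matched noise,
  nothing more.
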