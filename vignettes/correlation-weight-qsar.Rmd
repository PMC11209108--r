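---
title: "Correlation-weight QSAR models from SMILES text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight QSAR models from SMILES text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralcw)
```

## The model

`coralcw` builds one-descriptor regression models for ecotoxicological
endpoints (chronic NOEC, acute EC50, on the log10 scale) directly from
SMILES strings:

$$\log_{10}(\mathrm{endpoint}) = C_0 + C_1 \times DCW(T, N)$$

The optimal descriptor $DCW(T, N)$ is the sum of *correlation weights* over
the molecule's **SMILES attributes**:

$$DCW(T, N) = \sum_k CW(S_k) + \sum_k CW(SS_k)$$

where $S_k$ ranges over the *SMILES atoms* — the undivided fragments of the
SMILES text: one printable symbol, a two-character element (`Cl`, `Br`), or
a whole bracket-atom span such as `[N+]` — and $SS_k$ over pairs of adjacent
SMILES atoms. No molecular graph is perceived: ring-closure digits, branch
parentheses and bond symbols are attributes too, because the descriptor
operates on the string itself. Pair attributes are order-normalized
(`key(a,b) == key(b,a)`), since a fragment read backwards describes the same
local structure.

Two integer parameters govern the descriptor:

* **T** (threshold, default 5): an attribute must occur in at least `T`
  compounds of the active training set to be *active* (optimizable). Rarer
  attributes are kept in the registry but *blocked* at weight exactly 0,
  which protects the model from fitting noise through features it has
  essentially never seen.
* **N** (epochs, default 15): the number of Monte Carlo sweeps over the
  active attributes.

Stereo markers (`/`, `\`, `@`) are stripped before tokenization: the
endpoint data aggregated from chronic/acute assays carry no
enantiomer-specific information, so chirality is deliberately not encoded.
SMILES are otherwise used exactly as given; dialect differences (e.g. nitro
group notations) are the caller's responsibility, and a pre-normalization
hook can be applied upstream of `read_endpoint_table()` if a standardization
rule is available.

## The four-subset protocol and the target function

Compounds are randomly assigned (seeded, near-equal quarters by default) to
**active training**, **passive training**, **calibration** and
**validation** subsets. The weights are fitted by maximizing

$$TF = r_{AT} + r_{PT} - |r_{AT} - r_{PT}| \times 0.1 + (IIC_C + CII_C) \times 0.3$$

where $r_{AT}$, $r_{PT}$ are Pearson correlations of DCW with the log
endpoint on the two training sets, and two correlation-quality indices are
computed on the *calibration* set from the predictions of the line fitted on
the active training set:

* **IIC**, the index of ideality of correlation: the correlation damped by
  the asymmetry of positive- and negative-residual mean absolute errors,
  $r \cdot \min(MAE^-, MAE^+)/\max(MAE^-, MAE^+)$. Residuals are
  observed − calculated; zero residuals count in the non-negative class. If
  all residuals share one sign the ratio is 0 (maximally non-ideal); for an
  exact fit the ratio is taken as 1 so that IIC equals the correlation.
* **CII**, the correlation intensity index:
  $1 - \sum_k \max(0, R_k - R)$, where $R_k$ is the correlation with point
  $k$ deleted. Values near 1 mean no single compound props up the
  correlation. A protest threshold (default 0) can ignore tiny gains.

Steering 30% of the objective toward the calibration set is deliberate
*statistical forcing*: it trades training-set fit for generalization, and
the validation set — untouched by the objective — is the honest test of
the result. The validation row of the report is therefore best compared
with the calibration row, not with the (intentionally sacrificed) training
rows.

The final $(C_0, C_1)$ are re-fitted by ordinary least squares on the
active training set (configurable to the union of both training sets), and
the panel of statistics (n, R², IIC, CII, leave-one-out Q², RMSE, MAE,
Fisher F = R²(n−2)/(1−R²)) is reported per subset. The ± values printed
with model coefficients are OLS standard errors.

## The Monte Carlo optimizer

The move scheme is coordinate-wise stochastic hill climbing. Per epoch the
active attributes are visited in seeded random order; for each attribute a
step $\delta = \mathrm{step} \times U(0,1]$ is drawn, both $w \pm \delta$
are evaluated, and the better variant is accepted only if it strictly
improves TF (ties reject). Two refinements matter in practice:

* **Capped step extension** (`extend_steps`, default on). After an
  accepted move the step is greedily doubled along the improving direction
  while TF keeps increasing, at most 5 doublings. Without extension the
  ascent crawls (with the default step 0.05 the weights can travel at most
  ±0.75 in 15 epochs, far too little to reorganize an initialization drawn
  from [1, 3]); without the cap a single coordinate can run away along the
  nearly flat asymptote of a correlation and freeze the rest of the
  search. Turning extension off reproduces the classic slow
  one-step-per-visit ascent (see the forcing study below for why that
  regime is interesting).
* **Probes.** `n_probes` independent restarts are run and the final state
  with the best TF wins. The TF landscape has genuine coordinate-wise local
  maxima — even replacing the stochastic move with an exact per-coordinate
  line search stalls below the attainable optimum — so restarts are the
  cheapest reliable escape. Within one probe the accepted-move TF sequence
  is non-decreasing, so the probe's final state is also its best.

DCW values are updated incrementally per perturbed attribute (the
compound-by-attribute count matrix is precomputed; a move changes DCW by
$\delta \times$ count column), which makes a TF evaluation O(n) in the
number of compounds. Everything is driven by one integer seed: two runs
with the same records, configuration and seed are bit-identical, and the
caller's RNG state is restored afterwards.

One subtlety deserves a note. Inside the objective, the calibration
predictions that feed IIC and CII are taken from the line fitted on the
calibration set itself, not from the training line. Tying them to the
training line couples them to the *sign* of its slope: as $r_{AT}$ crosses
zero the calibration predictions flip orientation and the calibration
terms jump discontinuously, and the ascent can end up pinned exactly at
$r_{AT} = 0$ on the wrong side of the cliff. With the calibration-internal
line the indices measure the quality of the DCW–endpoint relationship on
the calibration set in a sign-coherent way, and the pathology disappears
(on zero-noise benchmarks the same optimizer then recovers the planted
signal essentially exactly). The *reported* statistics always use the
actual model — training-line predictions — so this choice affects only
the search.

Weights are initialized uniformly in [1, 3]: a strictly positive start
guarantees the initial descriptor has nonzero variance (it is then roughly
proportional to molecule size) so the first correlations are defined.
Degenerate statistics inside the objective (zero-variance subsets,
undefined CII after a deletion) contribute 0 to TF rather than aborting the
run; a non-finite TF aborts with a diagnostic naming the offending
attribute.

## Applicability domain

An attribute's *distributional defect* measures how unevenly it is spread
between the active training and calibration sets:
$d(A) = |P_T(A) - P_C(A)| / (N_T(A) + N_C(A))$, where $P_X$ is the fraction
and $N_X$ the number of compounds in set $X$ containing $A$ (0 if absent
from both). A compound's defect is the sum over its attribute multiset. A
prediction is **in domain** when the compound's defect is at most
`multiplier` (default 2) times the mean defect of the training compounds
*and* the compound contains no attribute unseen in both reference sets —
unknown attributes contribute 0 to DCW, so a molecule made of them would
otherwise look deceptively "defect-free". This defect-based domain is an
adopted convention of the correlation-weight modeling tradition; the
multiplier is configurable and reported alongside every AD table.

## The synthetic benchmark

`generate_dataset()` emulates the input tables the pipeline consumes,
without any external data. Strings are drawn from a small grammar — atoms
from a configurable alphabet (default C, O, N, Cl, Br), optional `=` bonds,
balanced one-atom branches, at most one ring-closure digit pair — so every
generated string tokenizes and round-trips. Every attribute observed in the
generated set receives a planted weight (uniform in [−1, 1] by default;
signed, as fitted correlation weights typically are), and

$$\mathrm{endpoint}_{\log} = c_0 + c_1 \sum_A w_A \, n_A + \mathcal{N}(0, \sigma)$$

with defaults $c_0 = 0$, $c_1 = 1$ and $\sigma = 0.5$ — a typical
inter-laboratory spread on a log10 concentration scale. The hidden truth
(planted weights, noise-free descriptor) is returned for recovery tests.

What the generator does *not* emulate: chemically valid valence, aromatic
ring systems, the real abundance spectrum of functional groups, or any
nonlinear structure–activity relationship. Passing benchmarks therefore
demonstrate that the machinery recovers a planted linear signal under the
model's own assumptions — not that the model is adequate for any particular
chemical domain.

Two benchmark studies are wired into the test suite and the acceptance
script:

* **Zero-noise recovery** (n = 60, T = 1, $\sigma$ = 0). This study uses a
  deliberately low-dimensional generator instance — linear chains over
  C/O/N only, i.e. 9 attributes against 15 active-training compounds —
  because recovery is only a meaningful claim when the planted weights are
  identifiable. With the full default grammar the same 60 compounds span
  ~43 active attributes, and materially different weight vectors then
  achieve near-identical TF; no optimizer could (or should) be expected to
  single out the planted one. Optimization runs long for this study
  (60 epochs, step 0.5, 8 probes). Under these conditions the pipeline
  recovers the planted signal essentially exactly across generator seeds
  (validation R² ≈ 1, recovered-weight correlation ≈ 0.99).
  The weight correlation is computed between *estimable images*: both
  vectors are projected onto the row space of the column-centered count
  matrix, because null-space directions (e.g. +β on every single-token
  weight and −β on every pair weight, which shifts each DCW by the same
  constant) are absorbed by $C_0$ and cannot be recovered from data even in
  principle.
* **Statistical forcing** (noisy datasets of n = 120 — the size of a
  typical curated endpoint table — at T = 5, N = 15, step 0.05, with the
  classic one-step-per-visit ascent, i.e. `extend_steps = FALSE`). Mean
  calibration R² exceeds mean active-training R² across seeds. Two
  honest caveats. First, the inversion is a property of the
  *under-converged* operating regime: within the 15-epoch budget the
  sharp calibration-steered terms (IIC's MAE ratio in particular) climb
  faster than the training correlations. Published models of this family
  show training R² in the 0.2–0.6 range — far below what their attribute
  capacity could fit — which places them in exactly this regime. When the
  accelerated moves are enabled and the same budget converges much
  further, the training sets are fitted (partly to their own noise) and
  the gap reverses into an ordinary generalization gap. Second, the
  margin is small (roughly 0.00–0.10 of R² depending on the seed panel);
  the direction, not the size, is the reproducible signature. At n = 60
  the 15-compound training set is essentially interpolable by the
  attribute weights and the pattern inverts at any budget, which is why
  the study uses paper-sized datasets.

## Numerical choices and limitations

* Q² uses the PRESS identity $e_{(i)} = e_i/(1 - h_i)$, algebraically
  identical to refitting without each point; a brute-force refit oracle
  pins this in the tests.
* CII is computed from leave-one-out sufficient statistics in O(n) per
  call, pinned against the naive O(n²) recomputation to 1e-12.
* Zero-variance inputs: user-facing statistics raise classed errors (or
  return 0 with a warning for R²/IIC); inside `fit_statistics()` a failed
  statistic becomes `NA` so one degenerate subset cannot kill a report.
* Subset apportionment uses largest-remainder rounding, so sizes differ
  from exact fractions by less than one compound (122 → 31/31/30/30,
  94 → 24/24/23/23).
* Splits are plain seeded permutations without stratification; duplicate
  SMILES are kept as distinct records (with a message), since endpoint
  tables can legitimately report repeat studies.
* Model artifacts are plain text with 17-significant-digit numbers; the
  read/write round trip is bit-exact and covered by tests.
* The split protocol requires every subset non-empty (n ≥ 8 at the default
  quarters); statistics on very small subsets (n < ~10) are reported but
  carry little meaning.
* Endpoint units are taken as provided; only the log10 transform is
  applied. Mixing units across rows is not detected.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
tables: 60-compound benchmarks for recovery, ten 120-compound benchmarks
for the forcing study, and toy sets of 12–40 compounds elsewhere. These
sizes were chosen to match the curated endpoint tables the method targets
(~100 substances) while keeping every oracle (grid searches, explicit
leave-one-out refits, O(n²) recomputations) exact and fast.
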