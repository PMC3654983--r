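---
title: "Scoring Q/N-rich prion-forming domains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Q/N-rich prion-forming domains: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prdscan)
```

## The model

Prion-forming domains (PrDs) of the Q/N-rich class are low-complexity
protein segments enriched in glutamine and asparagine and depleted in
charged residues, whose composition — far more than their exact residue
order — determines their ability to switch into a self-templating
aggregated state. `prdscan` scores protein segments for compositional
similarity to known prion proteins with a position-independent log-odds
model.

For each amino acid $i$, the statistical potential in bits is

$$\mathrm{LOr}_i = \log_2 \frac{f_i}{p_i},$$

where $f_i$ is the residue's frequency in the positive training class and
$p_i$ its background frequency in the protein universe. Under the
position-independence assumption, a window of length $L$ scores

$$\mathrm{Score}_L = \sum_{l=1}^{L} \mathrm{LOr}_{l}
  \;+\; \sum_{j=1}^{P-1} \mathrm{LOr}\!\left(d_{j+1} - d_j\right),$$

where the second sum runs over *consecutive* proline pairs in the window
($d_1 < \dots < d_P$ are the proline positions) and
$\mathrm{LOr}(d)$ is a separate log-likelihood table over pair
separations $d \in \{1, \dots, 60\}$. Prolines are structural disruptors
whose effect depends on their spacing — clustered prolines are tolerated
in prion domains while scattered ones antagonise aggregation — which is
why their arrangement gets a term of its own on top of their
compositional contribution.

Sequences are scanned with a sliding window of 60 residues at step 1.
Windows reaching the predictive cutoff of 50 bits are reported; by
default one domain per protein (the maximal window, leftmost on ties),
with an `all` mode that reports every non-overlapping qualifying window
for multi-domain proteins.

### Why these assumptions

* **Composition, not sequence.** Shuffling experiments on yeast prions
  show that prion behaviour survives randomisation of the residue order,
  so the model deliberately ignores position.
* **Complete training sequences.** The shipped propensity table was
  estimated from complete prion protein sequences rather than inferred
  domain cores, so its class composition is *milder* than the
  composition of a 60-mer that actually passes 50 bits. This matters for
  interpreting the synthetic generators (below).
* **One domain per protein by default.** This mirrors the typical use of
  the score for proteome triage; the `all` mode exposes the multi-domain
  case.

## Shipped tables and their provenance

`builtin_propensity_table()` carries the published per-residue odds
ratios of the prion-domain class. Log-odds are recomputed as
$\log_2(\text{odds})$; for a few residues the published rounded odds and
published log-odds disagree in the third decimal (the printed log-odds
were evidently derived from unrounded odds), and those residues are
listed in the table's metadata rather than silently averaged. A second
column set (`set = "library1"`, mutagenesis-library propensities) is
shipped for comparison only and is not wired into scoring.

The background $p_i$ is the standard average amino-acid composition of
the Swiss-Prot knowledgebase, shipped as a frozen file for
reproducibility and overridable by training on any user FASTA. A useful
internal consistency check: $\sum_i \text{odds}_i \, p_i = 1.003$ with
this background, confirming it closely matches the background the odds
were originally computed against. Class frequencies are reconstructed as
$f_i \propto \text{odds}_i \, p_i$.

The shipped proline model (`builtin_proline_model()`) deserves a caveat:
estimating spacing log-likelihoods properly requires a multi-million
sequence non-redundant reference database. The packaged model is instead
trained at build time on a **synthetic** reference — 5,000
background-composition sequences of 100–600 residues drawn with a fixed
seed — and is therefore nearly neutral: its log-likelihoods are small
(|lor| ≲ 0.4 bits, mildly negative at long separations, an edge effect
of finite sequence length that real proteins share). The scoring
pipeline is exact; only the *strength* of the proline term awaits a real
reference set, via `train_proline_model()` on any FASTA.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `window_length` | 60 | residues | typical PrD-core length |
| `cutoff` | 50 | bits | accuracy-maximising calibration point |
| `pseudocount` | 0.5 | counts | Jeffreys smoothing; 0 gives raw ML frequencies and permits `-Inf` potentials |
| `mode` | `max` | — | one domain per protein; `all` for multi-domain |
| `ambiguity` | `zero` | — | B/J/O/U/X/Z contribute 0 bits; `skip` drops such windows |
| `max_distance` | 60 | residues | proline-pair separations modelled |
| `n_iterations` | 10,000 | — | bootstrap repeats; scale to taste |

## Numerical choices

* **Exact incremental scanning.** Both the sliding scanner and
  single-window scoring compute the compositional term as a 20-term dot
  product over the window's integer residue counts; the sliding pass
  updates the counts (exact integer arithmetic) rather than the floating
  score. The incremental and naive paths are therefore *bitwise*
  identical, which the tests assert on thousands of random sequences.
* **`-Inf` potentials** (possible only at pseudocount 0) are excluded
  from the dot product when the offending residue's count is zero, so
  they poison only windows that actually contain the residue.
* **Ties.** Maximal-window ties resolve to the leftmost start;
  accuracy-grid ties resolve to the largest (most conservative) cutoff.
* **Empirical p-values** use the add-one rule
  $p = (1 + \#\{x \ge s\})/(n + 1)$ against the per-protein best-score
  distribution, avoiding $p = 0$.
* **Proline flooring.** Distances never observed in training get the
  half-count value $\log_2\!\big((0.5/n_{\text{pairs}})/e_d\big)$, keeping
  corrections finite on arbitrary input.
* **Geometric spacing null.** The expected separation distribution of
  independently placed prolines is geometric in the proline frequency,
  renormalised over 1..60; it is the deterministic analytic null. A
  shuffle-based empirical null (`null = "shuffle"`) is available for
  sensitivity analysis.
* **Degenerate inputs.** Proteins shorter than the window are skipped
  with a notice; empty classes, zero-residue records and truncated flat
  files are errors; all-tied score sets yield the diagonal ROC
  (AUC 0.5), not an error.

## Design decisions at genuinely open points

* The proline term counts **consecutive pairs only** (the spacing sum is
  indexed by adjacent prolines), with $d = 1$ for adjacent prolines;
  all-pairs counting was rejected because it double-counts clusters.
* Proline separations are measured **within each window**, not across
  the whole protein: the correction is part of the window score and must
  be recomputed per window (a test exhibits the non-additivity
  counterexample).
* The resampling assessment of training stability splits the positive
  set into **disjoint halves without replacement** (retrain on one half,
  test on the other, negatives fixed), which matches the operational
  description of half-exclusion; sampling the training half *with*
  replacement is available behind `resample_train = TRUE`.
* Mean bootstrap ROC curves are **vertically averaged** on a fixed
  101-point FPR grid with linear interpolation.
* Rank-sum p-values are **two-sided**, exact for tie-free designs up to
  $n \cdot m \le 400$ and normal-approximated with tie correction
  otherwise.
* A positive call is **score ≥ cutoff** (closed lower bound).

## What the synthetic generators emulate — and what they do not

The generators exist so that every pipeline stage is testable with known
ground truth and no downloads.

* `"prd"` flavor: i.i.d. draws from the built-in class composition
  $f$ — what the training sequences look like *on average*. Used for
  parameter-recovery experiments.
* `"core"` flavor: $f$ tilted by $\text{odds}^{1/2}$ and renormalised
  (~60% Q/N), emulating the composition of validated prion-domain
  *cores*. This distinction is forced by arithmetic: a 60-mer drawn from
  $f$ itself scores only $60 \sum_i f_i \mathrm{LOr}_i \approx 45$ bits
  on average (the training composition is diluted by non-prion flanks),
  so a detectable planted domain must be core-like. Core draws exceed
  50 bits with probability > 0.99, which keeps spike-recovery
  experiments meaningful.
* `make_benchmark_sets()` embeds one 60-mer at composition
  $c \cdot f_{\text{core}} + (1 - c) \, p$ inside background hosts of
  60–250 residues (18 vs 18 by default); `make_proteome()` plants
  core 60-mers in background proteins of 100–800 residues.

Passing tests on these fixtures show that the *scoring machinery* and
*calibration stack* behave as designed. They do not show performance on
real proteomes: synthetic sequences have no homology structure, no
domain architecture, no organism-specific length or composition biases,
and their "background" is exactly the model's own background. Claims
about real prion proteins require the original training sequences and
real proteome files, which this package reads but does not bundle.

## Known limitations

* **Maximal-window localisation drifts.** The best-scoring window
  occasionally (≈2% of planted domains) shifts 3–4 residues off the true
  domain start by trading a few edge residues for compositionally
  similar flank residues. This is a property of maximum-score
  localisation, not a scanning bug: boundaries of compositional domains
  are intrinsically soft at the residue scale.
* **Small-sample propensity recovery is noise-limited.** Training on 18
  sequences (a few thousand residues) estimates each $\mathrm{LOr}_i$
  with a binomial standard error of roughly
  $1/(\ln 2 \sqrt{c_i})$ bits at expected count $c_i$ — about 0.26 bits
  at $c_i = 30$. Recovery experiments must set tolerances with this in
  mind; sub-0.1-bit accuracy needs tens of thousands of residues.
* **The shipped proline model is synthetic and neutral** (see above).
* The acceptance and test runs use desk-scale problem sizes chosen by
  us: 300–10,000 randomisation/bootstrap iterations, 500-protein
  synthetic proteomes, 1,000-case oracle sweeps. All are configurable
  upward.

## Session

```{r}
m <- prd_model()
m
coef(m)[c("Q", "N", "S", "Y", "E", "P")]
```
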