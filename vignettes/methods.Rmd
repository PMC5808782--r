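---
title: "Scoring gene–tissue associations: model, calibration, and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-tissue associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuescore)
```

## The model

The package treats "gene *g* is expressed in tissue *t*" as a claim
whose support comes from heterogeneous evidence channels — expression
datasets (microarray intensities, RNA-seq FPKM/TPM), curated
annotations, and literature co-mentions — and puts all of them on one
0–5 star scale. The machinery rests on three ideas.

**Fold enrichment as an empirical quality readout.** A gold standard of
trusted (gene, tissue) pairs is reliable but very incomplete, so a
dataset's *precision* cannot be estimated. What can be estimated is how
much more often high-expression pairs appear in the gold standard than
chance predicts. Restricting to genes shared between dataset and gold
standard and to the benchmark tissues, all gene–tissue pairs are sorted
by descending raw expression (ties broken by gene id then tissue id, so
the curve is a pure function of the data) and traversed in windows of
`window` pairs. Each window yields a point (x̄, e): the mean raw value,
and the window's gold-standard hit fraction divided by the expected
fraction |GS ∩ (G×T)| / (|G|·|T|).

**A sigmoid links raw expression to confidence.** The (x̄, e) points are
fitted, on the log10 x axis, with

$$\mathrm{score}(x) = a_0 + \frac{a_1 - a_0}{1 + e^{-a_2(\log_{10} x - a_3)}}$$

under the constraints $a_1 \ge a_0 \ge 0$, $a_2 \ge 0$. The asymptotes
are in fold-enrichment units: $a_1$ is the enrichment the dataset
attains for its most highly expressed pairs (its effective quality
ceiling), $a_3$ the log10 expression value at which confidence is
halfway there. Every raw value in the dataset is then mapped through the
fitted sigmoid to a confidence score. This deliberately does *not*
normalize across platforms: each dataset gets its own curve against its
organism's gold standard, which is what makes intensities and FPKMs
comparable downstream.

**One monotone calibration to stars.** Confidence scores from all
datasets and organisms pass through a single piecewise-linear map to
0–5 stars, anchored at quantiles of one large reference channel (the
human text-mining channel, because it exists for every related resource
and organism). Below the lowest anchor the map extrapolates linearly;
associations whose pre-clamp score is negative are removed outright
rather than floored at 0 — a 0-star association ("no evidence either
way") is different from one the calibration actively disbelieves.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `window` | 100 | pairs per enrichment bin; smaller = noisier bins, more of them |
| `step` | `window` | stride between bin starts; `window` gives independent bins, 1 the fully sliding curve |
| calibration anchors | quantiles (0.05, 0.5, 0.9, 1.0) → stars (0, 2, 4, 5) | reference-channel quantiles pinned to star values; median at 2★ |
| `star_max` | 5 | star-scale ceiling |
| `alpha` | 0.6 | text-mining mixing weight: s = C^α (C·C·· / (C_g·C_t))^(1−α) |
| `w_sentence`, `w_abstract` | 1.0, 0.2 | co-mention weights for same-sentence vs same-abstract-only |
| `x_floor` | half the smallest positive x | pseudo-floor before log10 for zero raw values |

Design choices where the design was genuinely open:

- **Stride.** "Sliding windows of 100 pairs" does not fix a stride; the
  default is non-overlapping bins (`step = window`) so the fitted points
  are statistically independent; `step = 1` is available.
- **Sort direction** is descending raw expression: higher abundance ⇒
  more confidence is the premise of the whole scheme.
- **Propagation uses max**, not sum or mean, over descendants in the
  `is_a` DAG: a star score means "expressed somewhere at or below this
  term", and max preserves that semantics; it also makes propagation
  idempotent and monotone, which the tests assert as laws. Only `is_a`
  edges are used; `part_of` is ignored.
- **Channel integration uses max** as well: the integrated score
  reflects the single strongest piece of evidence, and stays consistent
  with propagation (the two operations commute in the cases where both
  apply).
- **Replicate/probe collapsing** is the plain arithmetic mean on the raw
  scale — no log transform — and a probe whose alias resolves to more
  than one gene is removed *before* averaging, so ambiguity never leaks
  into any gene's profile. Probe→gene collapsing defaults to running
  before replicate averaging; the two commute, and the tests check that.
- **1:1 orthologs**: a group contributes a pair only when it has exactly
  one gene of each organism; a gene appearing in several groups would
  yield conflicting pairs, so all its pairs are voided (conservative —
  the alternative, first-wins, would make results depend on file order).
- **Correlation vectors zero-fill**: a gene observed in a dataset but
  scoreless in tissue *t* contributes 0 there, otherwise correlations
  would be computed only over co-detected pairs and reward sparse
  channels; `mode = "co_detected"` implements the alternative.
- **ROC negatives** are "not in the gold standard", so with an
  incomplete gold standard the false-positive rate is an upper bound;
  AUCs are comparative measures between datasets, not absolute
  precision.
- **Benchmarking and propagation.** Whether fold enrichment should see
  propagated or leaf-level calls is an open choice. The benchmark
  consumes whatever it is given: the recommended default is a
  gold standard expanded to ancestor terms via
  `propagate_gold_standard()` against unpropagated dataset calls
  (annotations imply their ancestors; dataset columns are measured
  where they are), and either side can be propagated explicitly before
  the call. In the demo world both annotations and measurements live at
  leaf terms, so the choice is moot there.

## Numerical choices

The sigmoid fit is unweighted least squares via `optim` (L-BFGS-B) on
the reparameterization (a₀, a₁−a₀, a₂, a₃) with box constraints,
multi-started from the deciles of the observed log10-x range crossed
with slopes {0.5, 1, 2} plus a flat candidate; the best candidate by RSS
wins, and an error (carrying the best candidate) is raised only if no
start converges. A constant curve is fitted happily as a₀ ≈ a₁ — the
degenerate sigmoid. Zero raw values get a pseudo-floor of half the
smallest positive value before log10. Calibration between anchors is
linear interpolation (`approx`, ties to max); when all anchor
confidences coincide the map degenerates to a step. Ties in raw
expression are broken lexicographically so every curve, channel file and
correlation is byte-reproducible for a fixed seed.

## The synthetic world

The generator states one explicit world: every (gene, tissue) pair is
expressed with prevalence `p = 0.3` (a typical fraction of tissues in
which a gene shows meaningful expression in bulk atlases); a fraction
`q` of genes has a 1:1 ortholog in each other organism and orthologous
genes share their truth exactly (the assumption that justifies
orthology-based gold-standard transfer; a `divergence` knob can flip a
fraction of transferred truths); the gold standard samples true pairs at
`coverage` (default 0.5 — reliable but incomplete, no false positives
unless `contamination > 0`); raw values are log-normal with
meanlog μ_on = 3 for expressed and μ_off = 0 for silent pairs, common
sdlog σ, so separation (μ_on − μ_off)/σ is the dataset's quality — 3 for
a clean atlas, 0.5 for a noisy one. The toy corpus mentions its organism
by name and co-mentions gene–tissue pairs drawn from the truth with
probability `elevation` (0.95), otherwise uniformly.

What the generator does *not* emulate: probe cross-hybridization, 3′
bias, library-size effects, correlated tissues (each pair's truth is
independent), non-uniform annotation bias in the gold standard, and
real NER ambiguity (dictionary matching is exact). A green test
therefore establishes that the *scoring machinery* is correct and that
quality ordering is recovered under the stated generative model — not
that any particular biological dataset would reach a particular AUC.

## Known limitations

- The calibration anchors and the text-mining α and weights are
  configuration, not reverse-engineered values of any production system;
  star scores from this package are internally consistent but not
  comparable to any published database's stars.
- The OBO reader implements the minimal id/name/is_a/is_obsolete subset
  only.
- The co-occurrence normalization is homogeneous of degree α (doubling
  the corpus scales scores by 2^α, not 2): the ratio term is
  scale-invariant by construction. Scores are comparable within a
  corpus, not across corpora of different sizes unless α = 1.
- `one_to_one_across` tuples are filtered per group; they are consistent
  with, but not identical to, intersecting pairwise 1:1 maps (which
  apply multi-group voiding pair-wise).
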