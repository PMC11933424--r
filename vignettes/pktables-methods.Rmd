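---
title: "Classifying tables in pharmacokinetic literature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tables in pharmacokinetic literature: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pktables)
```

## The problem

Tables in pharmacokinetic (PK) publications hold the parameter estimates —
clearance, volume of distribution, AUC, C~max~, half-life — that modellers
need for first-in-human predictions and for initialising population models,
together with the study-population characteristics required to contextualise
them. Mining them at scale needs a filtering front end: most tables in the
literature are something else entirely (adverse events, in vitro assays, raw
concentration-time measurements), and passing them downstream wastes compute
and pollutes curated datasets. `pktables` implements that front end as a
three-class classifier over tables lifted from full-text JATS XML:
`PK`, `DEMOGRAPHICS`, `OTHER`.

The pipeline has four stages, each usable on its own:

1. **Extraction** (`parse_article_tables`): JATS `table-wrap` elements are
   parsed into structured records (caption, header rows, rectangular body,
   footer). Tables published only as images carry no cell content and are
   excluded.
2. **Serialization** (`select_field`): a table is rendered as text in one of
   seven field variants, from the caption alone to caption + full markdown
   table.
3. **Features and classifier** (`fit_vocabulary`, `bow_encode`,
   `train_boosted`): bag-of-words counts feed a class-weighted multiclass
   gradient-boosted tree ensemble.
4. **Hybrid routing** (`hybrid_classify`): predictions whose confidence
   falls below a threshold are double-checked by a zero-shot
   chain-of-thought language-model fallback behind a pluggable backend.

## The classifier

The model is a boosted ensemble $F(x) = \sum_{m=1}^{M} \gamma_m h_m(x)$ of
depth-limited regression trees, one tree per class per round, trained with a
softmax objective that minimises weighted cross-entropy. Trees are grown by
exact greedy search on second-order statistics: with per-sample gradient
$g_i$ and hessian $h_i$, a leaf takes the value $-\sum g_i / (\sum h_i +
\lambda)$ with $\lambda = 1$, and a split must improve the regularised gain
by more than `gamma` while leaving at least `min_child_weight` of hessian
mass in each child.

Because no gradient-boosting library is available in the target
environment, the tree learner is implemented inside the package (C++ via
Rcpp), following the conventions of the mainstream boosted-tree
implementations so the hyperparameter surface keeps its usual meaning:

| parameter | meaning | default / tuning range |
|---|---|---|
| `max_depth` | maximum tree depth | 2–10, step 2 |
| `min_child_weight` | minimum hessian mass per child | 1–6, step 2 |
| `gamma` | minimum loss reduction to split | 0.1–0.5, step 0.1 |
| `subsample` | row fraction per boosting round | 0.5–1.0, step 0.1 |
| `colsample_bytree` | feature fraction per tree | 0.3–1.0, step 0.1 |
| `learning_rate` | shrinkage | fixed 0.1 |

Boosting is capped at 1000 rounds and stops early after 10 rounds without
improvement of macro one-vs-rest AUC-ROC on a stratified 10% evaluation
split carved from the training data (the stopping metric is AUC; model
*selection* across the grid uses mean macro-F1 over 10 stratified CV folds,
matching how results are conventionally reported as mean (s.d.) tables).
All subsampling decisions are drawn from R's RNG in the driver and passed
to the C++ tree fitter as index vectors, so training is a pure function of
the seed.

Class imbalance (roughly 1 : 0.44 : 1.54 for PK : demographics : other in
the motivating corpus) is handled by inverse-frequency sample weights
$w_c = N/(K n_c)$, which conserve total sample mass: $\sum_c n_c w_c = N$.

### Numerical choices

- Grid values are generated by integer index scaling (`lo + i*step`,
  rounded), so 0.3–1.0 by 0.1 yields exactly 8 values despite floating-point
  division.
- Probability vectors use the fixed class order (PK, DEMOGRAPHICS, OTHER);
  argmax ties resolve to the first class in that order.
- Hessians are floored at 1e-16; split gains must beat the incumbent by
  1e-12 to avoid platform-dependent tie flips.
- The persisted model is a single JSON artifact (trees + vocabulary +
  serialization config + class order + format version) written at full
  precision, so save/load round-trips predictions bit-for-bit.

## Serialization decisions

The markdown dialect is GitHub-style pipes with a `---` separator row and
no alignment colons; any fixed dialect serves the purpose, and fixing one
makes outputs byte-stable for testing. A table without header rows emits
body rows only (no separator); the "first few rows" variant keeps the first
header row plus `k = 3` body rows by default — the smallest value that
distinguishes the variant from the bare header row. The "first column"
variant joins column-0 cells of the first header row and all body rows with
single spaces, dropping empties. Multi-row headers are preserved in the
record, but field selection uses the first header row only.

## Features

Bag-of-words tokenization lowercases and splits on runs of non-alphanumeric
characters, keeping digits — PK tables are number-dense and numeric tokens
carry signal. Vocabulary order is lexicographic in the C locale, making
index assignment deterministic. No TF-IDF, no n-grams: plain counts are the
point of the baseline, and they win on this task.

Long texts are handled by the chunk/pool machinery: the pluggable encoder
contract (`encoder_backend`) exposes the encoder's own tokenizer and its
input limit (512 tokens for the transformer encoders this mirrors); texts
are split into consecutive non-overlapping chunks, each encoded separately,
and chunk vectors are pooled elementwise by mean or max. The package ships
no pretrained weights — tests use a deterministic hash encoder — but any
published biomedical encoder can be wrapped to the contract. The zero-shot
fallback, by contrast, sends tables *unchunked*: the models it targets have
six-figure context windows.

## Hybrid routing

The supervised classifier answers by default; a prediction routes to the
fallback only when its confidence (the raw softmax maximum — no
calibration) is strictly below the threshold $T$, so confidence exactly
$T$ stays supervised. The fallback's parsed answer is adopted
unconditionally when it parses; an unparseable response degrades to the
supervised label. This makes the hybrid total, and gives it two provable
properties exercised in the tests: with a perfect fallback the hybrid never
has more errors than the supervised model, and with an adversarial fallback
never fewer — the router trusts whatever parses.

Threshold selection over the candidates {0.85, 0.9, 0.95} records, per
candidate, the routed fraction and the number of supervised errors captured
below it, then maximises captured errors subject to a routed-fraction cap
(default 10%, the operating regime the design targets). Tie-breaking was a
genuinely open corner: when several thresholds capture the same positive
number of errors at the same routed fraction, the smaller one is chosen
(the cheaper double-check achieving the same correction — a lower threshold
routes no more, and generally less, under distribution shift); when no
errors are capturable at all the trade-off data is uninformative and the
largest candidate is kept as the conservative default.

## The zero-shot prompt

The chain-of-thought prompt ships as an editable plain-text asset with
`{caption}`, `{table_markdown}` and `{footer}` slots — its wording is
configuration, not code. It distils the annotation-guideline content that
matters for the three-way decision: PK-parameter inclusion criteria, the
demographics definition, and the known edge cases (concentration-only
tables, PK parameters embedded in pharmacodynamic endpoints). Responses
must end with `ANSWER: <label>`; the parser takes the *last* such
directive case-insensitively and returns `UNPARSEABLE` rather than
throwing on anything else. Live backends are optional plugins behind the
`llm_backend` contract; every test uses deterministic mocks (scripted,
oracle, constant), so the suite runs offline and reproducibly.

## What the synthetic generator does and does not establish

`generate_corpus` emulates the *decision-relevant* features of the real
corpus: class-typical lexicons (parameter names and units for PK;
age/weight/sex/BMI for demographics), value ± SD cells, caption/footer
placement, class proportions matching the motivating corpus's training
split (532 : 233 : 819), an optional fraction of tables exceeding the
512-token chunk limit, and — deliberately — the hard negative that drove
annotator disagreement: concentration-time tables that share units with PK
tables but contain no parameter names. A lexical-noise dial swaps
class-typical tokens for cross-class ones; at noise 0 the classes are
lexically disjoint by construction and a keyword rule separates them
perfectly.

What it does not emulate: real tables' typographic variety, multi-level
spanned headers at realistic frequency, genuine pharmacological value
distributions, or the long-tail vocabulary of the literature. A green
end-to-end test therefore establishes that the machinery — extraction,
serialization, features, weighting, boosting, early stopping, routing — is
correct and deterministic, *not* that the headline corpus-scale F1 carries
over; reproducing that requires the external annotated corpus via the
`read_pktc_zenodo` adapter and is documented as a separate reproduction
exercise, outside CI.

Generator defaults were chosen once and are not tuned against test
outcomes: sample sizes in tests are the smallest that exercise the
contract, noise 0.2 for end-to-end runs (enough to make the task non-trivial
while staying in the separable regime the real caption+table features
occupy), and the long-table rate only where chunking is under test.

## Known limitations

- The tree learner is exact-greedy and dense; it is sized for corpora of
  thousands of tables with BoW vocabularies of tens of thousands of terms,
  not for millions of rows.
- The full 3600-candidate grid with 10-fold CV is expensive by design;
  `tune_boosted` is typically run on a reduced grid, and tests use toy
  grids.
- `HEADER_ROW` serialization emits the row without a separator line; the
  markdown "table-ness" of a single row is not meaningful to the
  classifier.
- Probability calibration is out of scope; the routing threshold operates
  on raw softmax maxima, and thresholds tuned on one corpus need
  re-selection after any retraining.
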