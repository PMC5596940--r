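---
title: "biodtm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biodtm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodtm)
```

This vignette is the package's own account of what it computes and why the
numerical and design choices were made. It states no empirical result that
the test suite does not itself compute.

## 1. The pipeline and its data model

`biodtm` turns a MEDLINE-format export (the PubMed "Send to: File,
Format: MEDLINE" dialect) into a fitted dynamic topic model in four
stages: parsing and slicing (`parse_medline()`, `assign_slices()`),
dictionary-restricted matrix construction (`build_dictionary()`,
`build_matrix()`), variational EM fitting (`fit_dtm()`), and analysis /
visualization (`top_words()`, `topic_strength()`, `river_layout()`,
`render_river_svg()`).

The central container is the `corpus_matrix`: an ordered vocabulary plus,
per time slice, a list of sparse documents `(word index, count)` with
0-based indices. On disk it is the three-file bag-of-words exchange
format (`-mult.dat` / `-seq.dat` / `-vocab.dat`): one document per line as
`"U idx1:cnt1 ... idxU:cntU"`, a sequence file with the slice count and
per-slice document counts, and the vocabulary in index order. Write
followed by read is an exact identity, which the suite asserts on
randomized matrices.

Records without an abstract are never admitted; skips and drops are
counted at every stage and surfaced in the CLI's drop report, so a corpus
shrinking from parse to fit is auditable rather than silent. The default
slice scheme (`default_slice_config()`) is the 16-range 1975–2017 layout
(four multi-year ranges covering 1975–2005 with roughly comparable
document counts, then one slice per year); it is data-driven rather than
principled, so every consumer accepts an arbitrary `slice_config()`.

## 2. Tokenization, stemming and the bio-dictionary

Tokenization lowercases and splits on every non-alphanumeric character
(hyphens and apostrophes are split points), then drops purely numeric
tokens, tokens shorter than 2 characters, and stop words. A standard
English stop-word list ships with the package in post-tokenization form
(contraction fragments as separate entries) and is overridable everywhere.

Stemming is the original Porter (1980) algorithm, implemented in the
package because no stemming library is available in the supported
dependency set. The implementation was cross-checked during development
against an independent reference on ~14,000 words; 92 verified
word–stem pairs are frozen in the test suite. Porter is the right choice
here because the stemmed surface forms it produces ("apoptosi", "memori",
"failur", "cognit") are exactly the ones that appear in biomedical
topic-model vocabularies.

The bio-dictionary is a whitelist of stems built from arbitrary term-list
files. Because the model is a bag of single words, multi-word terms
("heart attack") are split and contribute each unigram independently.
Single-character tokens are discarded (gene-symbol fragments add noise),
and the no-stop-word invariant is enforced again *after* stemming, since
stemming can itself land on a stop word. The four dictionary sources used
in the motivating analysis (a medical dictionary, a side-effect resource,
a biology dictionary, a gene-symbol table) are licensed and are not
bundled; any plain-text term lists plug in, and the synthetic generator
emits a matching dictionary file for offline testing.

## 3. Vocabulary filters

Two corpus-level filters prune the dictionary-restricted vocabulary, in a
fixed order:

1. **Total frequency**: words whose summed count over the whole corpus is
   below 2 are removed ("total frequency more than once").
2. **tf-idf**: each word scores `tf(w) * ln(D / df(w))` with `tf` its
   total corpus count, `df` its document frequency, and `D` the corpus
   size. The threshold is the first quartile (linear-interpolation
   quantile) of all scores; words are kept when their score is *strictly*
   greater, which implements "a bit more than the first quartile" without
   inventing a magnitude for the "bit". An explicit additive margin is
   available as a config knob (`tfidf_margin`, default 0).

Both `df`/`D` and the quantile threshold are computed once on the
dictionary-restricted, pre-filter matrix (single-pass semantics); the
filters differ under reordering, so the order is part of the contract.
A word occurring in every document has `idf = 0` and is always pruned by a
non-negative threshold — the filter's purpose is to drop both the rare
and the ubiquitous. For standalone use on hand-built matrices, a
vocabulary entry occurring in no document is given score 0 (the `tf -> 0`
limit). The whole filter stage is property-tested against a brute-force
oracle that recomputes survival by direct enumeration over a dense matrix.

## 4. The dynamic topic model and its inference

The generative model: document `d` in slice `t` draws
`theta_d ~ Dirichlet(alpha)` (symmetric, static over time); each token
draws topic `z ~ theta_d`, then word `w ~ phi_{z,t}` where
`phi_{k,t} = softmax(b_{k,t})` and the natural parameters follow a
Gaussian random walk `b_{k,t} ~ N(b_{k,t-1}, sigma^2 I)` with a broad
zero-mean prior (variance `sigma_0^2`) on the first slice.

Inference is variational EM:

* **E-step.** Exact LDA mean-field per document, with the document's
  slice-specific `phi` held fixed: responsibilities
  `r[n, k] ∝ phi[k, t, w_n] exp(digamma(gamma[k]))`, Dirichlet updates
  `gamma[k] = alpha + sum_n c_n r[n, k]`, iterated to tolerance.
  Each E-step after the first is **warm-started** from the previous
  iteration's `gamma`. This matters: coordinate ascent resumed from the
  incumbent can only improve the bound, whereas a cold start can land on a
  different (worse) per-document local optimum and visibly break EM
  monotonicity on small corpora. With warm starts the tracked objective
  is non-decreasing by construction, and the suite asserts it at relative
  slack 1e-6.
* **M-step.** Per topic, MAP over the whole chain `b_{k,1..T}` of the
  penalized objective `J_k` (word log-likelihood under softmax minus the
  two Gaussian penalties), using the analytic gradient
  `n_{k,t} - N_{k,t} phi_{k,t}` minus the chain-difference terms. The
  optimizer is L-BFGS-B, warm-started at the current chain. A first-order
  ascent with backtracking would be the textbook choice, but the
  stiff-chain regime (`sigma^2 -> 0`, penalty curvature `~ 1/sigma^2`)
  makes it impractically ill-conditioned; quasi-Newton handles both
  extremes, and the suite pins the behavior at the limits:
  `sigma^2 = 1e6` reproduces independent per-slice multinomial MLEs and
  `sigma^2 = 1e-8` the pooled distribution, each within total-variation
  1e-3 (observed < 1e-4).
* **Identifiability.** Softmax is shift-invariant, so the likelihood
  cannot pin a per-slice constant. Rather than centering *after*
  optimization (which changes the penalty terms and can decrease the
  objective), the M-step optimizes directly in the mean-centered
  subspace: the objective centers its argument per slice and the gradient
  is projected accordingly. Centering is then a no-op and monotonicity is
  preserved.
* **Tracked objective.** The variational bound splits cleanly: the word
  term `sum n log phi` lives in `J_k`, everything else
  (`theta` prior, `z` entropy, `q(theta)` terms) in the E-step's
  "non-word" objective. The reported trace is their sum evaluated after
  each M-step — a proper EM surrogate, monotone under the warm-start
  scheme.

Defaults: `K = 20` (the setting of the motivating 16-slice analysis),
`alpha = 0.1`, `sigma^2 = 0.005` (drift of a few percent TV per slice at
typical vocabulary sizes), `sigma_0^2 = 1`, at most 100 EM iterations,
relative convergence 1e-4. All are exposed in `fit_config()`, and every
stochastic choice (the seed-deterministic Gaussian init perturbations;
`K = 1` needs none) flows from the single integer seed.

Out of scope by design: the evolving document-mixture chain of the
original DTM formulation (the document side here is static LDA),
variational Kalman smoothing over the chains (the MAP M-step is a
compatible, simpler substitute), and correlated/author/continuous-time
topic variants.

## 5. Topic scores, tables and the river

The per-slice **topic strength** is defined as the token-weighted expected
topic share: `s[k, t]` is the expected number of slice-`t` tokens assigned
to topic `k`, over the slice's token count. Alternatives (document share,
posterior-mean mixing weight) are defensible; the token-weighted variant
was chosen because it makes the river mass-conserving — the stacked band
height is exactly the slice's (normalized) token mass. Whole-period topic
tables rank words by the unweighted mean of `phi[k, t]` over slices; the
per-slice tables use `phi[k, t]` directly. Ties break by ascending word
index, stated so the outputs are reproducible byte-for-byte.

The ThemeRiver layout stacks stream widths `s[k, t] * scale` in fixed
topic-id order, symmetric about a straight baseline (no wiggle
minimization — determinism and testability over aesthetics). Between
slice anchors each *width* is interpolated with monotone piecewise cubics
(Fritsch–Carlson, `splinefun(method = "monoH.FC")`); monotone interpolants
are bounded by their endpoint values on every interval, so interpolated
widths cannot undershoot zero, and stacking interpolated widths around a
recentered baseline guarantees gap-free, overlap-free tiling everywhere,
not just at anchors. Anchors are equally spaced by default because the
slicing intentionally equalizes document counts, not calendar spans; a
calendar-proportional axis is available via `anchor_x`. The SVG renderer
emits one closed path per topic (zero-strength topics included, as
zero-area paths), axis ticks, and a legend, with fixed-precision number
formatting so identical layouts produce byte-identical files.

## 6. The synthetic world

`synthetic_spec()` describes a corpus drawn from *exactly* the generative
process the model fits — that is its purpose and its main limitation.
Defaults emulate the shape of the motivating corpus: 20 topics, 16
slices, 400 documents per slice. Where the source analysis states no
value, realistic ones were fixed once: vocabulary 2000 stems and mean
length 120 tokens (a dictionary-restricted title + abstract), drift
`sd = 0.1` per coordinate, and an initial topic separation of `sd = 1` on
the natural parameters over a Zipf-like log-frequency base — topics whose
characteristic words sit roughly an order of magnitude above base rate,
as in fitted text models. Document lengths are Poisson (truncated at 1);
any positive law would do and Poisson is conventional.

Pseudo-words (`w0001`, ...) are chosen so Porter stemming is the identity
and lexicographic order equals index order; the emitted dictionary file
adds 20% never-used distractors. Emission writes the first five tokens as
the title and the remainder as the abstract — the pipeline tokenizes
title + abstract concatenated, so this split (rather than duplicating the
leading tokens) is what makes the round trip exact: MEDLINE emission
followed by parse → dictionary restriction → matrix construction with
filters off reproduces the generating matrix bit-for-bit, the suite's
integration test of the whole document side.

What a green synthetic test establishes: the inference machinery recovers
the truth of its own model class (matched mean TV ≈ 0.06 on the standard
recovery harness, against a 0.15 bound), conservation laws hold, and the
pipeline stages compose losslessly. What it does not establish: behavior
under model misspecification — real abstracts have burstiness, correlated
topics, vocabulary growth over calendar time, and non-Dirichlet mixing,
none of which the generator emulates.

## 7. Degenerate inputs, tolerances, determinism

* Documents emptied by dictionary restriction or filtering are dropped
  and counted; a slice left empty is an error naming the slice (a model
  over a gap in time is not meaningful).
* `K = 1` fits are supported and used as analytically forced test cases
  (unit responsibilities, strength ≡ 1).
* Probability-vector invariants are asserted at 1e-10; suff-stat
  conservation at 1e-8; EM monotonicity at 1e-6 relative (line-search
  round-off); the recovery bound at 0.15 matched mean TV.
* Determinism: identical seed + config implies bit-identical model
  parameters, manifests, CSVs and SVGs; the suite asserts byte-identical
  re-exports. Output manifests carry the package version, the full
  configuration, an FNV-1a hash of it, and the seed.

## 8. Known limitations

* The M-step is MAP over the chains, not a full variational treatment of
  the state-space posterior; uncertainty over `b` is not quantified.
* `alpha` is fixed, not learned, and the document-mixture prior does not
  evolve over time.
* The E-step stores per-document responsibilities for the analysis stage;
  at the scale of millions of tokens this is the memory bottleneck and
  would need streaming aggregation.
* The Porter stemmer passes non-alphabetic tokens through unchanged; gene
  symbols like `p38` are therefore never conflated, which is usually but
  not always the desired behavior.
* Dictionary quality bounds everything downstream: the package
  deliberately ships no biomedical lexicon, so the user's term lists
  define what "biomedical" means for a given run.
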