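---
title: "Ranking figures within an article: model, features and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking figures within an article: model, features and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figrank)
```

## The problem

Biology articles typically carry four to six figures, and the figures are
not equally important: some present the central finding, others are
supporting controls.  Given the full text of an article — title, abstract,
sectioned body and figure captions — `figrank` predicts an importance
ordering of the figures.  The supervision signal is a per-article gold
ranking with ties allowed: a list such as `(2, 1, 2)` says the second
figure is the most important and the other two are tied below it.  Gold
ranks are always normalized to *dense* numbering (1, 2, 2, 3 rather than
1, 2, 2, 4); dense numbering makes the reciprocal-rank ground-truth scores
used in training depend only on the rank-group index, and normalization is
order-preserving so no annotation information is lost.

## The listwise model

Each article contributes one *list* of figure feature vectors
$x_1, \dots, x_n$.  A linear scorer $f_w(x) = w^\top x$ produces scores
$z = (f_w(x_1), \dots, f_w(x_n))$, and training minimizes a cross-entropy
loss between two permutation-probability distributions: one induced by the
model scores $z$, one by the ground-truth scores
$y_j = 1 / r_j$ (reciprocal dense gold rank).

With the exponential potential, the probability that figure $j$ tops the
list is the softmax $P_1(j) = e^{z_j} / \sum_l e^{z_l}$.  The top-1 loss is
$-\sum_j P_1^{(y)}(j) \log P_1^{(z)}(j)$.  Because figure lists are short
(almost never more than nine figures), the distribution can affordably be
extended to ordered *pairs* of top figures.  Under the Plackett–Luce model
the probability that the ordered pair $(j, k)$ occupies the first two
positions is

$$P_2(j,k) \;=\; \frac{e^{z_j}}{\sum_l e^{z_l}} \cdot
  \frac{e^{z_k}}{\sum_l e^{z_l} - e^{z_j}}, \qquad j \ne k,$$

which sums to one over the $n(n-1)$ ordered pairs; the top-2 loss is the
cross entropy between the pair distributions of $y$ and $z$.  The top-2
loss sees more of the reference ordering than the top-1 loss and is the
package default (`loss = "top2"`).  Both losses have analytic gradients
(implemented in `loss_gradient()` and verified against central finite
differences in the test suite), and `top2_distribution()` is verified
against a brute-force enumeration of all $n!$ permutations for $n \le 6$.

Training (`figrank()`) is plain gradient descent with per-list updates in
fixed dataset order, weights initialized at zero (the model is linear, so
zero initialization is deterministic and seed-free).  Defaults follow the
configuration commonly used for this family of rankers: learning rate
0.0009 and 200 iterations.  An adaptive schedule multiplies the rate by
0.875 while it remains above $10^{-6}$ whenever the training metric
(mean ~WER-RK) improved or stayed equal in the pass.  Decaying on
*improvement* is unusual — most schedules decay on stagnation — but it is
the behavior this implementation standardizes on; `adapt = "on_worse"`
gives the conventional rule and `adapt = "none"` a constant rate.
Features are z-scored per column before training (`standardize = TRUE`)
because the raw feature mixture of cosines in $[0,1]$ and unbounded counts
cripples a single global learning rate; the scaling is stored in the model
and applied at prediction time.  Prediction sorts by descending score with
exact ties broken by figure position, so the output is always a strict
permutation.

Single-figure articles are trivially ranked; they are skipped during
training (the top-2 loss is undefined for $n = 1$, and the top-1 gradient
vanishes) but still scored at prediction time.

## Features

Each figure is represented by 57 named features in four categories, in a
fixed registry order (`feature_registry()`; lexicographic within category).
All similarities are cosines in one tf-idf space built over the whole
corpus collection (paragraphs, captions, titles and abstracts as indexing
units), with lowercasing, alphanumeric tokenization and a small function-word
stopword list.  The preprocessing spec reserves a stemmer switch, but only
the unstemmed path is implemented.  A zero vector (empty or
out-of-vocabulary text) has cosine 0 against everything, never `NaN`.

* **Centrality (15)** — cosine of the figure, represented as caption,
  associated context, and caption+context, against each of the four IMRAD
  section texts (12 values), plus caption+context against title, abstract
  and full text (3).  A figure's *associated context* is every body
  sentence that mentions it plus up to two sentences before and after each
  mention; windows clip at paragraph boundaries (so context never bleeds
  across sections) and overlapping windows merge, each sentence kept once.
  Mention detection understands "Figure 2", "Fig. 2", "Figs. 2 and 3" and
  ranges like "Figures 2–4" (interior labels included); panel references
  such as "2A" count as mentions of figure 2.  The abstract is not
  searched for mentions — context is a body-text notion.
* **Frequency (12)** — raw mention counts per IMRAD section (4); counts
  normalized by section token length (4); and counts weighted per
  paragraph by the paragraph's cosine with the title and with the abstract,
  for RESULTS and DISCUSSION (4).
* **Topic (26)** — an LDA topic model is fitted *per article*, treating
  each paragraph as a document (K = 10 topics by default, symmetric priors
  $\alpha = 1/K$, $\beta = 0.01$, 500 collapsed-Gibbs sweeps, seeded).
  Topics get two text representations: their top-20 words, and the
  concatenation of the paragraphs whose argmax topic they are.  Topics are
  ranked by cosine between their word representation and title+abstract,
  and the top 4 kept (fewer topics simply pad the missing features with
  zeros).  Features: figure (caption / context / caption+context) against
  each of the top-4 topics in both representations (24), plus the summed
  context similarity to the top-2 topics by *abstract-only* relevance, one
  per representation (2).
* **Structural (4)** — 1-based figure position; mean and population
  standard deviation of the caption+context cosine against every other
  figure (0 for single-figure articles); and the number of distinct
  sub-figure markers in the caption ("A.", "b:", "c," and "(A)" forms,
  letters a–f, counted once per letter).

Section headings map to IMRAD through a case-insensitive synonym table;
combined "Results and Discussion" headings resolve to RESULTS so shared
text is never double counted, and unknown headings fall into OTHER, which
contributes to the full-text representation but not to per-section
features.

The 57-feature inventory is this package's own enumeration; published
feature sets for this task quote larger totals without itemizing their
composition, so the registry (dumpable as YAML) documents exactly what is
computed rather than forcing a particular count.

## Evaluation metrics

All metrics compare a strict system permutation $s$ with a dense,
possibly tied reference $r$, and are reported in "higher is better" form.

**~WER-RK** (rank-weighted pair error).  The error is the weighted
fraction of discordant pairs,
$$\mathrm{WER\text{-}RK} = \frac{\sum_{j<k} I[(s_j-s_k)(r_j-r_k)<0]\,
  (1/r_j + 1/r_k)}{\sum_{j<k} (1/r_j + 1/r_k)},$$
so mistakes on pairs containing important figures cost more.
Reference-tied pairs express no preference: they can never be error pairs,
but they stay in the normalizing total.  Two consequences are worth
spelling out.  First, for any *strict* reference the expected ~WER-RK of a
uniformly random permutation is exactly $1/2$ for every list length — a
symmetry argument shows this for *any* fixed pair weighting, since each
pair is discordant in exactly half of all permutations.  Second, with ties
present the random expectation rises above $1/2$ by half the tie-pair
fraction ($E[\sim\!WER\text{-}RK] = 1 - (1-\tau)/2$ for tie-pair share
$\tau$), and since longer figure lists are empirically more tie-prone,
random baselines drift upward with list length.  Reports of
random-baseline values above 0.5 for this metric family are therefore a
signature of tied references, not of the metric rewarding chance.

**NDCG.**  Gain of reference rank $r$ is $2^{-(r-1)}$ (halving per rank
step, the learning-to-rank convention), discounted by $1/\log_2(k+1)$ at
system position $k$ and normalized by the ideal ordering's DCG, so a
perfect ordering scores exactly 1 under any tie structure.  The
exponential gain was chosen over reciprocal-rank gain because its random-
permutation mean at realistic list lengths (about 0.71–0.75 at 5–6
figures) matches the random baselines reported for this task, while
reciprocal gain sits visibly higher.

**~WER-FR** (first-rank error).  $\mathrm{WER\text{-}FR} =
(s(x_1) - 1)/(m - 1)$, the displacement of the human-top figure scaled by
the worst case.  With a tied top group the best (minimum) system rank in
the group is used: placing *any* most-important figure first is a perfect
outcome.

`random_expectation()` computes the mean of any metric over random
permutations, exactly (full enumeration, capped at $m \le 9$ where $9!$
is still affordable) or sampled (default 100 repeats, matching the
conventional random-baseline protocol).  `tie_pair_percentage()` reports
the tie share of a reference; the worked three-figure example
"figure 2 first, figures 1 and 3 tied second" gives ranks $(2,1,2)$ and a
tie-pair share of $1/3$.

## Feature selection

`fgfs()` implements forward greedy selection: start from the empty set;
each iteration appends every unselected feature in turn, scores the
candidate set, and keeps the best (ties resolved toward the lower registry
index, for reproducibility).  The candidate score is the article-mean
metric under seeded k-fold cross-validated training (5 folds by default;
the protocol is injectable).  Selection stops after 10 iterations without
improvement, or at `max_features`; the result records the full selection
path, the per-iteration best scores, the optimum and its iteration, and an
optional audit log (TSV of every candidate evaluation) from which the
selection performance curve can be plotted.  `select_top_individual()`
provides the naive comparison — rank features by their solo score and pool
the top k — and `combine_fgfs_sets()` unions selections from runs driven
by different metrics.

## Synthetic data

Two generators make the pipeline testable without a private annotated
corpus; their defaults are the package's study conditions and are not
tuned per experiment.

`generate_ranking_dataset()` draws i.i.d. standard-normal features,
scores them with a planted weight vector $w^*$, adds optional Gaussian
noise, and dense-ranks the true scores (optionally collapsing adjacent
ranks into ties with a given probability).  Figure counts default to 2–6
per list.

`generate_article()` builds whole articles from pseudo-word pools (one
shared background pool plus per-topic pools, the simplest vocabulary model
that gives both tf-idf and LDA real co-occurrence structure to find).
Importance is planted three ways at once: more important figures receive
more mention sentences in RESULTS and DISCUSSION, captions borrowing more
title/abstract vocabulary, and more sub-figure markers — so centrality,
frequency and structural features all correlate with the gold ranking by
construction.  Figure counts follow a 2–9 distribution peaked at 4–6,
mirroring the empirical shape of experimental-biology articles.  What the
generator does *not* emulate: real journal prose, realistic sentence
grammar, vocabulary burstiness, figure-free sections, or annotator noise
in the gold rankings.  Passing end-to-end tests therefore demonstrates
that the pipeline recovers a planted text-structure signal, not that any
particular accuracy will transfer to real articles.

## Numerical and design notes

* Zero-vector cosines are defined as 0; all similarity features lie in
  $[0,1]$ and the two cumulative topic features in $[0,2]$.
* `top2_distribution()` guards the $S - e^{z_j}$ term with the smallest
  positive double so extreme score gaps cannot produce `-Inf` logs.
* Exhaustive permutation enumeration is capped at $m = 9$; beyond that the
  sampled mode is mandatory.
* LDA fitting is restartable bit-for-bit from its seed; changing the seed
  changes feature values but never the registry shape.
* The divergence guard aborts training with diagnostics if the loss goes
  non-finite (e.g. under an absurd learning rate).

Problem sizes used by the shipped test and benchmark suites were chosen
once as the package's own desk-scale conditions: gradient checks on 100
random instances ($n \le 6$, $d \le 10$); distribution checks against
$n!$ enumeration for $n \le 6$; a 200-list recovery study; a 100-article
simulated corpus (6 topics, 150 Gibbs sweeps) for the end-to-end baseline
comparison; and a 30-list, 20-feature selection benchmark over 10 seeds
with 3-fold inner cross-validation and a short fixed-rate trainer.

## Known limitations

* **Ordering recovery is bounded away from perfection on rank-supervised
  synthetic data.**  The cross-entropy target uses reciprocal-rank scores,
  which a linear scorer cannot reproduce in magnitude; with 200 lists and
  10 features the exact loss minimizer recovers the planted direction only
  to a cosine of about 0.99, and per-list exact ordering (Kendall
  $\tau = 1$) plateaus near 80% of lists across optimization regimes.
  Exact per-list recovery at such sample sizes would require supervision
  by the underlying scores rather than their ranks.  The test suite states
  the stronger 95% recovery expectation and documents its failure rather
  than weakening the check.
* The strict-reference random expectation of ~WER-RK is exactly 0.5 at
  every list length (the symmetry argument above); only tied references
  raise it.
* The JATS reader targets a minimal dialect (front/article-meta, body/sec,
  fig/caption); heavily nested or non-conforming XML should be converted
  to the JSON schema instead.
* No stemming, no lemmatization, no sub-word handling; mention detection
  is regex-based and will miss prose like "the previous figure".
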