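---
title: "Active and semi-supervised SVM classification of protein-interaction sentences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active and semi-supervised SVM classification of protein-interaction sentences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppispotter)
```

## The problem and the model

Sentence-level protein–protein-interaction (PPI) detection asks, for
each sentence of a biomedical abstract, whether it asserts an
interaction between two proteins. Expert labels are scarce and
expensive; unlabeled sentences are plentiful. `ppispotter` combines two
complementary ways of using the unlabeled pool:

* **Active learning (breaking ties).** A calibrated linear SVM assigns
  each pool sentence a positive-class probability $p$; the *tie score*
  $|2p-1|$ is the gap between the two class probabilities. The budgeted
  set of smallest-gap (most ambiguous) sentences is sent to the human
  oracle, whose labels join the training set.
* **Semi-supervised learning (deterministic annealing).** The unknown
  labels of the remaining pool are relaxed to Bernoulli soft labels
  $p_j \in [0,1]$ and the annealed transductive objective (free energy)

  $$F(w,b,p;T) = \tfrac12\lVert w\rVert^2
    + C\sum_{i \in L} H_1(y_i f_i)
    + C^{*}\sum_{j \in U}\bigl[p_j H_1(f_j) + (1-p_j) H_1(-f_j)\bigr]
    - T \sum_{j \in U} S(p_j)$$

  is minimized while the temperature $T$ decreases. Here
  $H_1(t)=\max(0,1-t)$ is the hinge loss, $f_i = w\cdot x_i + b$, and
  $S(p)$ is the Bernoulli entropy with $0\log 0 = 0$. At high $T$ the
  entropy dominates and the problem is nearly convex with $p\approx
  \tfrac12$; as $T \to 0$ the soft labels harden and $F$ approaches the
  hard-label transductive SVM objective. Each temperature is
  warm-started at the previous solution (a homotopy); there is no
  global-optimality guarantee, and the package's tests assert descent
  and recovery, never optimality.

The combined driver (`run_btda()`) runs break-tie rounds first, then
hands the *high-confidence* machine-labeled instances to the annealer
as initial soft labels instead of discarding them — the calibrated
probability of each confidently classified sentence seeds its $p_j$,
while genuinely ambiguous sentences start at $0.5$.

## Block updates and their exactness

At fixed $T$ the free energy is minimized by exact alternation:

* **$(w,b)$ step** (`weighted_train()`): for fixed $p$, $F$ equals (up
  to the constant $-T\sum S(p_j)$) a weighted SVM objective in which
  each unlabeled point appears twice, with label $+1$ and weight
  $C^{*}p_j$ and label $-1$ and weight $C^{*}(1-p_j)$. The solver
  (`train_linear_svm()`) is a dual SMO with maximal-violating-pair
  selection, iterated until the *relative duality gap* is at most
  $10^{-6}$, with the bias recovered by exact one-dimensional
  minimization of the piecewise-linear primal (flat stretches resolve
  to their midpoint for determinism). Two guarantees matter for the
  annealer: the solver never returns a worse primal than its warm
  start, and `anneal()` additionally accepts the $(w,b)$ update only if
  it does not increase $F$ — so free-energy descent across block
  updates holds exactly, not merely up to solver tolerance.
* **$p$ step** (`update_soft_labels()`): for fixed $(w,b)$ the
  minimizer is closed-form, $p_j = 1/(1+\exp(g_j/T))$ with
  $g_j = C^{*}(H_1(f_j) - H_1(-f_j))$. With a class-balance target $r$,
  a common offset $\nu$ is found by bisection so that the mean of $p$
  equals $r$ to within $10^{-9}$.

The inner loop stops when the symmetrized Kullback–Leibler divergence
between consecutive soft-label vectors falls below `inner_tol`. This is
the package's concrete reading of a "consecutive-iteration similarity"
stopping rule: it is zero iff the vectors agree and grows smoothly with
their disagreement. The outer loop stops when the total entropy
$\sum_j S(p_j)$ drops below `entropy_tol` or the temperature floor is
reached. Because free energies at different temperatures contain
different $-T\,S$ terms, they are not mutually comparable; the state
returned as "best" is therefore the one minimizing the entropy-free
transductive objective (the $T\to 0$ limit of $F$), evaluated at the
end of each temperature. The fully annealed soft labels are also
returned (`p_final`), and the whole trajectory is logged in a trace
table (one row per block update: temperature, free energy, entropy,
KL to the previous $p$).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `C` | 1 | penalty on labeled hinge losses |
| `Cstar` | 1 | penalty per unlabeled expected hinge (see scaling below) |
| `T0`, `R`, `T_min` | 10, 1.5, 1e-4 | geometric annealing schedule $T_0 > T_0/R > \dots \ge T_{\min}$ |
| `inner_tol`, `inner_max` | 1e-6, 50 | inner-loop stopping (sym-KL threshold, iteration cap) |
| `entropy_tol` | 1e-6·\|U\| | outer stopping threshold on total entropy |
| `theta` | 0.9 | confidence threshold for the fuzzy / high-confidence split |
| `budget`, `rounds` | 20, 1 | oracle queries per active-learning round, and rounds |
| `window` | 5 | negation scope window (in NegEx-style terms, see below) |
| `hash_dim` | 64 | hash buckets for interactor-name encoding |

**Scaling of the unlabeled penalty.** The free energy sums the
unlabeled loss over all of $U$, so with a fixed per-point $C^{*}$ the
aggregate unlabeled force grows linearly with the pool while the
labeled force does not. Any slight class asymmetry in the soft labels
then exerts a net pull of order $(2\bar p - 1)\,C^{*}|U|$ that the
labeled term cannot counter, and the annealer degenerates into labeling
the whole pool with one class. The driver therefore multiplies
$C^{*}$ by $|L|/|U|$ by default (`cstar_scale = "labeled_ratio"`),
which equalizes the total labeled and unlabeled influence — the same
per-point normalization used in annealed transductive SVM formulations
that divide the unlabeled loss by $|U|$. `anneal()` itself applies no
scaling, so its objective is exactly the formula above.

**Class balance.** The balance constraint (mean of $p$ pinned to a
target $r$) is implemented but off by default. In the combined
algorithm the oracle-labeled sample is gathered near the decision
boundary, so the labeled class ratio is a biased estimator of $r$; in
pilot runs on the overlapping-clusters fixture a misestimated $r$
*caused* the degenerate fixed point ($w\to 0$, all $p\to r$) more often
than it prevented one. Instead, the driver detects the degenerate
outcome — every unlabeled point rounded to one class — and falls back
to the break-tie model with a warning. On the overlapping fixture this
triggers in roughly 3 of 20 seeds.

## The sentence representation

Nine features per sentence, computed by `extract_features()`:

1. **Negation status.** A NegEx-style detector with pre-, post- and
   pseudo-negation phrase lists. *Findings* are protein mentions and
   interactor terms. A finding is negated when a pre-phrase precedes it
   (or a post-phrase follows it) within a window of 5 units, where the
   counting is NegEx-fashion in *terms* rather than raw tokens:
   punctuation and the coordinators ",", ";", "and", "or" are
   transparent, and each complete coordinated segment between trigger
   and finding counts as one unit, the way a multi-word concept counts
   as one token in the original rule set. A leading "No" therefore
   reaches across an enumerated list of findings ("No relevant changes
   in heart rate, body weight, and plasma levels of renin activity …"
   negates *renin*), while five plain intervening words exhaust the
   window. Pseudo-phrases ("no increase …") are matched first and block
   triggers nested inside them. The boolean feature collapses any
   negated finding to `TRUE`; per-finding spans are also returned.
2. **Protein occurrences.** Greedy longest-match gazetteer lookup
   (case-insensitive, non-overlapping); gold mention spans, when a
   corpus provides them, bypass the gazetteer.
3–5. **Interactor name, POS, position.** Tokens are conservatively
   stemmed — plural/-ed/-ing stripping with doubling and e-restoration
   candidates, never below three characters, looked up against the
   interactor lexicon so the part-of-speech is preserved (an aggressive
   stemmer would conflate nominal and verbal uses). Among multiple
   matches the first one between the outermost protein mentions wins,
   then the first anywhere. The position is the 0-based character
   offset (configurable in spirit: the token index is also returned).
6–8. **Positional counts.** Tokens strictly between the outermost
   mentions, strictly before the first, strictly after the last; the
   sentinel −1 marks every undefined case (fewer than two mentions, a
   mention at the sentence edge).
9. **Link path.** Whether a grammatical connection chain exists between
   the two outermost mentions. The built-in provider is a documented
   heuristic stand-in for a link parser: `TRUE` iff an interactor term
   occurs between the mentions with no sentence-boundary punctuation
   intervening. The provider is pluggable so a real parser can be
   substituted.

Encoding (`fit_encoder()`/`encode_features()`): booleans to 0/1 with
missingness indicators; counts z-scored using statistics of the
*defined* training values only, sentinels routed to dedicated indicator
columns; interactor names feature-hashed to 64 one-hot buckets
(deterministic polynomial hash); POS one-hot over a closed tag set with
unknown tags mapped to `OTHER`. Standardization constants always come
from the training rows, so no test-set statistics leak.

## Synthetic data: what it emulates and what it does not

`make_clusters()` realizes the cluster assumption literally: isotropic
Gaussian clusters per class, stratified labeled/unlabeled/test splits,
gold labels retained for the pool. Two named regimes recur in the
tests: a *separated* fixture (centers $(\pm 2, 0)$, $\sigma = 0.5$, one
labeled point per class, 100 unlabeled — semi-supervision is easy and
supervision from two points is brittle) and an *overlapping* fixture
(centers $(\pm 1, 0)$, $\sigma = 0.8$, 4 labeled, 200 unlabeled —
methods separate by quality). `make_sentences()` fills templated
English sentences with gazetteer proteins and inflected interactor
verbs: positives place an interactor between two proteins; negatives
lack one or negate it with a pre-negation phrase; gold labels and
mention spans follow from the template, and 40% of sentences are
positive by default.

These generators exercise every code path, but templated sentences are
linearly separable in the encoded features and contain no lexical
ambiguity, anaphora or parse errors, and Gaussian clusters match the
SSL assumption exactly. Passing tests therefore demonstrate
correctness of the machinery and the *relative* behavior of the
methods under the cluster assumption — not performance on real
corpora, whose class ratios, feature noise and non-separability are
deliberately out of scope.

## Evaluation protocol

Positive-class precision, recall and F1 (zero denominators report 0
with a warning) and rank-based AUC with ties counted one half.
`kfold_cv()` uses *stratified* seeded folds — PPI corpora are class
imbalanced, and unstratified small folds can lose a class entirely —
and within each training portion draws a small stratified labeled set
(default 50), the remainder forming the unlabeled pool; the aggregate
is the unweighted fold mean. `learning_curve()` evaluates
transductively: the labeled set is sampled randomly, all remaining
points are the evaluation pool, and oracle-queried points are excluded
from the method that consumed them; results are averaged over seeded
repetitions. The acceptance script runs 20-dataset QP-oracle
comparisons, 20-seed recovery and ordering studies and a 500-sentence
10-fold cross-validation — sizes chosen so the whole battery completes
in minutes on one CPU while keeping the Monte-Carlo noise on mean F1
comparisons near one percentage point.

## Numerical choices and degenerate inputs

* SMO stops on a certified relative duality gap ($10^{-6}$); the pair
  update regularizes a vanishing curvature at $10^{-12}$; warm starts
  are clipped to the new box and re-projected onto the equality
  constraint by shrinking the over-weighted side.
* The calibration slope is constrained to $[-50, -10^{-6}]$: the lower
  cap keeps perfectly separated data from driving probabilities to
  exact 0/1, the upper cap fixes the orientation (higher score, higher
  positive probability). The intercept is identically zero so boundary
  points score exactly 0.5.
* Ties: query selection breaks tie-score ties by ascending pool index;
  `round_labels()` sends $p = 0.5$ to $+1$; the bias plateau takes its
  midpoint.
* $T \le 0$ in the soft-label update is an error (use `round_labels()`
  at the zero-temperature limit); negative temperatures are rejected in
  the free energy; empty unlabeled sets reduce every pathway exactly to
  the supervised model.
* K-means clusters with tied or absent labeled members fall back to
  the label of the nearest labeled point by centroid distance; if the
  resulting pseudo-labels collapse the SVM to $w = 0$, calibration is
  reported unavailable rather than fabricated.

## Known limitations

* The link-path heuristic is a stand-in; a real grammatical parser
  would change feature 9 on real text.
* The negation detector collapses "possible" negation into
  not-negated for the boolean feature, as a binary feature requires.
* The annealer can still converge to a degenerate labeling on hard
  pools (detected and logged, with the break-tie fallback); no global
  optimality is claimed.
* Whether the random-sampling and clustering baselines should also
  feed a DA stage is genuinely ambiguous; the package defaults to "no"
  (they are baselines for the *querying* strategy) and exposes
  `post_da = TRUE` for the other reading.
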