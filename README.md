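# ppispotter

Classifying sentences from the biomedical literature by whether they
assert a protein–protein interaction (PPI) is a bottleneck for pathway
databases and curation pipelines: expert labels are expensive, while
unlabeled sentences are abundant. `ppispotter` implements a combined
strategy for this setting — pool-based **active learning** by breaking
ties, feeding into a **deterministic-annealing semi-supervised SVM**
(BTDA-SVM) — together with the nine-feature lexico-syntactic sentence
representation it classifies, four comparison baselines, synthetic data
generators, and an evaluation harness. It is aimed at text-mining and
machine-learning practitioners who want a transparent, fully
reproducible reference implementation of the combined algorithm.

## The method

**Sentence representation.** Each sentence is mapped to nine features:
negation status from a NegEx-style detector (pre-, post- and
pseudo-negation phrase lists, bounded scope window), the number of
protein mentions from longest-match gazetteer lookup, the interactor
term (a trigger word such as *bind* or *inhibit*, matched after
conservative suffix-stripping) with its part-of-speech and character
position, three positional counts relative to the outermost protein
mentions (−1 when undefined), and a link-path indicator between the two
outermost mentions (a pluggable provider; the built-in heuristic stands
in for a grammatical link parser). Features are encoded numerically
with train-set-only standardization, sentinel indicators and a hashed
one-hot for interactor names.

**Classifier.** A weighted linear soft-margin SVM minimizing

    0.5 ||w||^2 + C * sum_i s_i * max(0, 1 - y_i (w·x_i + b)),

solved in the dual by SMO to a certified relative duality gap ≤ 1e-6.
Decision values are margin-normalized, f̂(x) = (w·x + b)/||w||, and
calibrated through a one-parameter sigmoid P(+1|x) = 1/(1 + exp(A·f̂))
with A < 0 fitted by regularized maximum likelihood and the intercept
fixed so boundary points get probability exactly 0.5.

**Active learning (breaking ties).** The binary tie score
|P(+1) − P(−1)| = |2p − 1| ranks the unlabeled pool; the budgeted
smallest-gap instances are sent to the oracle each round.

**Semi-supervised stage (deterministic annealing).** Unlabeled labels
are relaxed to Bernoulli soft labels `p` and the free energy

    F = 0.5||w||^2 + C Σ_L H1(y_i f_i)
        + C* Σ_U [ p_j H1(f_j) + (1−p_j) H1(−f_j) ]  −  T Σ_U S(p_j)

is minimized by exact alternating block updates (a weighted SVM solve
in (w, b); a closed-form logistic update in p) while the temperature T
is lowered geometrically from an entropy-dominated start to a hard
labeling. The combined BTDA driver exploits the supervised stage's
high-confidence calibrated probabilities as the initial soft labels.

Baselines: supervised SVM, random-sampling labeling (RS-SVM),
k-means cluster-then-label (C-SVM), and break-tie active learning
alone (BT-SVM).

## Worked example

```r
library(ppispotter)
lex <- default_lexicons()

# the nine-feature record for one sentence
s <- sentence("ex1", "We found that GerE directly binds ykuD in vitro .")
extract_features(s, lex)
#>   is_negated n_proteins interactor_name interactor_pos interactor_position
#> 1      FALSE          2            bind             VB                  28
#>   n_words_between n_left_words n_right_words link_path
#> 1               2            3             3      TRUE

# synthetic corpus -> features -> 10-fold CV of the combined method
corp <- make_sentences(sentence_spec(n_sentences = 300, seed = 42), lex)
fr   <- extract_features_corpus(corp, lex)
X    <- vectorize(fr)$matrix
y    <- attr(fr, "label")
kfold_cv(X, y, run_config("btda", budget = 10, seed = 42),
         n_folds = 10, n_labeled = 40, seed = 42)
#> <ppi_eval_report> btda | 10-fold | P = 1.000  R = 1.000  F1 = 1.000  AUC = 1.000

# semi-supervised recovery: 2 labels + 100 unlabeled points
d  <- make_clusters(cluster_spec(seed = 7))
st <- anneal(d$labeled$X, d$labeled$y, d$unlabeled$X)
st
#> <ppi_da_state> |U| = 100 | T = 0.1156 | free energy = 0.441686 | entropy = 3.034e-06
mean(st$labels == d$unlabeled$y)
#> [1] 1
```

The feature record shows two gazetteer mentions (`GerE`, `ykuD`), the
stemmed interactor *bind* (a verb at character offset 28), two tokens
between the mentions, and a link path. The cross-validation report is
the fold-mean positive-class precision/recall/F1 and AUC; the templated
corpus is linearly separable in the encoded features, so all methods
except cluster-then-label reach the ceiling. The annealer labels all
100 unlabeled points by their generating cluster from just two labeled
examples.

A command-line front end wrapping these functions (subcommands
`simulate`, `featurize`, `train`, `evaluate`, `curve`) is installed at
`inst/cli/ppispotter.R`.

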