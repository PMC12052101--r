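# synnorm

Frequency-guided synonym normalization for biomedical text corpora, with an
embedding-coherence evaluation framework.

## The problem

Biomedical NLP pipelines routinely collapse synonymous *biomedical* terms
("Myocardial Infarction", "Heart Attack") into a single concept-identifier
token before training word embeddings, which sharpens the resulting concept
vectors. The *non-biomedical* vocabulary surrounding those concepts gets no
such treatment: the same general notion is scattered across lexical variants
("amount", "quantity", "measure"), so related biomedical concepts that share
a meaning-level context do not share a token-level context. That lexical
variability dilutes the contexts a skip-gram model learns from and loosens
the clustering of related concept embeddings.

`synnorm` implements a simple corpus-normalization heuristic for this:

* compute the corpus frequency `f(w)` of every token; let `μ` be the mean of
  `f(w)` over distinct tokens (per-type mean);
* words with `f(w) < τ` (default `τ = μ`) are replacement candidates `R` —
  frequent words are assumed important and left alone;
* for each candidate `w`, look up its synonym pool `S_w` (union of the
  word's synonym sets across senses, e.g. from WordNet) and find
  `smax = argmax_{s ∈ S_w} f(s)`, the most frequent synonym *in this
  corpus*;
* if `f(smax) ≥ τ`, every occurrence of `w` is replaced by `smax`; if all
  synonyms are infrequent too, `w` is presumed to carry specific,
  discriminating meaning and is retained. Concept-identifier tokens are
  protected and never replaced.

Because sources are strictly below τ and targets at or above it, the mapping
can never chain, and applying a plan is idempotent.

The package also ships the evaluation framework used to judge whether the
normalization helps: seeded single-threaded skip-gram (negative sampling)
embedding training, GMT concept-set loading and filtering (sets need ≥ 5
members embedded in both spaces), mean intra-set pairwise cosine distance
(`1 − cos`, smaller = more coherent), per-set paired t-tests between two
embedding spaces, per-category win/loss summaries, and ECDF / Q-Q /
Kolmogorov–Smirnov diagnostics of the global distance distribution. A
synthetic corpus generator with known synonym classes, topic-linked concept
sets, and concept-linked lexical preferences makes the whole pipeline
testable end to end without any download.

## Worked example

The classic illustration: a corpus where "measure" (10 occurrences) and
"13" (8) dominate their synonym pools, while "amount", "bill", "step",
"thirteen" and "xiii" are rare. The per-type mean frequency is
`μ = 34/9 ≈ 3.78`.

```r
library(synnorm)

co <- corpus(list(rep(
  c("measure", "13", "cid_d001", "assay", "bill", "thirteen",
    "amount", "step", "xiii"),
  times = c(10, 8, 5, 4, 2, 2, 1, 1, 1)
)))
freq <- count_frequencies(co)
res  <- synonym_resource(fixture_synonym_path())
plan <- build_replacement_plan(freq, res, tau = default_threshold(freq))
tidy(plan)
#> # A tibble: 5 × 4
#>   source   target  f_source f_target
#>   <chr>    <chr>      <int>    <int>
#> 1 amount   measure        1       10
#> 2 bill     measure        2       10
#> 3 step     measure        1       10
#> 4 thirteen 13             2        8
#> 5 xiii     13             1        8
```

The three rare variants of "measure" collapse onto it and the numeral
variants collapse onto "13"; the concept identifier `cid_d001` is protected
and "assay" (frequency 4 ≥ τ) is left alone. `apply_replacement(co, plan)`
rewrites the corpus one-for-one, preserving document count and length.

The full experiment on the default synthetic collection (10 topics × 200
documents, 100k tokens):

```r
ex <- run_experiment(synth_config(seed = 1))
glance(ex)
#>   n_sets norm_better_all orig_better_all norm_better_sig mean_dist_change_pct
#> 1     10               8               2               2                -4.45
```

Normalization tightened 8 of the 10 concept sets and reduced the mean
intra-set cosine distance by 4.5% on average, while the global
pairwise-distance distribution moved only slightly (KS ≈ 0.06; see
`autoplot(ex$diagnostic)`).

A command-line front end over the same functions lives at
`inst/cli/synnorm.R` (`replace`, `evaluate`, `simulate` subcommands).

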