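---
title: "Mapping target–disease literature evidence onto biological levels of study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping target–disease literature evidence onto biological levels of study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litlevels)
```

## The problem

Platforms that aggregate literature support for target–disease associations
attach to each association a set of *evidence fragments*: sentences from
publications that mention both the target and the disease. What these records
do not say is the biological **level of study** — whether the association was
established by looking at DNA or RNA (genotyping, sequencing, expression),
at the protein itself (immunoassays, Western blots, proteomics), or at a
related metabolite (metabolomics, lipidomics). That distinction matters for
target triage: genomic evidence is plentiful but indirect, while
protein- and metabolite-level evidence speaks more directly to a druggable
mechanism.

`litlevels` implements a triage pipeline that recovers this missing
dimension at corpus scale:

1. **Candidate selection** — keep only fragments whose (target gene, PubMed
   ID) pair is backed by a high-quality protein annotation record.
2. **Dictionary screening** — assign fragments to the DNA/RNA, protein and
   metabolite categories by method-term matching.
3. **Review-sample selection** — pick a small, maximally diverse subset per
   category for manual review.
4. **Manual review** — a three-question protocol validating or invalidating
   each screened fragment.
5. **Automated review** — per-category naive Bayes classifiers trained on
   the review labels and applied to the whole screened corpus.
6. **Reporting** — raw and dictionary-size-adjusted counts, review
   summaries, confirmed/unrelated partitions.

The numbered scripts under `analysis/` run these stages in order on a
synthetic corpus; every computation they perform lives in the package and is
unit-tested.

## Candidate selection

Annotation records (`read_annotations()`) carry a protein accession, its
Ensembl gene mapping, an annotation hierarchy group, quality grades for both
the annotation and its evidence, the evidence type and descriptor (ECO
term), and a PubMed ID. `filter_annotations()` emits a (gene, PMID) pair
only when **all ten** selection criteria hold: protein-level existence; an
allowed hierarchy group (`general-annotation` and its generic-function,
generic-interaction and medical subgroups); GOLD annotation quality; no
membership in the cautionary categories (caution, domain-info,
sequence-caution, variant-info); no negative evidence; GOLD evidence
quality; evidence type "publication"; one of four allowed experimental ECO
descriptors; a present PubMed ID; and a one-to-one gene mapping. Records
with zero or multiple Ensembl genes are excluded, never expanded — a
many-to-one mapping would let one protein's annotation vouch for fragments
about a different gene. Per-criterion exclusion tallies are attached to the
result so a corpus audit can see *why* records fell out.

Deduplication (`deduplicate_fragments()`) keys on the case-folded,
whitespace-collapsed text together with the target gene and disease IDs.
This is deliberately the narrowest key that removes re-ingested copies of
the same sentence: the same text mentioning two different targets encodes
two distinct claims and both are kept.

## Dictionary screening

The packaged dictionary (`default_dictionary()`) maps method terms from the
IUPAC bioanalytical-chemistry terminology groupings onto the three
categories (Enzymatic/Immunoanalytical/Proteomics → protein; Genomics and
Nucleic Acid Analysis → DNA/RNA; Metabolomics/Glycomics/Lipidomics →
metabolite). Matching is case-insensitive and, by default, allows a term to
occur inside a longer word — "mutation" should hit "mutations",
"intron" should hit "intronic". A small set of short terms would be
useless under that rule ("ria" occurs inside "criteria", "gag" inside
"engagement"), so they are flagged `whole_word_only` and match only between
word boundaries; a word character is a letter, digit or underscore, and the
boundary test runs on the case-folded text. Short nucleic-acid tokens
("dna", "rna", "mrna", "cdna", "sirna", "snp", "gwas", "elisa") get the same
flag for the same reason.

Membership is multi-label: a fragment mentioning both a Western blot and a
PCR legitimately belongs to two categories, and per-category counts are
independent. Match spans are recorded as 0-based half-open character
offsets, which drive the review-form highlighting: entity names in square
brackets, matched terms in curly brackets —

```{r}
text <- paste0("Using IP with an anti-acetyl lysine antibody, we identified ",
               "Aurora B as an acetylated protein in PC3 prostate cancer cells.")
hits <- screen_fragment(list(fragment_id = "ex", text = text),
                        default_dictionary())
highlight_fragment(text, hits, "Aurora B")
```

Overlapping term spans are merged left-greedily, a term span overlapping an
entity occurrence yields to the entity, and stripping the bracket characters
recovers the original text (guaranteed for texts that contain no brackets of
their own).

Because the adjusted counts in reports divide each raw count by its
category's dictionary size, the dictionary object carries its per-category
term counts as data, and `adjust_counts()` refuses a zero term count rather
than silently producing infinities.

## Diversity-maximising review sampling

Manual review is expensive, so the sample must earn its keep: 200 fragments
per category are chosen to be as mutually dissimilar as possible. Fragments
are vectorized twice — as bag-of-words counts of the whole text and as
counts of their matched dictionary terms — and the objective is the
weighted sum over selected pairs of the two cosine similarities,

$$ f(S) = w_t \sum_{i<j \in S} \cos(x_i, x_j) + w_m \sum_{i<j \in S} \cos(t_i, t_j), $$

minimized over size-$k$ subsets. Equal weights $w_t = w_m = 1$ on raw counts
are the default; both are exposed in `selection_config()` since the relative
scaling of the two components is a genuinely open choice. The term-profile
vector uses only matched dictionary terms, not the full vocabulary —
otherwise the two components would be nearly collinear and the term
diversity signal would drown.

Minimizing $f$ exactly is a quadratic subset-selection problem, so the
package uses a fixed-size-subset genetic algorithm: random initial
population (at least 100 seeded random subsets, whose best always enters,
so the result can never be worse than that baseline), tournament selection
of size 2, union-resampling crossover, per-position swap mutation
(probability 0.01), and single-survivor elitism, for 200 generations with a
population of 100 by default. All hyperparameters are configurable and the
whole run is reproducible from one seed. Tie-breaks return the
lexicographically smallest id set so results are deterministic. An
exhaustive-enumeration oracle (`brute_force_select()`, refusing instances
beyond $10^6$ subsets) backs the test suite; on every tested instance with
$n \le 12$ the GA attains the enumeration optimum.

For the corpus sizes in the bundled workflow (1,000 candidates per
category, $k = 200$) the GA runs 50 generations per category, which on such
instances has always reached a plateau in the trace; the full 200-generation
default is kept for smaller, harder instances.

## Manual review and term–answer associations

Each sampled fragment is presented (highlighted) with three questions: (1)
does the fragment allow judging the category of the experimental method, (2)
are the highlighted terms sufficient to judge it, and (3) is the specific
level of study mentioned. Validation of the screened category is the
question-3 judgment, so `validated = TRUE` requires `q3 = TRUE` and the
package enforces that invariant. For the term–answer association tables the
"positive answer" is operationalized as `q1 AND q2` — the fragment is
judgeable and the terms sufficed; since the two questions are presented
jointly, per-question counts are also emitted so either single-question
reading remains recoverable. A conservation law ties the tables to the
screening output — summed positive+negative counts over terms equal the
summed distinct-term incidences over reviewed fragments — and is
property-tested.

## Automated review

One binary classifier per category is trained on that category's review
sample: validated fragments are positive examples, the rest negative.
Fragments are tokenized into **distinct** lowercase words (set semantics),
which dictates a Bernoulli event model: for token $t$ and class $c$ with
Laplace smoothing $\alpha$,

$$ P(t \mid c) = \frac{n_{ct} + \alpha}{n_c + 2\alpha}, $$

where $n_{ct}$ counts class-$c$ documents containing $t$. Priors are class
frequencies; prediction multiplies presence/absence likelihoods over the
training vocabulary, ignores unseen tokens, and labels positive only when
the posterior exceeds 0.5 — an exact tie goes negative, the conservative
direction for a triage tool (a fragment is not confirmed without evidence).
$\alpha = 1$ is the default; a multinomial event model sits behind a config
switch for corpora where token multiplicity matters. Evaluation is
stratified 5-fold cross-validation from a seeded shuffle (per-fold class
counts within ±1), reporting per-fold sensitivity, specificity and balanced
accuracy — the mean of sensitivity and specificity, which any constant
classifier scores at exactly 0.5 regardless of class imbalance.

The test suite checks `nb_fit()`/`nb_predict()` against an explicit
Bayes-rule enumeration oracle (plain counting and full probability products
over the vocabulary, no shared code) to $10^{-10}$, and against an
independent reference implementation where available.

## The synthetic-corpus generator

Every stage above must be testable without network access, so
`generate_corpus()` builds corpora with planted ground truth. Each fragment
is a sequence of background tokens (disjoint from all dictionary terms) plus
its target's name; a category fragment receives one of its category's terms
with probability `term_injection_rate`; with probability `homograph_rate` a
whole-word-only term is embedded strictly inside a longer word (a trap that
must never fire); with probability `duplicate_rate/(1-duplicate_rate)` a
fragment is emitted twice, making duplicates the expected `duplicate_rate`
fraction of the corpus; and a term-bearing fragment is planted invalid with
probability `false_positive_rate`.

Review separability is controlled exactly: a valid fragment carries a token
from a positive-context block with probability $s$ (`separability`), an
invalid one a negative-context token with the same probability, and cue-free
fragments are identically distributed in both classes. Any classifier's
behavior on cue-free fragments moves sensitivity and specificity by equal
and opposite amounts, so the Bayes-optimal balanced accuracy is exactly
$(1+s)/2$ regardless — a closed form that makes parameter recovery
assertable. The defaults plant $s = 0.44$, i.e. an optimum of 0.72, with a
40% false-positive rate: a mid-range operating point for dictionary
screening of heterogeneous biomedical text, where roughly a quarter to
three-fifths of screened fragments fail review and trained classifiers
reach balanced accuracies in the low 0.7s.

Two sizing choices matter for that closed form to bind in practice. The
background vocabulary defaults to 150 tokens and the cue blocks to 4 tokens
each: with 500 labeled fragments per category, every background token is
then seen often enough that its estimated class-conditional log-ratio is
small against the cue's, and the cross-validated balanced accuracy of the
trained classifier lands within ±0.05 of the planted optimum. A much larger
background vocabulary at the same sample size injects estimation noise that
drags the learner visibly below the optimum — a real small-sample effect,
but not the property the generator exists to control.

What the generator does **not** emulate: natural language (no grammar, no
polysemy beyond the planted homographs), realistic term co-occurrence,
citation structure, or any correlation between categories and vocabulary
beyond the injected terms. Tests passing on synthetic corpora therefore
demonstrate the pipeline's mechanics — filtering, matching, selection,
estimation — not the real-world error rates of dictionary screening, which
depend on the database snapshot and dictionary in use.

## Numerical and degenerate-input choices

* Cosine similarity of an all-zero vector is 0 to everything (diagonal
  included); similarity values are clamped to $[0,1]$ against floating-point
  overshoot.
* The selection objective of an empty or singleton subset is 0; `k > n` is
  fatal; `k = n` short-circuits to the full set.
* GA ties (within $10^{-12}$) resolve to the lexicographically smallest id
  set; the trace is non-increasing by elitism.
* Posterior ties at exactly 0.5 classify negative. Likelihoods are
  accumulated in log space and normalized by the max before
  exponentiation.
* Single-class training sets, classes smaller than the fold count, empty
  dictionaries with unknown category labels, and malformed JSON lines all
  fail loudly (or warn-and-skip with a line number, for the streaming
  reader).
* An empty review category is reported as absent rather than zero-divided.

## Problem sizes

The bundled workflow and the reproduction script run at 1,000 screened
fragments per category (about 3,600 emitted records before deduplication),
select 200 per category, and cross-validate on the 600 reviewed fragments;
the calibration checks use 500 labeled fragments per category over 10
generator seeds. These sizes give stable recovered rates (binomial standard
errors of 1–2 points on the planted percentages) while keeping a full run
in seconds on one core.

## Known limitations

* The packaged dictionary is a curated reconstruction of the IUPAC
  grouping scheme, sufficient for the bundled worked examples and the
  synthetic corpora; it is not the exhaustive appendix of any published
  screening study, and real-corpus screening sensitivity depends on
  dictionary completeness.
* Highlight round-tripping assumes the fragment text itself contains no
  square or curly brackets.
* The GA is a heuristic; optimality is only guaranteed where the
  enumeration oracle can check it ($n \le 12$ in the tests).
* Negatives for each category's classifier are the invalidated fragments of
  the same category's review sample (the classifier operates within its
  screened pool). Using all other reviewed fragments as negatives is
  selectable but changes what "unrelated" means.
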