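---
title: "Weighted risk lexicons for Chinese microblog text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted risk lexicons for Chinese microblog text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suilex)
```

## The measurement model

`suilex` implements a closed-vocabulary approach to screening for suicide
risk in social-media text. The instrument is a *weighted lexicon*: a set of
words

$$W = \{(w_i, c_i, x_i)\}_{i=1}^{m},$$

where each word $w_i$ carries one of 13 risk-related category labels $c_i$
(suicide ideation, suicide behavior, psychache, mental illness,
hopelessness, somatic complaints, self-regulation, negative personality,
stress, trauma/hurt, talk about others, shame/guilt, anger/hostility) and an
integer sensitivity weight $x_i \in \{1, 2, 3\}$, from 1 ("light") to 3
("heavy", most indicative of risk). The reference instrument of this kind
for Simplified Chinese holds 2,168 words — 1,862 manually reviewed seed
words (990 of weight 1, 505 of weight 2, 367 of weight 3) plus 306 accepted
automatic expansions — but the package is agnostic to the word list: any
lexicon in the TSV format documented in `read_lexicon()` works, including
general-purpose psycholinguistic lexicons used as baselines.

Three derived quantities form the measurement chain:

1. **Post score.** All lexicon-word occurrences in a post are found and
   their weights summed. A post whose score reaches the threshold (default
   3) is flagged as carrying suicide risk, so a single "heavy" word
   suffices.
2. **User risk level.** Within an observation window, the proportion of a
   user's posts flagged risky, a number in $[0, 1]$.
3. **Feature vector.** Per user, $X = (X_1, \dots, X_{13})$ with
   $X_c = (\text{occurrences in category } c) / (\text{total tokens})$,
   feeding a margin classifier that separates high from non-high
   questionnaire-defined risk groups.

## Matching unsegmented text

How dictionary words should be counted in unsegmented Chinese is genuinely
underdetermined, so both defensible conventions are implemented as matcher
modes:

* `leftmost_longest` (default): scan left to right, at each position take
  the longest lexicon word starting there and resume after its end.
  Occurrences never overlap, and a nested word (死 inside 想死) is not
  double counted. No segmenter dependency is needed, and the result is a
  pure function of (lexicon, text).
* `all_occurrences`: every substring equal to a lexicon word counts,
  overlaps allowed — the convention of LIWC-style word-count programs.

The all-occurrences match set is always a superset of the leftmost-longest
set. Matching is exact for CJK characters and case-insensitive for Latin
letters; input is assumed NFC-normalised UTF-8, and no further
normalisation is applied, for determinism. Both modes are continuously
tested against a brute-force oracle that enumerates every substring of the
text and applies the mode's rule directly.

Weight summation counts every occurrence rather than unique words, because
frequencies are counted before weights are summed in the underlying
procedure; `score_post(unique_words = TRUE)` provides the alternative for
sensitivity analysis. The "score up to three" flagging rule is read as
$\ge 3$: weight 3 marks the maximally risk-sensitive words, so one of them
should flag a post.

## Windows, profiles and features

Calendar windows are pinned to fixed day counts (1 week = 7 d, 1 month =
30 d, 2 months = 60 d, 3 months = 90 d) so windowed results are
reproducible, and the window interval is half-open, $(a - L, a]$: a post
exactly at the anchor is included, one exactly at $a - L$ is excluded,
which avoids double counting across adjacent windows. Users with no posts
(or no tokens) in a window are excluded from that window's analysis and
reported, rather than given an arbitrary risk level.

The feature denominator is a token count produced by an injected tokenizer
contract — any deterministic function from text to a token vector
qualifies. A word segmenter can be plugged in where available;
`tokenize_characters()` is the dependency-free default (one token per
non-whitespace character) and `tokenize_whitespace()` suits pre-segmented
corpora. Ratios are invariant to the choice up to a per-user scale factor,
which the classifier's per-fold standardisation absorbs. Features are
computed over whichever posts are passed in: pass `select_window()` output
for window-scoped features (the default protocol in the evaluation
scripts) or all posts for lifetime features.

## Lexicon maintenance: votes and expansion

Review decisions follow an agreement rule: a word is eliminated if at least
`quorum` distinct coders (default 2, matching a 2-of-3 panel) vote to
eliminate it, and a category or weight override on an expansion candidate
applies only when at least `quorum` coders propose the identical value;
conflicting proposals without quorum keep the inherited values. Elimination
is monotone — more eliminate votes can only shrink the retained set.

Expansion searches a word-embedding space (word2vec text format) for each
lexicon word's $k = 4$ most similar corpus words by cosine similarity;
candidates inherit the seed word's category and weight, candidates already
in the lexicon are dropped, and low-corpus-frequency candidates (below
`min_corpus_freq`, default 5 — the underlying procedure filters rare words
without stating its cutoff, so it is configurable) are dropped when
frequencies are available. Ties in similarity are broken lexicographically
so output is reproducible; a candidate reached from several seeds is kept
once under its most similar seed. Embedding *training* is out of scope —
the module consumes pre-trained vectors; the algorithmic content is the
neighbour search and the inheritance/review rules. Merging accepted
expansions into the seed lexicon never replaces a seed entry: collisions
keep the seed word and are logged.

## Screening and evaluation

SPS (Suicidal Possibility Scale) totals are plain sums of 36 items rated
1-4 (range 36-144). The high-risk cutoff is the sample mean plus one sample
standard deviation (n−1 denominator) of the observed totals — e.g. mean
69.35 and SD 11.66 give 81.01 — and group assignment is strictly greater
than the cutoff, so a total exactly at the cutoff is non-high.

The classifier is a support vector machine with the settings fixed to
linear kernel, cost 1, and per-training-fold feature standardisation; an
optional `class_weights = "balanced"` reweights hinge losses by inverse
class prevalence for heavily imbalanced labels. Evaluation uses stratified
5-fold cross-validation with a seeded fold assignment; `cross_validate()`
reports per-fold metrics, their means, and the metrics of the pooled
out-of-fold predictions (the pooled figures are the stabler summary at
modest sample sizes and are what the package's own recovery checks use).
Precision and recall of the high class use the 0-on-zero-denominator
convention, flagged in the report; the F-measure is the harmonic mean
$2pr/(p+r)$, and reported values are rounded half away from zero to two
decimals, the precision of published comparison tables.
`permutation_null()` repeats the cross-validation on label permutations
(default 20, seeded) to give the chance-level F against which the real F is
compared.

## What the synthetic data emulates — and what it does not

Because the original word list, microblog corpus and participant data are
not published, every input has a seeded generator, and all generators are
pure functions of (specification, seed):

* `make_lexicon()` reproduces the reference bookkeeping: the 13 published
  category counts (total 2,168) and, rescaled to 1,862 entries by
  largest-remainder apportionment, exactly the 990/505/367 weight classes.
  Words are unique random CJK strings of 2-4 characters (an ASCII mode
  exists for readable fixtures), so the matcher is always exercised on
  multi-byte text.
* `make_corpus()` plants the group effect at the token level: each token
  of a high-group (non-high-group) user's post is a lexicon word with
  probability 0.08 (0.02), else a filler token verified disjoint from the
  lexicon. Defaults — 60 users per group, 50 posts per user of 5-40 tokens
  (typical microblog lengths), timestamps uniform over the 90 days before
  the anchor — define the standard simulated study used in the package's
  recovery checks. Tokens are joined without separators, like real
  unsegmented Chinese text; with a ~21,000-character alphabet, spurious
  cross-token matches have probability around $10^{-6}$ per position,
  negligible against the sampling tolerances used.
* `make_sps()` draws totals around group means with the published pooled
  distribution (mean 69.35, SD 11.66) and a default group separation of 18
  points (~1.5 SD, a strong but realistic questionnaire effect), placed so
  the pooled mean is preserved, then decomposes each total exactly into 36
  valid items.
* `make_expert_ratings()` maps true per-category occurrence counts (and,
  per user, the risky-post proportion) linearly onto the 1-7 rating scale,
  adds per-coder Gaussian noise, clips to the scale and averages three
  simulated coders. The aggregation of category content into the overall
  post rating is configurable (sum, the default, or mean) since either
  convention is plausible. In the noiseless limit ratings correlate
  perfectly with content; as noise grows the correlation decays to zero —
  the package's validity checks verify exactly this monotone chain.
* `make_embeddings()` gives each lexicon word a random unit vector, each
  planted synonym a small perturbation of its seed's vector, and each
  distractor an independent unit vector, and *verifies at generation time*
  that every synonym is strictly closer to its seed than any other
  vocabulary word (halving the perturbation and retrying on failure).

Passing recovery tests on these generators therefore shows that the
pipeline's arithmetic and algorithms are correct and that planted signal of
realistic magnitude survives the full chain. It does **not** show that the
instrument works on real social media: synthetic posts have no grammar, no
context effects (negation, quotation, sympathy expressed with risk words),
no innovative slang, and uniform word usage within groups — precisely the
phenomena a closed-vocabulary frequency method is known to be blind to.
Real-data headline results (convergent-validity correlations near 0.5
against expert ratings; F-measures of 0.48-0.56 against questionnaire
groups) are not reproducible without the unpublished data and are not
claimed by any test here.

The classifier recovery check labels users by their *planted* group, read
from the generator's ground-truth table, rather than re-deriving labels by
re-thresholding synthetic questionnaire totals: the generators emit ground
truth precisely so that recovery tests never have to re-derive it, and
mean-plus-SD re-thresholding of a balanced two-group sample would
manufacture a small positive tail only weakly coupled to the planted
effect, turning a signal-recovery check into a test of an artefactual label
definition.

## Numerical and degenerate-input conventions

* Ties in nearest-neighbour similarity break lexicographically (byte
  order); matcher output orders by start offset, then descending length.
* `sps_threshold()` requires $n \ge 2$ (the SD is undefined below that);
  `pearson()` requires $n \ge 3$ and nonzero variance in both arguments.
* Precision or recall with a zero denominator is reported as 0 and the
  report flagged `degenerate`; `f_measure(0, 0) = 0`.
* Training a classifier on a single class is an error, as is building a
  matcher from an empty lexicon; scoring an empty text returns an empty
  occurrence set and score 0.
* Largest-remainder apportionment (`apportion_counts()`) converts count
  shapes or proportions into exact integer partitions; exact integer
  inputs pass through unchanged.

## Problem sizes used in the packaged checks

The bundled tests and the acceptance script run entirely on generated
data at desk scale, chosen to keep full runs to a couple of minutes while
leaving comfortable sampling margins: the full 2,168-word lexicon with
120 users × 50 posts for signal recovery; 50 seed words × 4 planted
synonyms against 500 distractors in 50 dimensions for expansion recovery;
an exhaustive sweep of all texts up to length 7 on a 3-letter alphabet
plus 1,000 random 200-character texts for matcher-oracle equivalence; and
n = 788 users for the questionnaire sampling checks.

## Known limitations

* The matcher is a plain R scan; throughput is roughly a few hundred
  microblog-length posts per second with the full lexicon. Adequate for
  research corpora; an Aho-Corasick automaton would be the next step for
  streaming use.
* No morphological analysis, negation scope or contextual disambiguation —
  inherent to the closed-vocabulary design, not just to this
  implementation.
* Windows are fixed day counts, not calendar months.
* The embedding reader loads the full matrix into memory; very large
  vector files should be pre-filtered to the relevant vocabulary.
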