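---
title: "Analyzing consumer reactions to ancestry-test results: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing consumer reactions to ancestry-test results: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcreactions)
```

## The problem

Direct-to-consumer (DTC) genetic ancestry tests return a customer's
estimated biogeographical ancestry as percentages attributed to regional or
ethnic populations. Consumers discuss these results at scale on social
platforms — forum posts, video comments, app reviews — and those discussions
carry recoverable structure: the reported percentages themselves, explicit
statements of self-identity, and characteristic emotional reactions ranging
from acceptance and excitement to dispute and identity disruption.
`dtcreactions` is a pipeline for extracting and analyzing that structure
from free text: which ancestries people report, how they react, how reaction
and sentiment relate, and whether self-declared ethnicity agrees with the
genetic estimate.

Raw platform text generally cannot be redistributed, so the package pairs
every analysis stage with a synthetic corpus generator that plants known
structure into generated posts. All recovery claims made by the test suite
are claims about that generator's output; the section on the generator below
is explicit about what it does and does not emulate.

## Post schema and ingestion

All platforms are normalized into one schema: `id`, `platform` (closed enum:
`reddit`, `youtube`, `googleplay`, `synthetic`), `text`, optional `author`,
optional UTC `timestamp`, optional non-negative `engagement`. Two decisions
here were genuinely open:

* **Title/body concatenation.** Forum-style records carry both a title and a
  body; the pipeline analyzes their concatenation joined by a single
  newline, keeping both surfaces available to keyword matching. Analyzing
  the body alone would silently discard reaction keywords that users often
  put in titles.
* **Absent versus zero engagement.** Platforms differ in what they expose;
  an absent engagement count is stored as missing, never coerced to 0.

Serialization is JSONL (absent fields dropped per line) or CSV (explicit
`NA` markers, so an empty-string author remains distinct from an absent
one). Round-trips are lossless and order-preserving; malformed lines are
skipped with a logged count and duplicate ids are an error, since every
downstream join is keyed by id.

## Ancestry percentage extraction

Three pattern variants cover the common reporting formats:
`45% Irish`, `Irish: 45%`, and `Irish 45%`. The scanner walks percent tokens
left to right, trying the most specific context first (term before a colon,
then term directly before the percent, then term directly after), and never
reuses a consumed span, which resolves overlaps left-to-right. Choices the
format skeletons do not determine:

* The ethnicity capture takes one to three word tokens and stops at
  punctuation, conjunctions, and a blacklist of function words and
  result-talk nouns ("got", "total", "results", ...). This captures
  "Native American" and "Ashkenazi Jewish" without swallowing clauses.
* The percent grammar accepts decimals, treats a leading `<` as the bare
  number, and maps ranges (`20-30%`) to their midpoint. Values outside
  (0, 100] are discarded.

Extracted surface terms are normalized by whole-term, case-insensitive
lookup in a lexicon of 42 standardized categories spanning six regions
(12 European, 7 African, 9 Asian, 8 Americas, 3 Middle Eastern, 3 Oceania).
Every surface term maps to exactly one category; there is no fuzzy
matching. The shipped lexicon covers the documented example terms, each
category's canonical name, and country names (used by the born/raised-in
identity pattern); it is a YAML file users can extend, with validation of
the uniqueness and regional-layout invariants. Category names beyond the
documented examples are this package's own choices.

A per-post profile collapses duplicate categories for the category count
while summing every mention's percent into the total; the top percent is
the largest single mention. Summing (rather than deduplicating) duplicate
percents is a declared choice: users who report the same category twice
("Irish 40%, Irish 10%") almost always mean additive sub-components.

## Self-reported ethnicity

Six anchored patterns target explicit identity statements: "I'm/I am X",
"I identify as X", "my family are/were X", "born/raised in L",
"my ethnicity/heritage is X", and "I'm X American/Canadian/British". The
captured segment is split on conjunctions so multi-identity statements
("I'm Irish and Italian") yield multiple categories; each part is
normalized through the same lexicon, with locations handled by the
lexicon's country terms ("born in Turkey" maps to the Turkish category,
and a location with no lexicon entry is dropped rather than guessed). The
hyphenated-nationality pattern strips the trailing nationality token, so
"I'm Italian American" contributes the Italian category while
"I'm African American" — an exact lexicon term — stays African American.

## Reaction classification

Six non-exclusive binary labels (surprise, dispute, acceptance,
disappointment, identity crisis, excitement) are assigned by keyword
matching against a shipped lexicon of phrases per category. The matching
discipline is deliberately strict:

* **Whole-word/phrase boundaries**, not substrings: "scam" must not fire
  inside "scampi", at the accepted cost that "wowed" does not trigger
  "wow".
* Matching happens on lowercased, whitespace-normalized text; multi-word
  phrases tolerate any internal whitespace (line breaks included).
* Apostrophe variants ("don't"/"dont", curly or straight) all match, which
  also answers how an all-caps abbreviation like NPE is matched: the text
  is lowercased, and the word-boundary rule keeps `npe` from firing inside
  ordinary words.

The flags are independent; a post may express surprise and dispute at
once, and the corpus-level mean reactions per post is reported alongside a
pairwise co-occurrence table.

### Validation harness

Classifier quality is assessed against human annotation on a stratified
sample: up to 35 positives per category (strata filled in the fixed
category order for reproducibility), 60 posts with no detected reaction,
and uniform top-up to 300, all without replacement and deterministic per
seed. Annotation rows with incomplete labels are dropped with a logged
count. Per-category confusion counts feed precision, recall, F1, Cohen's
kappa (chance agreement from marginal products) and accuracy;
micro-averages are computed from the pooled confusion matrix and
macro-averages as unweighted means over per-category values. Metrics with
zero denominators return an undefined sentinel (`NA`) that is excluded
from macro averages with a logged count — silent zero-imputation would
bias the averages downward.

## Sentiment

Two scorers sit behind one injectable contract (`function(text) -> scores`),
so the pipeline is testable with deterministic stubs. The package ships its
own deterministic lexicon scorers as defaults:

* a **social-media valence scorer** summing word valences with simple
  negation flipping (a negator within three preceding tokens flips and
  damps the valence) and booster amplification, normalized to a compound
  score in \[-1, 1\] via `s / sqrt(s^2 + 15)`, with positive/negative/
  neutral component fractions;
* a **polarity/subjectivity scorer** averaging per-word polarity and
  subjectivity over lexicon matches.

Compound scores are categorized as positive above 0.05, negative below
-0.05, and neutral on the closed interval \[-0.05, 0.05\] — the boundary
values are neutral, reading "-0.05 to 0.05" as closed, which matches the
convention the thresholds come from. Empty text scores neutral (compound
0, polarity 0), and a scorer failure on a post degrades to neutral scores
with a warning rather than aborting a corpus run. Pairwise Pearson
correlations among compound, polarity and subjectivity quantify how much
the two scorers agree; with the shipped lexicons the two polarity measures
correlate strongly on synthetic corpora because both lexicons cover the
same generated vocabulary — real social-media text, with its much larger
vocabulary, emoji and sarcasm, would show weaker agreement.

## Descriptive analytics

Reaction prevalence uses all posts as the denominator. Dispute rate by
ancestry is computed per normalized category over the posts mentioning that
category (a post counts once per category regardless of how many
percentages it reports for it — "posts containing that ancestry" is
post-level), with categories under a minimum of 20 mentioning posts
suppressed as unstable. Concordance compares the self-reported and genetic
category sets per post by set intersection, ignoring percentages; posts
missing either side are excluded. Company mentions use case-insensitive
whole-token alias matching with spacing variants ("23 and me").

## Inferential battery

The battery wraps base R's tests and adds the effect sizes: chi-square
independence (no continuity correction) with Cramér's V
(`sqrt(chisq/(N (min(r,c)-1)))`), one-way ANOVA with eta squared and Tukey
HSD, pooled-variance (Student) t with Cohen's d (classic d uses the pooled
SD, which is why Welch is not used), Mann-Whitney U and Kruskal-Wallis H
with tie-corrected asymptotic p-values and rank eta squared
(`(H - k + 1)/(n - k)`), and Pearson r. P-values are asymptotic
throughout — the intended use is corpus-scale n — and no multiple-testing
correction is applied. For the reaction-wise rank test the caller supplies
the group vectors explicitly, since posts belong to multiple reaction
groups and no single grouping is canonical.

## Topic modeling

Preprocessing deletes URL tokens first, then replaces every non-alphabetic
character with a space, lowercases, and collapses whitespace (idempotent by
construction). The document-term matrix applies, in a fixed order:
stopword removal (shipped snowball-style English list), document-frequency
filters (drop terms in more than 95% or fewer than 10 documents), then a
5,000-term vocabulary cap by corpus frequency with alphabetical
tie-breaking for determinism.

The topic model is latent Dirichlet allocation fit by batch
variational-Bayes coordinate ascent, written in-package: per-document
variational updates to convergence inside each of 15 passes over the
corpus ("iterations" means full variational EM passes, the common
estimator parameterization), symmetric Dirichlet priors at 1/k (a standard
default; nothing in the analysis motivates asymmetric priors), gamma-random
topic initialization from a seed, and an evidence-lower-bound trace that
is non-decreasing across passes — the suite checks this at desk scale.
Per-topic sentiment uses hard argmax assignment with ties broken toward
the lowest topic index; soft weighting was rejected because the reported
quantity is a per-topic mean of posts, not an expectation over fractional
memberships.

## Dispute prediction

A logistic regression predicts the dispute flag from four features: text
length (characters), compound sentiment, number of distinct ancestries
mentioned, and top ancestry percentage. The modeling population is posts
with extractable ancestry results — top percentage is undefined elsewhere.
Features are z-scored; in cross-validation the z-scoring is fit on each
training fold and applied to its test fold, avoiding leakage (whether to
standardize globally or within folds was open; within-fold is the
conservative choice). Folds are stratified by label and deterministic per
seed. The reported coefficients come from a full-data fit on globally
standardized features; AUC is computed by the rank (Mann-Whitney) formula
with midrank ties. No regularization is applied — the reported quantities
are plain logistic coefficients.

## The synthetic corpus generator

The generator's defaults encode the study conditions the pipeline is meant
to emulate: a 68.8/29.5/1.7 platform mix; per-category reaction base rates
of 5.3% (surprise), 8.6% (dispute), 9.5% (acceptance), 3.6%
(disappointment), 2.3% (identity crisis) and 9.4% (excitement); 7.5% of
posts carrying percentage results with 1 + Poisson(1.3) categories (mean
2.3) whose percents are drawn from a Dirichlet scaled to a total near
94.2%; a 1.7% marginal self-report rate concentrated on result posts (4%
of result posts, reproducing a ~0.3% joint rate); 61.8% concordance
between self and genetic sets for posts carrying both; and per-ancestry
dispute multipliers shaped like the observed dispute-rate table. Percent
rendering mixes integers with occasional one-decimal values across the
three extraction formats; identity statements render through the six
self-ID patterns.

Design points worth knowing:

* **Label purity.** Filler sentences are drawn from a bank screened
  against every lexicon (no reaction phrases, no percent signs, no
  identity anchors), and reaction phrases are planted only from the subset
  of each category's lexicon that classifies to exactly that category
  (e.g. "never expected" contains the acceptance keyword "expected" and is
  excluded from the planting bank while remaining in the classifier
  lexicon). Recall and prevalence recovery are therefore exact properties,
  not approximations.
* **Dispute attribution.** A result post's dispute probability is the base
  rate times the boost of one *focal* mentioned category, drawn uniformly
  from the post's categories. Boosting by, say, the maximum boost across
  all mentioned categories lets co-mentions contaminate every category's
  marginal rate and destroys the rank ordering the boosts are supposed to
  induce; focal attribution keeps each category's marginal dispute rate
  strictly monotone in its configured boost.
* **Valence coupling.** Excitement-flagged posts receive positive filler
  and dispute/disappointment-flagged posts negative filler, so the
  qualitative sentiment ordering of reactions is reproduced; exact
  compound means are scorer-dependent and deliberately not targeted.

What the generator does **not** emulate: platform idiolects, sarcasm,
misspellings, code-switching, keyword mentions in negated or quoted
contexts, or any correlation structure beyond the planted one. Passing
recovery tests therefore demonstrates that the pipeline's machinery is
correct on well-formed input — not that its precision on real platform
text matches the validation numbers, which only annotation of real posts
can establish.

## Numerical choices and degenerate inputs

* Undefined metrics (zero denominators, chance agreement of 1) return
  `NA`, never 0, and are excluded from macro averages with a logged count.
* The LDA E-step guards variational normalizers with `1e-100`; document
  convergence threshold is a mean absolute gamma change below `1e-6`, with
  a 100-inner-iteration cap.
* Z-scoring guards zero-variance features by leaving them centered but
  unscaled.
* Degenerate statistical inputs (zero margins, constant samples, single
  classes) raise errors rather than returning misleading numbers.
* Composition percentages, dispute rates and concordance are recomputed
  from counts, so they are exact by construction.

## Problem sizes used by the checks

The test suite exercises recovery at corpus sizes of 5,000 posts (planted
mention/self-ID recall, prevalence, concordance, dispute-model coefficient
recovery at n = 5,000 with effects planted on standardized features), and
the dispute-boost rank-order property pools ten seeded corpora of 10,000
posts. The statistical wrappers are checked against longhand
direct-definition oracles on 100 random small instances each at tolerance
1e-9, and the topic model on two-cluster corpora of 120–160 documents.
These sizes were chosen so every property has enough resolution for a
three-standard-error binomial bound while keeping a full run of the suite
comfortably interactive.

## Known limitations

Keyword classification has no negation or sarcasm handling, so precision
on real text degrades in ways the generator cannot show. The ethnicity
lexicon is a curated subset; recall on real text depends on its coverage
and the born/raised-in pattern is only as good as the country-term list.
The shipped sentiment lexicons are compact and tuned for the generated
vocabulary; for production analysis of real platform text, bind
full-scale scorers through the scorer contract. The dispute model's four
features are deliberately minimal; text length dominating its coefficients
partly reflects the mechanical fact that longer posts have more chances to
contain a keyword.
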