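---
title: "Methods: surveillance of e-liquid flavor mentions on social media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance of e-liquid flavor mentions on social media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavorwatch)
```

## The problem

Electronic-cigarette liquids ("e-liquids") are sold under thousands of
flavor names, and flavor availability is a live regulatory question.
Social-media discussion is a cheap, timely signal of which flavors people
use and how they feel about them. `flavorwatch` implements an
infoveillance pipeline for that signal: classify flavor keywords into a
hierarchy, reduce a raw post corpus to reliable flavor mentions, track
monthly mention trends, and quantify per-category sentiment with formal
proportion tests.

## The flavor taxonomy

Flavors live in a three-level hierarchy: seven top-level categories
(`fruit`, `sweets`, `beverage`, `tobacco`, `menthol_or_mint`, `mixed`,
`others`), subcategories within each (e.g. `berry`, `tropical`, `citrus`,
`melon`, `mixed fruits`, `others` under `fruit`), and specific flavor
keywords within each subcategory. `mixed` holds flavors whose configured
ingredients span two or more categories (e.g. "fruit + mint"); `others`
is the total fallback. Both must exist in every valid taxonomy, and
validation is strict: a keyword under two paths, a missing fallback, or
an unknown category name is an error, never a warning.

The bundled config (`inst/extdata/table1_taxonomy.tsv`) is a diff-able
tab-delimited file, one row per keyword, with optional alias and
ingredient columns. Two deliberate choices:

* **No automatic parsing of compound names.** A term is multi-category
  only if its configured ingredient list says so; flavor standardization
  in practice is a manual curation step, and guessing from surface
  strings ("dragon punch") would misclassify silently.
* **Single-ingredient fallback subcategory.** A term known only through
  one ingredient category is filed under that category's `others`
  subcategory when one exists, otherwise its first subcategory. This
  keeps `classify_term()` total without inventing subcategory structure.

## Matching and filtering

The matching rule is the pipeline's backbone: keywords match
case-insensitively **at token boundaries** (the characters around a match
may not be letters or digits), with a leading `#` stripped so hashtags
match, and multi-word keywords matching across single spaces. Substring
matching is exactly the failure mode the denoise step exists to repair,
so it is never used for topic or body keywords; author-handle screening
is the one deliberate exception (promotional accounts embed keywords in
compound handles like `BestVapeStore`, where token boundaries do not
exist).

Corpus reduction is staged, and every stage logs exact input/output
counts to a run manifest:

1. **Topic filter** — keep posts matching at least one e-cigarette topic
   keyword (bundled list of 20).
2. **Promotion filter** (two observable steps) — drop posts whose author
   handle contains a promotion-related substring, then posts whose body
   matches a promotion keyword (`customer`, `promotion`, `discount`,
   `sale`, `free shipping` by default — shipped as a user-extensible
   config, not a closed list). On by default for the Twitter-style
   sentiment workflow; off by default for the Reddit-style trend
   workflow, where promotion screening is not part of the standard
   reduction. A config flag flips either.
3. **Mention extraction** — all non-overlapping flavor-keyword matches,
   longest-match-first (so "cotton candy" is one mention, not two), each
   resolved to its taxonomy path. A post matching keywords in several
   categories contributes one mention per match: the counting unit is
   the mention, not the post, which is what makes subcategory count
   tables internally consistent.
4. **Denoise** — for each suspect keyword, labeled sample posts give a
   confusion matrix; keywords with sample precision below 0.90 or recall
   below 0.75 are excluded from all further matching. Undefined
   precision/recall (zero denominator) excludes. The keyword-level
   exclusion is the only lever: there is no per-post reweighting.
5. **Single-flavor subset** (sentiment workflow only) — keep posts with
   exactly one distinct flavor keyword, so each post attributes to one
   category unambiguously. Repeated mentions of the same keyword count
   once.

## Trends

Monthly tables count mentions per (UTC month, category) over a fixed
seven-category set, zero-filled across the requested range so months are
comparable. Normalization divides by the month's total mention count;
proportions in an active month sum to 1, and empty months are flagged
rather than dropped. Subcategory percentage tables use half-up rounding
to two decimals — the convention of published distribution tables —
implemented with an epsilon guard against binary representation of
decimal halves. The trend tables report *mentions* per category; a
post-level count would undercount posts discussing several flavors of
one category, and the mention unit is the one under which subcategory
counts sum to their category total.

## Sentiment

A valence scorer is an injected contract: any function mapping texts to
compound scores in [-1, 1]. Scores are thresholded into three labels:
[-1, -0.05] negative, (-0.05, +0.05) neutral, [+0.05, +1] positive —
boundaries assign outward, and the three intervals partition [-1, 1].
Two adapters ship with the package:

* `stub_valence_scorer()` — reads cue words with fixed valences that the
  synthetic generator plants, deterministically; end-to-end tests
  therefore never depend on any lexicon's weights.
* `lexicon_valence_scorer()` — a small authored word-list scorer with
  simple negation flipping, adequate for demonstration on real text. For
  production surveillance, inject a full lexicon-and-rules analyzer
  (e.g. a VADER-class model) through the same contract.

Per-category aggregation reports post count, mean score, sample (n-1)
standard deviation (at surveillance sample sizes the n vs n-1 choice is
immaterial; n-1 is the convention), and label proportions normalized by
the category's post count. Categories under `min_count` posts (default
300) are flagged and excluded from testing: miscellaneous low-volume
categories (typically `others` and `mixed`) give unstable proportions.
The default sits between the low-volume categories seen in practice
(roughly 100-300 posts) and the well-populated ones (1500+).

## Proportion tests

Within each tested category, the positive proportion is compared with
the negative proportion by the textbook pooled-variance two-proportion
z-test — pooled `p = (x1+x2)/(n1+n2)`, no continuity correction, the
default form of the standard statistical packages — with a two-sided
normal p-value, Bonferroni-adjusted (`p_adj = min(1, m p)`, `m` = number
of categories tested after the minimum-count filter) and flagged
significant when `p_adj < 0.05`, strictly. Both raw and adjusted
p-values are reported. A degenerate pooled proportion (0 or 1) yields an
undefined statistic, p = 1, and an explicit flag.

One statistical caveat is accepted deliberately: the positive and
negative counts come from the *same* posts, yet the test treats them as
independent samples of size `n_posts` each. That is the convention under
which such comparisons are reported in the surveillance literature, and
fidelity to that convention wins over a within-sample multinomial test;
the manifest records the counts so a reader can re-test under any model.

## The synthetic generator

`generate_corpus()` emulates every statistical structure the pipeline
assumes, with a ground-truth ledger covering each post exactly once:
template posts embedding taxonomy keywords (including hashtag and
multi-word forms) drawn from a configurable category distribution with
optional linear drift across months; promotional posts split between
handle-detectable and body-detectable; optional ambiguous-keyword posts
with a planted labeling precision; and sentiment cue words with planted
valences the stub scorer reads back. All randomness flows from one seed
through R's generator, scoped so global RNG state is untouched; the same
seed yields a byte-identical corpus.

Defaults are the study conditions the pipeline targets: the category
distribution follows observed Reddit flavor-mention shares (fruit 0.58,
sweets 0.15, beverage 0.10, menthol/mint 0.08, tobacco 0.06, others
0.02, mixed 0.01), sentiment mixes are positive-leaning (0.50/0.30/0.20)
for fruit, sweets and menthol/mint and negative-leaning (0.25/0.30/0.45)
for beverage and tobacco — matching the reported direction of Twitter
sentiment — and uniform for the two miscellaneous categories; 10% of
posts are promotional and 5% carry a second flavor keyword.

What the generator does *not* emulate: linguistic realism (templates are
slot-filled sentences), platform idiosyncrasies (thread structure,
retweets, character limits), topic drift in the background vocabulary,
and sarcasm or other phenomena that defeat lexicon scorers. Passing
recovery tests therefore validates the pipeline's bookkeeping and
statistics — filtering, counting, normalization, thresholding, testing —
not the adequacy of any particular sentiment model on real language.

## Validation problem sizes

The recovery experiments use corpora the package generates at run time:
20,000 posts for end-to-end parameter recovery (recovered proportions
checked within 3 binomial standard errors of planted values; directional
test conclusions checked after Bonferroni), 1,500 posts with a 30%
planted ambiguous keyword for the denoise harness, and 10,000 replicates
at n = 200 per arm for null calibration of the z-test (rejection rate
0.05 ± 0.01). Published percentage tables are reproduced from their
printed counts exactly at two decimals under half-up rounding; two
printed cells (candy 24.18, milk 7.85) differ from exact recomputation
by 0.01 — truncation rather than rounding in the source — and are
documented rather than matched.

## Known limitations

* Keyword matching has no word-sense disambiguation beyond the denoise
  exclusion; an ambiguous keyword that passes the precision bar still
  contributes noise below that bar.
* The taxonomy covers configured keywords only; novel flavor names are
  invisible until added to the config.
* The independence caveat on the within-category proportion test, above.
* Trend tables are descriptive; no changepoint or trend-significance
  testing is attempted.
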