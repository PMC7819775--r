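---
title: "Retrieving similar chat segments: model, parameters, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving similar chat segments: model, parameters, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatmatch)
```

## The retrieval model

`chatmatch` treats "find me a similar past situation" as nearest-neighbour
search in a sentence-embedding space. The unit of retrieval is not a whole
chat but a **window** of 5 consecutive messages, because helpline
conversations are long and typically move through several distinct problems;
a whole-chat embedding would blur them together. Every chat of $m$ messages
contributes all $m - 4$ stride-1 windows, so consecutive windows share 4
messages and the index covers every 5-message context the corpus contains.

A window is embedded by **smooth inverse frequency (SIF)** weighting:

$$ v \;=\; \frac{1}{n} \sum_{w \in \text{kept tokens}}
   \frac{a}{a + p(w)}\, \mathrm{vec}(w), $$

with $p(w)$ the word's relative frequency in the (filtered, normalized)
chat corpus itself, $a$ a smoothing constant, and "kept" meaning the token
has both a pretrained vector and a corpus frequency. The weight decreases
strictly in $p(w)$: common function words contribute little, rare content
words dominate. This is a bag-of-words model — token order inside the window
is irrelevant by construction — and it assumes the pretrained vector space
places semantically related words near one another; the embedding adds no
information the vectors do not carry.

The query side is deliberately symmetric: the last 5 messages of the
ongoing conversation go through the *identical* normalize → tokenize → SIF
pipeline, and windows are ranked by cosine similarity. Cosine, not
Euclidean distance, because SIF averages of different window lengths differ
in norm for uninteresting reasons; only direction carries content here.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `window_size` | 5 messages | retrieval granularity; smaller windows localize problems, larger ones add context |
| `min_interactions` | 20 messages | chats shorter than this are dropped at indexing time; very short chats rarely contain a developed situation worth recommending. A chat of exactly 20 is kept. |
| `sif_a` | $10^{-3}$ (dimensionless) | the canonical choice for SIF weighting; weights halve roughly where $p(w) = a$, so $10^{-3}$ discounts words more frequent than ~1 in 1000 tokens |
| `context_size` | 5 messages | the query uses only the conversation tail: the recommendation should track the *current* problem, not the whole history |
| `top_k` | 10 windows | enough choice for a counselor to scan without overwhelming them |
| `remove_common_component` | `FALSE` | the optional SIF post-step (projecting out the first singular direction of the embedding matrix); off by default so the default pipeline is exactly the weighted average |
| `dedup_per_chat` | `FALSE` | overlapping windows of one chat may legitimately crowd the top 10 (they are genuinely the most similar contexts); the flag offers one-best-per-chat when diversity matters |

Out-of-vocabulary tokens are **skipped**, and the $1/n$ average runs over
kept tokens only — imputing vectors would invent geometry, and dividing by
the full token count would shrink vectors of OOV-dense windows toward zero
for no semantic reason. A window with no embeddable token at all becomes a
zero vector, is kept in the index metadata, and is excluded from ranking
(cosine is undefined at zero).

## Numerical and tie-breaking choices

* Message indices are 0-based and windows half-open `[start, start + w)`,
  so window counts and overlaps are uniform arithmetic.
* Ranking ties are broken by `(chat_id, start)` ascending. Ties occur in
  practice (duplicated windows, symmetric synthetic geometry), and metadata
  tie-breaking makes results invariant to index row order.
* Retrieval is exact and exhaustive: a dense matrix-vector product over all
  rankable rows. At the scales this package targets (~10^4–10^6 windows)
  this is fast and keeps the ranking contract testable against a
  brute-force oracle to 10^-9.
* The index artifact is a single versioned RDS container; loading verifies
  the format version and the matrix/metadata row alignment.
* Text cleaning keeps letters, digits, whitespace and `. , ? ! ' -`. The
  retained punctuation carries tone (questions, emphasis) through to
  display; tokens are edge-stripped of it, so `"het?"` and `"het"` coincide
  while an internal hyphen (`"stop-gap"`) survives. Cleaning is idempotent,
  which makes re-normalizing already-clean synthetic text a no-op.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` describes a topic-structured stand-in for a real
helpline corpus: each chat carries one latent topic (the help-seeker's
problem); tokens mix a topic vocabulary with shared function words
(`shared_rate` = 0.3); senders alternate; chat lengths are uniform on
20–40 messages so the default corpus passes the length filter intact; and
word vectors cluster around per-topic centroids of norm
`topic_separation × noise_sd` with isotropic noise `noise_sd`. The defaults
(200 chats, 5 topics, 40 topic words + 20 shared, dimension 25, separation
3, noise 0.3) give roughly 5,200 windows — large enough to exercise ranking
and evaluation, small enough that a full experiment runs in about a second.

The generator is a pure function of its config and seed, which is what the
determinism and byte-reproducibility tests rely on.

It does **not** emulate natural dialogue: no grammar, no emotional arc, no
per-window topic drift (ground truth is one topic per chat, which is what
makes the evaluation oracle unambiguous), no misspellings, and token
frequencies are uniform within a vocabulary rather than Zipfian. Passing
tests on this corpus therefore demonstrate the *mechanics* of the pipeline
— segmentation arithmetic, weighting laws, exact ranking, calibration of
the random arm — not linguistic retrieval quality on real chats, which
depends on the pretrained vectors supplied in deployment.

One property of the generator deserves emphasis. Topic vocabularies are
disjoint, so the corpus carries topic signal through **two** channels:
the geometry of the word vectors (controlled by `topic_separation`) and
plain lexical overlap (same topic ⇒ same words). The lexical channel does
not vanish when `topic_separation = 0`: with any fixed assignment of
vectors to words, windows of one topic still share word identities and
concentrate around their topic's empirical vocabulary-mean vector (its norm
scales as $\sigma\sqrt{d/V}$ for vocabulary size $V$, and the expected
same-topic window cosine behaves like $n/(n+V)$ for $n$ window tokens). A
bag-of-words embedding therefore still separates topics at zero geometric
separation, and matched segments keep beating random ones there. The
separation dial calibrates the *geometric* channel only; the package keeps
the disjoint-vocabulary design because it is what gives every chat an
unambiguous ground-truth label. The degenerate calibration that *is* exact
is the single-topic corpus, where matched and random arms both score 1 and
the gap is identically 0.

## The in-silico validity experiment

`run_validity_experiment()` mirrors a matched-versus-random design: per
ongoing chat, 10 segments are presented — the algorithm's top 5 and 5 drawn
uniformly without replacement from the remaining rankable windows (the
exclusion prevents a segment from appearing in both arms) — and each
segment is scored by a ground-truth oracle: 1 if its source chat shares the
query's topic, else 0. Three queries per experiment give 30 judged
segments. The oracle replaces human similarity ratings, so the testable
content is *direction and calibration* — the matched arm must beat the
random arm, whose mean must sit at the corpus topic base rate — not the
magnitude of any human rating. Per-trial records are exposed in the report
(and its JSON serialization) so downstream statistics can be run outside
the package.

The test suite runs this experiment over 20 seeds at the default
conditions and checks that the gap is positive in at least 19 of them and
mean precision@10 is at least 0.8 against a 0.2 chance level; those problem
sizes (200 chats, 3 queries, 20 seeds) are the package's chosen balance
between statistical resolution and suite runtime.

## Known limitations

* Bag-of-words SIF cannot distinguish negation, speaker, or word order;
  contextual encoders would, but are a different artifact.
* Frequencies come from the indexed corpus, so the index should be rebuilt
  when the corpus changes materially; there is no incremental update.
* The recommender never judges *usefulness* — only similarity. Whether a
  similar past chat actually helps a counselor is an empirical question
  about humans, outside what simulation can answer.
* No anonymization is provided; the package is built to be developed and
  validated entirely on synthetic data precisely so that real transcripts
  never need to leave their secure environment.
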