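---
title: "Models and methods behind readguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind readguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readguide)
```

## The problem

Fluent reading requires several abilities at once: recognizing a string of
letters simultaneously (the *recognition span*), fixating it long enough
for recognition to succeed (*temporal summation* of visual evidence, which
is effective up to roughly 500 ms), executing reading saccades whose
amplitude matches the span, and delaying pronunciation until the phoneme
sequence has been retrieved from memory.  Poor readers often overreach:
they attempt more letters per fixation than they can recognize, saccade
too far, fixate too briefly, and speak too early.  `readguide` implements
the machinery to (a) measure a reader's span and required fixation time
with an adaptive pseudoword staircase, (b) compile that profile into a
timed guidance script that steers fixations, saccades and speech onsets
through a text, and (c) evaluate the approach end to end on synthetic
readers with the statistics used for crossover reading experiments.

Everything is simulation-based: the package contains no human data.  The
synthetic cohort is calibrated to a published cross-tabulation of 60 poor
readers (spans 3–6 letters, fixation times 250–500 ms), which serves as a
fixture for parameter-recovery and protocol tests.

## Pseudoword stimuli

Assessment lists use pronounceable pseudowords so that responses cannot
rely on lexical guessing — every letter must actually be recognized.  Each
length has one fixed consonant/vowel template (`CV`, `CVC`, `CVCV`,
`CVCVC`, `CVCCVC`), so all items of a list place consonants and vowels at
the same positions.  Phonotactic plausibility is operationalized as a
shipped permitted-bigram table (all CV and VC pairs over a German-style
alphabet without umlauts, plus a fixed list of word-medial consonant
clusters) rather than a lexicon: this is reproducible, auditable and
configurable.  Lists contain 20 unique items and regenerate bit-identically
from their seed.

```{r}
generate_list(4, n = 5, seed = 7)$items
```

## Scoring responses at the letter level

A word counts as misread if at least one letter is omitted, replaced,
shifted to another location, or added.  `align_letters()` computes a
minimal edit alignment (ties broken match > substitution > deletion >
insertion, left to right); `classify_response()` maps deletions to
omissions, insertions to additions, and substitutions to substitutions —
except that two substituted positions at most two apart whose letters
appear swapped are reported as a transposition.  Position flags attribute
each error to a target letter position; an inserted letter charges the
nearest following target position (end insertions charge the last
position) so that the per-position profile always has the word's length.
These profiles reproduce the characteristic left-to-right rise of
misread-letter rates when fed from the simulator's graded error model.

```{r}
classify_response("belo", "bleo")$error_kinds
position_error_flags("raket", "rakte")
```

## The adaptive staircase

The assessment starts at 4-letter pseudowords presented for 250 ms.  A
list passes when at least 19 of 20 items (95%) are read correctly.

* pass at 250 ms, before any demotion, below 6 letters → length + 1;
* any other pass → terminate; the profile is the current (length, time);
* fail below 500 ms → same length, + 50 ms;
* fail at 500 ms above 2 letters → length − 1, time resets to 250 ms, and
  a demotion latch is set;
* fail at 500 ms at 2 letters → terminate at the floor (2, 500 ms).

Three choices here were genuinely open and are fixed as follows.  After a
demotion the time ladder restarts at 250 ms, which yields the *minimal*
passing time and matches reporting exactly one (span, time) pair per
reader.  A pass at a time above 250 ms terminates instead of promoting,
for the same reason.  The demotion latch forbids re-promotion, which
excludes pass/fail cycles; termination is guaranteed within
(6−2+1)·6 + 6 = 36 list administrations, and the default budget of 30
lists encodes the bounded session length.

With the default simulator cost of 300 ms per letter beyond the span,
a deterministic threshold reader with span s\* and threshold T\* passes
sub-span lists at 250 ms and fails over-span lists everywhere on the
grid, so the staircase provably recovers (s\*, T\*) exactly for every one
of the 30 grid combinations — the test suite asserts all 30, and the
60-reader cohort round-trips to its generating cross-tabulation.

## The synthetic reader

Recognition of an `n`-letter string after a fixation of `t` ms follows a
shifted logistic in time with a linear length cost:

τ(n) = T\* + κ·(n − s\*) for n ≥ s\*, and
τ(n) = max(150 ms, T\* − κ·(s\* − n)) below the span;

p(n, t) = logistic(slope · (t − τ(n)) + logit(p₀)).

The psychometric family is a modeling choice; the data constrain only
monotonicity (nondecreasing in time, nonincreasing in length).  The
calibration constant p₀ (`p_at_threshold`, default 0.99) anchors the
curve so that recognition at exactly (s\*, T\*) succeeds with probability
0.99, consistent with these thresholds being *defined* by the ≥95%
criterion: with p₀ = 0.99 the list-level pass probability at threshold is
about 0.98.  An infinite slope gives the deterministic step reader used
for exact recovery tests.  κ defaults to 300 ms per letter, which places
τ(s\*+1) beyond the 500 ms grid for every threshold on it (one letter too
many is unrecognizable at any allowed time) and τ(n < s\*) at or below
250 ms (shorter strings need no extra time) — both properties the
staircase's start-at-4 design relies on.

Failed recognitions are corrupted with at least one letter error drawn
from a mixture over omission, substitution, transposition and addition
(defaults 0.40/0.35/0.15/0.10), with victim positions drawn with weights
1 + g·(i−1)/(len−1); the default gradient g = 1 produces the rising
positional error profile.

In **free reading** the reader advances in chunks of `attempted_span`
letters with self-chosen fixation durations sampled lognormally around
`duration_factor`·T\* (default factor 1.2, CV 0.1); with probability
`premature_speech_p` a fixation is cut to 50–90% of T\* (a too-early
saccade).  Only the first min(s\*, chunk) letters can be recognized;
letters in the gap are guessed correctly with `guess_p`, and a failed
guess is always wrong.  Regressions are interspersed at `regression_rate`
per chunk and cost time without changing outcomes.  In **guided reading**
fixations follow the script's offsets and planned durations, a failed
segment is retried once, speech waits for tone + 250 ms, and regressions
occur only as compliance lapses (probability `compliance_lapse_p`), which
also spoil that segment's pronunciation.

What the generator deliberately does *not* emulate: oculomotor dynamics
(velocity profiles, landing-site noise), lexical or contextual guessing
beyond a flat per-letter probability, learning within a session, and
fatigue.  Passing tests therefore show that the pipeline behaves correctly
under the stated model, not that the model captures everything about real
readers.

## The guidance script

`build_script()` renders the text as one line with single spaces (0-based
character offsets), splits each word greedily into segments of at most the
profiled span (remainder last — this maximizes segment fill and never
exceeds the span), and puts the fixation mark on each segment's middle
letter (left of middle for even lengths).  Per segment the schedule is:
cursor move, tone at +1000 ms, speech window at +1250 ms, segment advance
after a 500 ms pronunciation window, and a 40 ms saccade gap before the
next cursor move.  The planned fixation duration is
max(profile time, 250 ms).  Text left of the current segment is hidden, so
the hidden-region boundary is non-decreasing and regressions have no
target.  Within-word saccade amplitudes are bounded by the span
(⌊k/2⌋ + ⌈k'/2⌉ ≤ span for consecutive segment sizes k, k' ≤ span).

## Statistics

Group differences use the pooled-SD standardized mean difference
d = (X̄₁ − X̄₂)/S_w with S_w = √[((n₁−1)S₁² + (n₂−1)S₂²)/(n₁+n₂−2)].
Confidence intervals use the standard large-sample form
d ± z·√((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂))); no claim is made that this
reproduces any particular published interval, whose formula is not
documented.  Wilcoxon tests are implemented with mid-ranks for ties and
exact null distributions (generating-function counting over doubled
mid-ranks) up to 25 informative pairs (signed-rank) or 10 per group
(rank-sum), with a tie-corrected, continuity-corrected normal
approximation beyond; two-sided p is min(1, 2·min(lower, upper)).  The
Holm step-down adjustment is delegated to `stats::p.adjust`.  Positional
misread-rate comparisons are intended to be run as paired signed-rank
tests across readers' per-position rates, Holm-corrected within each word
length.

## Study protocols and problem sizes

`table1_cohort()` instantiates one deterministic threshold reader per
cell of the published 60-reader cross-tabulation, with the published
group labels, ages drawn from N(122.4, 19.3²) months, and speech-retrieval
parameters matched to the per-span latency summaries.  Its free-reading
defaults encode the miscalibration hypothesis: attempted span = true span
+ 2, 5% premature fixations, 30% regressions, `guess_p` = 0.9 (meaningful
words, unlike pseudowords, can usually be guessed from partial letters),
and a 2% compliance-lapse rate under guidance.  These values were fixed
once, from the consideration that they put unaided error rates in the
7–8% region reported for poor readers on this material, and are not tuned
per run.

`match_groups()` stratifies by (span, time), splits age-adjacent pairs
between the groups, and sends odd leftovers to the smaller group, so
imbalance is at most one per stratum and overall.  `crossover_assign()`
counterbalances part order within each group; therapy readers are aided
on their second-read part, controls never.  `run_experiment2()` simulates
all 60 readers over the four synthetic texts (216 words; the per-part
word/letter counts equal the published material counts, so percentage
denominators match), then computes group summaries, signed effect sizes,
their contrast, and signed-rank p-values.  The default run derives each
deterministic reader's profile directly from its generative parameters;
`assess = TRUE` instead runs the full staircase per reader (used in the
end-to-end recovery tests).  One full experiment takes a few seconds; the
directional acceptance check repeats it over 50 master seeds, the scale at
which a single CPU completes the property comfortably while leaving
Monte-Carlo noise on the win proportion negligible.

All randomness flows through explicit integer seeds; derived sub-seeds
stay below 2³¹, and seeded package functions restore the caller's RNG
state.

## Known limitations

* The simulator's free-reading saccade and duration distributions are
  invented defaults (no quantitative distributions are published); they
  are configurable and clearly separated from the protocol logic.
* Speech-onset modelling (truncated normal retrieval plus exponential
  reaction) targets the published group means/SDs only loosely; the
  recovery test checks means within sampling error, nothing finer.
* The guidance engine schedules events but does not render displays or
  play tones; hyphenation and punctuation receive no special cursor
  handling (punctuation stays attached to its word).
* Effect sizes from simulated cohorts need not numerically match any
  published human value and are only checked directionally (therapy
  effect dominating the control effect); published numbers are reproduced
  only where they are pure summary arithmetic.
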