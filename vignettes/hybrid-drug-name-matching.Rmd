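---
title: "Hybrid string and phonetic matching of misspelt drug names"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid string and phonetic matching of misspelt drug names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fonospell)
library(dplyr)
```

## The problem

Free-text clinical notes in Brazilian Portuguese carry frequent misspellings
of drug names — both *typographic* (dropped, doubled, swapped or substituted
letters: `fluoxetna`, `fluxoetina`) and *phonetic* (a different spelling of
the same sound: `parassetamol` for `paracetamol`, often produced by writers
whose first language is Spanish or Italian). Exact dictionary lookup misses
these mentions; a pure edit-distance search either misses phonetic errors at
tight cutoffs or floods the annotator with false positives at loose ones.

`fonospell` implements a hybrid decision rule: a token `w` is accepted as a
variant of drug `d` only if it passes **both** a phonetic-similarity cutoff
and a string-similarity cutoff,

$$\mathrm{match}(d, w) \iff \mathrm{PhonSim}(d, w) \ge \theta_p \;\wedge\;
  \mathrm{StrSim}(d, w) \ge \theta_s ,$$

with the pair $(\theta_p, \theta_s)$ tuned by grid search on labelled
candidate pairs. The accepted variants form a dictionary that a trie-backed
bounded-edit-distance index then applies to whole corpora.

## Similarity metrics

Edit distance is plain Levenshtein: unit-cost insertions, deletions and
substitutions, no transposition primitive, so an adjacent swap costs 2. String
similarity normalizes by the longer word,

$$\mathrm{StrSim}(w_1, w_2) = 1 - \frac{ED(w_1, w_2)}
  {\max(|w_1|, |w_2|)} \in [0, 1],$$

which equals 1 only on identity. Phonetic similarity applies exactly the same
formula to the two *phoneme sequences* instead of the letter sequences, using
symbol-level edit distance. Both scores are undefined (`NA`) when a
denominator would be zero — two empty strings, or a word whose encoding is
empty (for instance a bare `h`).

```{r}
string_similarity("fluoxetina", "dfluoxetina")
phonetic_similarity("cassa", "caça")
```

## The grapheme-to-phoneme rule table

The phonetic encoder is driven by an ordered, versioned rule table shipped at
`inst/extdata/phonetic_rules_pt.tsv` (`phonetic_rules()` loads it; any
user-supplied table with the same columns can replace it). It is a compact
model of Brazilian-Portuguese orthography, *not* an IPA transcription: no
stress, no vowel quality, one symbol per sound class. The design goal is that
the common homophone classes collapse onto shared symbols:

* `ss`, `ç`, and `c` before `e/i` all emit `S`; single `s` and `z` between
  vowels both emit `Z`; word-final `z` emits `S`;
* `ch` and `x` word-initially or after a consonant emit `SH`; between vowels
  `x` emits `K S` (as in `fluoxetina`);
* `qu`/`gu` before `e/i` emit bare `K`/`G`; `h` is silent; `lh`, `nh`, `rr`
  have their own symbols; `m`/`n` before a consonant merge into the nasal
  `N`; doubled letters collapse.

Normalization lower-cases, strips diacritics and removes non-letters before
rule application, keeping `ç` because it carries phonetic information.
Accent-stripping is deliberate: misspellings routinely omit diacritics. One
consequence worth noting: because intervocalic `x` expands to two symbols, a
phoneme sequence can be one symbol longer than its word per intervocalic `x`;
every other rule emits at most one symbol per letter consumed.

The published description of the original Portuguese phonetic-map metric does
not include its phoneme inventory, so this table is a declared, testable
substitute rather than a reproduction: thresholds tuned with it can differ
slightly from values obtained with the original metric.

```{r}
pt_phoneme_key(c("fluoxetina", "chave", "xave", "hora", "ora"))
```

## Candidate generation (blocking)

Comparing every drug against every token is wasteful, so candidates are
blocked first: a vocabulary word enters a drug's candidate list iff it shares
at least 3 consonantal phonemes with the drug (order-preserving longest
common subsequence — order sensitivity keeps anagrams out; a multiset count
is available via `method = "multiset"`) **or** lies within edit distance 3.
Tokens shorter than 4 letters are dropped because they match almost anything
within 3 edits, and a drug is never its own candidate. A deliberately loose
string-similarity pre-filter (`filter_candidates()`, cutoff 0.6) then trims
the list while still keeping roughly half false candidates — the set a human
annotator (or the simulator) labels.

## Threshold tuning

`tune_thresholds()` performs the exhaustive grid search. The default grid is
the Cartesian product of phonetic cutoffs $\{0.500, 0.505, \dots, 1.000\}$
with string cutoffs $\{0\} \cup \{0.500, \dots, 1.000\}$ (10 302 pairs);
string cutoff 0 encodes the phonetic-only rule, and the exact grid is an
input, so any TSV of pairs can replace it. Walking the grid in file order,
the incumbent is replaced only when a pair **strictly** improves both the
training-set and the validation-set F1 — ties never replace the incumbent,
which makes the search deterministic — and the last accepted pair is
returned together with both confusion summaries and the full grid trace
(`tidy()`, `glance()`, `autoplot()`). Undefined F1 (no predicted or no true
positives) never enters the comparison; if no grid point is defined on both
sets, tuning fails loudly. Metrics are kept at full precision internally and
rounded only for display.

The train/validation split is an explicit input: `split_drugs()` provides a
seeded random half/half split of the drug list, and candidate pairs follow
their drug.

## Variant dictionary and trie search

`build_variant_dictionary()` chains blocking, the pre-filter and the tuned
decision rule, and adds each canonical name as a variant of itself; a variant
spelled exactly like a canonical name always maps to itself. The dictionary
feeds `fuzzy_index()`, a character trie over the variants. `fuzzy_lookup()`
propagates one Levenshtein row per trie edge and prunes a branch as soon as
the row minimum exceeds the bound, returning every entry within `max_ed`
edits with its exact distance, sorted by distance then entry. The default
bound is 1 — with a dictionary that already contains the common misspellings,
distance 1 recovers the long tail — and the implementation warns above 2,
where trie search costs grow steeply. Equal-distance ties at annotation time
resolve to the lexicographically first canonical name and are counted in the
run summary; proper disambiguation is out of scope.

## The misspelling simulator

No clinical corpus ships with the package; `make_benchmark()` generates the
study conditions instead. Per drug it draws positives from three error
classes — 50 % typographic (edit budget 1 with probability 0.7, else 2;
observed misspelling lists are dominated by single-edit errors), 30 %
phonetic (one homophone-class substitution, applied only in contexts where
the rule table makes the substitution an exact homophone, so
`phonetic_similarity` is exactly 1), 20 % concatenation (the drug name run
together with a short function word, `por`/`para`/`ate`) — and negatives
from other drug names, a packaged lexicon of common clinical-note filler
words, and verbal derivatives of the drug itself (`glicosizando`-style,
emulating nouns turned into verbs). Documents embedding every positive (and
every derivative decoy) at known 0-based half-open offsets are emitted
alongside, so annotation can be scored span-exactly. Everything is a pure
function of the seed.

What the simulator does *not* model: keyboard-layout-specific substitution
probabilities (substitutions are uniform over the alphabet), Spanish-
interference patterns beyond the homophone classes, real prefix/suffix
families shared between drug names, and corpus token-frequency effects. A
high F1 on simulated benchmarks therefore demonstrates that the machinery
separates the encoded error classes from clean decoys — not a clinical
performance claim.

Near-homophone vowel swaps (`i`/`e`, `o`/`u` word-finally) exist as an
opt-in class (`include_near = TRUE`) and are labelled separately, because
they change the encoding and are excluded from the exact-homophone
invariant.

## Problem sizes and numerical conventions

The bundled tests and the acceptance script run at desk scale, chosen to
exercise every code path in well under their budgets: 20 drugs with 30
positives and 30 negatives each for tuning (about 1 200 labelled pairs
against the 10 302-point default grid), 1 000-word dictionaries with 200
queries for the trie/brute-force equivalence property, and 500 generated
words for the homophone-invariance sweep. Score comparisons in tests use an
absolute tolerance of 1e-9; threshold comparisons are inclusive (`>=`), as
the decision rule defines them.

## Known limitations

* The rule table is a pragmatic stand-in; words borrowed from other
  languages (e.g. `w`, `y`, internal `k`) get coarse mappings.
* Multi-word drug names are indexed but only single tokens are matched.
* A token similar to several drugs is resolved by distance then
  lexicographic order, not by context.
* The tuned thresholds depend on the candidate labelling and, through the
  phonetic metric, on the rule table; they are not directly comparable to
  thresholds tuned with a different phonetic encoder.
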