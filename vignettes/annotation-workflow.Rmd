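---
title: "Repository-driven semantic annotation: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repository-driven semantic annotation: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmsemantics)
```

## The annotation model

A data element on a clinical form follows the ISO/IEC 11179 split into a
concept domain (the item definition: "what is measured") and a value domain
(its code list: "which values are permissible"). Both can carry a semantic
annotation — here, a set of terminology concept codes. `odmsemantics`
represents an annotation as a **signature**: the code set deduplicated,
sorted ascending and joined with `+`. Two consequences follow:

* *Postcoordination is first-class.* When no single code captures a meaning,
  a combination (e.g. `C0005615+C0011008+C0027361`: birth + date in time +
  persons) is one signature, not three annotations.
* *Uniformity is decidable.* Two elements are uniformly coded exactly when
  their canonical strings are equal, regardless of the order in which codes
  were entered.

The central data structure is the **term index**: a map from
(normalized item name, signature) to a usage count and the (model, form)
references where that combination occurs. It is a surrogate for a curated
metadata repository: the count tells an annotator how established a code
choice is, the references let them review the context in which it was made
(`form_context()`).

The workflow itself is semi-automatic by design. `suggest()` proposes;
a human decides (`apply_decisions()` consumes a decisions table). The
package never auto-commits a vocabulary-origin suggestion, because
automated coding of clinical items is not reliable enough to go unreviewed,
and the whole value of the index lies in its curation. A `skip` action
exists because some concepts genuinely have no suitable code yet; skipped
targets are listed in the report rather than silently dropped.

### Why re-use first?

Large terminologies offer several plausible codes for many elements
(two for height, three for serum creatinine in the shipped vocabulary
alone). Which one is chosen matters less than that *the same one* is always
chosen. `suggest()` therefore ranks curated repository entries strictly
before vocabulary hits, regardless of raw string similarity: once a code
choice exists in the index, every later synonymous item inherits it. The
`annotate_corpus()` policy simulation makes this mechanism measurable —
`"reuse_first"` converges to one variant per concept cluster, while
`"independent"` (each model coded straight from the vocabulary, with the
candidate choice varying by model) manufactures exactly the coding variants
the workflow is meant to prevent.

## Name matching

Item names are noisy: case, punctuation, diacritics and token order vary
freely across forms. Matching happens on normalized names — lowercase,
diacritics transliterated through a fixed table (so results do not depend on
the platform's iconv), punctuation to spaces, whitespace collapsed — and
similarity is

$$s(a, b) = \max\!\left(J(a, b),\; 1 - \frac{\mathrm{lev}(a, b)}{\max(|a|, |b|)}\right)$$

with $J$ the Jaccard similarity of token sets and $\mathrm{lev}$ the
Levenshtein distance. The Jaccard part makes token reordering free
("Marker, Serum" matches "serum marker" at 1.0); the Levenshtein part
covers small spelling edits that token sets miss. Both components lie in
[0, 1], the measure is symmetric, equal strings (including two empty
strings) score 1, and for mixed cases the larger component wins — e.g.
`s("body weight", "weight")` is `max(1/2, 1 − 5/11) = 6/11`. The measure is
deterministic and explainable, which matters more here than linguistic
sophistication: an annotator shown a ranked list should be able to see why
each candidate is on it.

## Tunable parameters

All workflow knobs live in `annotation_config()`:

| Parameter | Default | Meaning |
|---|---|---|
| `similarity_threshold` | 0.6 | minimum $s$ for a repository suggestion; over half the tokens or characters must agree. Lower values recall more, at the cost of cross-concept noise (two-token names sharing one token score 1/3 by Jaccard but can exceed 0.6 by edit distance). |
| `suggestion_limit` | 20 | suggestions per target; keeps review lists readable. Vocabulary hits only fill the remainder below the limit. |
| `alias_context` | `"UMLS"` | the ODM `Alias` `Context` string that marks an alias as a semantic annotation. ODM 1.3's `Alias` is the standard extension point for terminology bindings; the exact context label used by any given repository is a convention, so it is a setting rather than a constant. |
| `count_codelist_entries` | `TRUE` | whether annotated code-list entries count as index contributions and annotation targets. Value domains carry meaning (a blood-pressure-location code list's "left arm" deserves a code as much as the item does), so they are counted by default; the toggle exists because repositories differ on this. |

Two further conventions are fixed rather than tunable:

* *Canonical code order* is ascending lexicographic. Any deterministic
  order would do; lexicographic needs no external information.
* *`set_annotation()` replaces* rather than merges. The workflow's human
  decision is authoritative; merging would silently manufacture
  postcoordinations nobody chose.

## ODM dialect and degenerate inputs

The reader/writer covers a documented metadata-only subset of ODM 1.3:
`Study`/`MetaDataVersion`, `FormDef`, `ItemGroupDef`, `ItemDef`
(description, question, range checks, measurement-unit reference, code-list
reference), `CodeList` with decoded entries, and `Alias`. Clinical-data
sections are out of scope and not preserved. Multilingual question text
keeps the first translation plus its language tag; no language logic is
attempted. Serialization is deterministic — fixed creation timestamp,
element order following model order, one `Alias` per code in canonical
order — so repeated writes are byte-identical and fixture regeneration is
reproducible.

Degenerate inputs have defined behaviour rather than undefined edges:
a file with no `ItemDef` is an `empty_model` error (there is nothing to
annotate); dangling OID references are an `integrity` error naming the
reference; structural problems below that level (range inversion, duplicate
coded values, non-canonical signatures) are *data* returned by
`validate_model()`, since an annotator may need to load an imperfect model
to fix it. Code-list entries, which have no OID in ODM, are addressed by the
pseudo-OID `<codelist_oid>/<coded_value>`, split at the first `/`.

Index bookkeeping: one annotated item definition counts once, even if
referenced from several forms; the recorded reference is the first
containing form in model order, chosen for determinism. Per-model
contributions are stored as (model, form, n) triples, so re-submitting an
edited model first retracts its entire previous contribution — the index
after any sequence of updates equals a from-scratch rebuild, a property the
test suite asserts directly. Ties in ranking are always broken
deterministically: count descending, then canonical signature ascending,
then name.

## What the synthetic data emulates — and what it does not

`make_table1_fixture()` encodes a five-element annotation profile with
realistic proportions: one uniformly coded element (body weight, 86
occurrences of one signature) and four elements with two or three coding
variants, including a 55/30 split between a precoordinated and a
postcoordinated date-of-birth annotation — 303 annotated occurrences in
total, spread round-robin over ten small models so the incremental update
and retraction paths are exercised rather than one bulk insert.

`make_synonym_corpus()` generates the controlled experiment for the policy
comparison: `n_clusters` concepts, each with a two-token base name, several
synonymous vocabulary codes whose preferred terms all contain the base
tokens, and surface name variants of the kinds real forms exhibit (case
changes, hyphenation, comma-inverted token order, stray punctuation). The
defaults used in the test suite and the acceptance script are 5 clusters ×
10 models × 3 codes — small enough to run in seconds, large enough that
every cluster sees several name variants and both parities of the
independent-coding chooser.

What the generators do *not* emulate: homonyms (the same surface name
meaning different things on different forms — the corpus guarantees name
clusters are semantically clean), multilingual names, misspellings beyond
punctuation noise, annotation errors by the simulated annotator, and
repository scale (hundreds of thousands of terms). Passing tests therefore
show that the mechanism works — re-use propagates one code choice per
concept — not that a real annotator facing homonyms and a four-million-term
metathesaurus will always pick the right cluster. In particular, with a 0.6
threshold a sufficiently similar name from a *different* concept can attract
a repository suggestion; context review by the human expert is the intended
safeguard, not string similarity.

## Known limitations

* Concept identity for the uniformity analyzer is an explicit
  label-to-names map supplied by the analyst. Automating it would amount to
  solving the matching problem the workflow exists to curate, so no
  automatic grouping is attempted; a name matching two labels is an error,
  not a guess.
* The vocabulary is a flat table: no semantic-network relations, no
  subsumption (an atrial-fibrillation item is not recognized as a cardiac
  arrhythmia), no maximum-specificity guidance. These are curation policy,
  out of scope for the data structures here.
* Two externally sourced per-element statistics sometimes reported alongside
  variant counts — the number of matching codes in a full terminology
  release and browser hit counts — depend on licensed resources and are
  treated as optional external metadata, never computed.
* The index is single-user and in-memory with JSON-lines persistence;
  concurrency control and database backends are out of scope.

```{r example}
corpus <- make_table1_fixture()
rows <- group_elements(corpus, table1_label_map())
summarize_uniformity(rows)

syn <- make_synonym_corpus(5, 10, 3, seed = 1)
res <- annotate_corpus(syn$corpus, syn$vocab, policy = "reuse_first")
vapply(group_elements(res$corpus, synonym_label_map(syn$truth, syn$corpus)),
       `[[`, integer(1), "variant_count")
```
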