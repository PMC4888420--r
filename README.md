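# odmsemantics

Uniform semantic annotation of clinical data elements in CDISC ODM study
metadata.

## The problem

Clinical studies describe their data elements (items on case report forms:
"height", "date of birth", "serum creatinine", ...) in CDISC ODM 1.3 XML.
For data integration across studies and EHR systems, each element needs a
*semantic annotation* — a terminology concept code, typically a UMLS CUI
such as `C0005890` (Body Height) — so that software can decide whether two
items from different sources mean the same thing. Large terminologies do not
provide uniform coding: height alone can be coded `C0489786` or `C0005890`,
and "patient sex" versus "gender of patient" map to different CUIs. When
every site codes in isolation, the same concept ends up with several *coding
variants*, which defeats the point of annotating.

`odmsemantics` implements the repository-driven remedy: curated annotations
are collected in a **term index** keyed by (normalized item name, annotation
signature) with usage counts, and every new item is annotated **re-use
first** — codes already chosen for like-named items are proposed before any
fresh vocabulary lookup, and each finished model feeds back into the index.
An annotation signature is the canonical rendering of a code set
(deduplicated, sorted, `+`-joined, e.g. `C0005615+C0011008+C0027361` for a
postcoordinated "date of birth"), so uniformity is well defined even for
multi-code annotations.

Name matching uses `max(J, L)` where `J` is the token-set Jaccard similarity
and `L = 1 − levenshtein(a, b) / max(|a|, |b|)` over normalized names
(lowercase, diacritics folded, punctuation stripped); the default acceptance
threshold is 0.6.

The package provides:

* `read_odm()` / `write_odm()` — the ODM 1.3 metadata subset with
  annotations as `Alias` elements (one per code, `Context="UMLS"`),
* `build_index()` / `update_index()` / `lookup_exact()` / `form_context()` —
  the incremental term index,
* `search_similar()` / `suggest()` — fuzzy retrieval and re-use-first
  suggestion ranking, with fallback to a pluggable vocabulary TSV
  (`load_vocabulary()`, `find_concepts()`),
* `propose_all()` / `apply_decisions()` / `annotate_corpus()` — the
  human-in-the-loop batch workflow and policy simulations,
* `group_elements()` / `summarize_uniformity()` / `report_table()` — the
  uniformity analyzer (coding variants per data element),
* `make_table1_fixture()` / `make_synonym_corpus()` — synthetic corpora,
* `cmd_*()` functions and `inst/cli/odmtool.R` — a shell entry point.

## Worked example

A built-in corpus realizes the annotation profile of five common data
elements (303 annotated occurrences across 10 small models):

```r
library(odmsemantics)
corpus <- make_table1_fixture()
index  <- build_index(corpus)

lookup_exact(index, "Date of Birth")
#>            name                  signature count
#> 1 date of birth                   C0421451    55
#> 2 date of birth C0005615+C0011008+C0027361    30

suggest(index, make_toy_vocabulary(), "date-of-BIRTH")
#> Suggestions for 'date-of-BIRTH' (2)
#>  rank     origin                  signature similarity count example_names
#>     1 repository                   C0421451          1    55 date of birth
#>     2 repository C0005615+C0011008+C0027361          1    30 date of birth
```

The most-used curated signature is ranked first, so an annotator who accepts
the top suggestion perpetuates the majority code — that is the mechanism
that drives coding toward uniformity. The uniformity analyzer summarizes the
current state per data element:

```r
rows <- group_elements(corpus, table1_label_map())
print(rows)
#> Body weight: 86 occurrence(s), 1 variant(s)
#>   86x C0005910
#> Date of Birth: 85 occurrence(s), 2 variant(s)
#>   55x C0421451
#>   30x C0005615+C0011008+C0027361
#> Creatinine in Serum: 66 occurrence(s), 3 variant(s)
#>   44x C0201976
#>   13x C0010294
#>   9x C0201975
#> Platelets: 29 occurrence(s), 3 variant(s)
#>   13x C0005821
#>   12x C0942474
#>   4x C1287267
#> ALT: 37 occurrence(s), 2 variant(s)
#>   30x C0201836
#>   7x C0001899

summarize_uniformity(rows)[c("uniform_elements", "max_variant_count")]
#> $uniform_elements
#> [1] 1
#> $max_variant_count
#> [1] 3
```

Body weight is uniformly coded; the other four elements carry two or three
coding variants — the situation the re-use-first workflow is designed to
prevent. `annotate_corpus(..., policy = "reuse_first")` on a synthetic
synonym corpus converges to exactly one variant per concept, while
`policy = "independent"` (each model coded straight from the vocabulary)
produces variants; see the vignette in `vignettes/annotation-workflow.Rmd`.

The same steps run from a shell:

```sh
Rscript inst/cli/odmtool.R fixture --kind table1 --out fx
Rscript inst/cli/odmtool.R build-index --corpus fx --out index.jsonl
Rscript inst/cli/odmtool.R uniformity --corpus fx --labels fx/label_map.json --out report.tsv
```

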