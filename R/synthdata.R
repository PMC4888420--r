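#' Built-in demonstration vocabulary
#'
#' A 20-concept vocabulary covering the worked examples shipped with the
#' package: anthropometry (body height/weight), demographics (date of birth,
#' patient sex/gender), laboratory measurements (serum creatinine, platelets,
#' alanine aminotransferase), tumour size and antidementia drugs. Several
#' concept pairs are deliberate near-synonyms with distinct codes (e.g. two
#' codes for height, two for antidementia medication, three creatinine
#' variants) — exactly the situation in which independent annotators produce
#' coding variants and curated re-use is needed for uniformity. Semantic
#' types are included where established; otherwise `"(unspecified)"`.
#'
#' @return an `odm_vocabulary` with 20 concepts.
#' @export
make_toy_vocabulary <- function() {
  recs <- list(
    concept_record("C0005890", "Body Height"),
    concept_record("C0489786", "Height"),
    concept_record("C0475440", "Tumor size"),
    concept_record("C0150831", "Patient Sex", semantic_type = "Organism Attribute T032"),
    concept_record("C1548569", "Gender of Patient", semantic_type = "Intellectual Product T170"),
    concept_record("C1276997", "Antidementia drug", semantic_type = "Pharmacologic Substance T121"),
    concept_record("C1531592", "Antidementia agents", semantic_type = "Pharmacologic Substance T121"),
    concept_record("C0421451", "Patient date of birth"),
    concept_record("C0011008", "Date in time"),
    concept_record("C0027361", "Persons"),
    concept_record("C0005615", "Birth"),
    concept_record("C0005910", "Body weight"),
    concept_record("C0201976", "Creatinine measurement, serum"),
    concept_record("C0010294", "Creatinine"),
    concept_record("C0201975", "Creatinine measurement"),
    concept_record("C0005821", "Blood Platelets"),
    concept_record("C0942474", "Platelets:NCnc:Pt:Bld:Qn"),
    concept_record("C1287267", "Finding of platelet count"),
    concept_record("C0201836", "Alanine aminotransferase measurement"),
    concept_record("C0001899", "Alanine Transaminase")
  )
  vocabulary(recs)
}

# The five-element worked example: per-variant occurrence counts of annotation
# signatures for common clinical data elements, as curated in a large public
# metadata repository. Used to exercise indexing, ranking and the uniformity
# analyzer at realistic proportions.
table1_occurrences <- function() {
  data.frame(
    label = c("Body weight",
              "Date of Birth", "Date of Birth",
              "Creatinine in Serum", "Creatinine in Serum", "Creatinine in Serum",
              "Platelets", "Platelets", "Platelets",
              "ALT", "ALT"),
    signature = c("C0005910",
                  "C0421451", "C0005615+C0011008+C0027361",
                  "C0201976", "C0010294", "C0201975",
                  "C0005821", "C0942474", "C1287267",
                  "C0201836", "C0001899"),
    count = c(86L, 55L, 30L, 44L, 13L, 9L, 13L, 12L, 4L, 30L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Label map for the five-element demonstration corpus
#'
#' @return named list mapping element labels to the item names used in
#'   [make_table1_fixture()], suitable for [group_elements()].
#' @export
table1_label_map <- function() {
  list(
    "Body weight" = "Body weight",
    "Date of Birth" = "Date of Birth",
    "Creatinine in Serum" = "Creatinine in Serum",
    "Platelets" = "Platelets",
    "ALT" = "ALT"
  )
}

#' Five-element demonstration corpus
#'
#' Builds a corpus of minimal one-form models whose annotated items realize
#' exactly the occurrence counts of [table1_occurrences()]: 86 body-weight
#' items all coded C0005910 (uniform), date of birth split 55/30 between a
#' precoordinated code and a three-code postcoordination, three creatinine
#' variants (44/13/9), three platelet variants (13/12/4) and two ALT variants
#' (30/7) — 303 annotated occurrences in total. Occurrences are distributed
#' round-robin over `n_models` small models rather than one big model, so
#' incremental index update and retraction paths see realistic input.
#'
#' @param n_models number of models to spread occurrences over.
#' @return list of [odm_model] objects.
#' @export
make_table1_fixture <- function(n_models = 10L) {
  occ <- table1_occurrences()
  inst_label <- rep(occ$label, occ$count)
  inst_sig <- rep(occ$signature, occ$count)
  inst_model <- ((seq_along(inst_label) - 1L) %% n_models) + 1L

  lapply(seq_len(n_models), function(m) {
    sel <- inst_model == m
    labs <- inst_label[sel]
    sigs <- inst_sig[sel]
    items <- lapply(seq_along(labs), function(k) {
      odm_item(sprintf("IT.%d.%d", m, k), labs[k],
               data_type = if (labs[k] == "Date of Birth") "date" else "float",
               annotation = sigs[k])
    })
    oids <- vapply(items, `[[`, "", "oid")
    odm_model(
      model_id = sprintf("T1M%03d", m),
      study_name = sprintf("Synthetic element collection %d", m),
      forms = list(odm_form(sprintf("F.%d", m), sprintf("Form %d", m),
                            group_refs = sprintf("G.%d", m))),
      groups = list(odm_group(sprintf("G.%d", m), "Data elements", item_refs = oids)),
      items = items
    )
  })
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.corpus_words1 <- c("serum", "plasma", "cardiac", "hepatic", "renal",
                    "neural", "gastric", "pulmonary", "ocular", "dermal")
.corpus_words2 <- c("marker", "index", "score", "ratio", "level",
                    "volume", "count", "rate", "span", "grade")

#' Synthetic synonym-cluster corpus
#'
#' Generates the controlled setting for studying annotation policy: a corpus
#' of unannotated models, a vocabulary offering several synonymous codes per
#' concept, and the ground truth linking them. Each of `n_clusters` concepts
#' gets a two-token base name, `codes_per_cluster` synonymous vocabulary
#' codes (all of whose preferred terms contain the base tokens), and a pool
#' of surface name variants (case changes, punctuation, token reordering) of
#' the kind real forms exhibit. Every model contains one item per cluster
#' with a randomly drawn name variant, so each cluster occurs
#' `models_per_cluster` times. Generation is fully reproducible from `seed`
#' and leaves the caller's RNG state untouched.
#'
#' @param n_clusters number of concept clusters (<= 100).
#' @param models_per_cluster number of models (each model holds one item per
#'   cluster).
#' @param codes_per_cluster synonymous codes offered per cluster.
#' @param seed integer seed.
#' @return list with `corpus` (list of [odm_model]), `vocab`
#'   (`odm_vocabulary`), `truth` (data frame: `cluster`, `base_name`,
#'   `codes` as `+`-joined string).
#' @export
make_synonym_corpus <- function(n_clusters = 5L, models_per_cluster = 10L,
                                codes_per_cluster = 3L, seed = 1L) {
  stopifnot(n_clusters >= 1, models_per_cluster >= 1, codes_per_cluster >= 1,
            n_clusters <= length(.corpus_words1) * length(.corpus_words2))
  with_local_seed(seed, {
    w1 <- rep(.corpus_words1, each = length(.corpus_words2))
    w2 <- rep(.corpus_words2, times = length(.corpus_words1))
    pick <- sample.int(length(w1), n_clusters)
    base <- paste(w1[pick], w2[pick])

    term_suffix <- c("", " measurement", " finding", " value", " observation",
                     " result", " assessment", " determination", " reading")
    stopifnot(codes_per_cluster <= length(term_suffix))
    recs <- list()
    codes <- matrix("", n_clusters, codes_per_cluster)
    for (i in seq_len(n_clusters)) {
      for (j in seq_len(codes_per_cluster)) {
        code <- sprintf("C9%03d%03d", i, j)
        codes[i, j] <- code
        pref <- paste0(tools::toTitleCase(base[i]), term_suffix[j])
        recs[[length(recs) + 1L]] <- concept_record(code, pref,
                                                    semantic_type = "(synthetic)")
      }
    }

    variants_of <- function(b) {
      toks <- strsplit(b, " ", fixed = TRUE)[[1]]
      unique(c(
        b,
        tools::toTitleCase(b),
        toupper(b),
        paste(rev(toks), collapse = ", "),      # "Marker, Serum" style
        paste(toks, collapse = "-"),            # hyphenated
        paste0(tools::toTitleCase(b), " :")     # stray punctuation
      ))
    }

    corpus <- lapply(seq_len(models_per_cluster), function(m) {
      items <- lapply(seq_len(n_clusters), function(i) {
        v <- variants_of(base[i])
        odm_item(sprintf("IT.%d.%d", m, i), sample(v, 1L), data_type = "float")
      })
      oids <- vapply(items, `[[`, "", "oid")
      odm_model(
        model_id = sprintf("SYN%03d", m),
        study_name = sprintf("Synthetic synonym study %d", m),
        forms = list(odm_form(sprintf("F.%d", m), sprintf("Form %d", m),
                              group_refs = sprintf("G.%d", m))),
        groups = list(odm_group(sprintf("G.%d", m), "Cluster items", item_refs = oids)),
        items = items
      )
    })

    truth <- data.frame(
      cluster = sprintf("cluster%02d", seq_len(n_clusters)),
      base_name = base,
      codes = apply(codes, 1L, paste, collapse = "+"),
      stringsAsFactors = FALSE
    )
    list(corpus = corpus, vocab = vocabulary(recs), truth = truth)
  })
}

#' Label map for a synonym corpus
#'
#' Maps each cluster of a [make_synonym_corpus()] result to all surface name
#' variants its items can carry, for use with [group_elements()].
#'
#' @param truth the `truth` data frame from [make_synonym_corpus()].
#' @param corpus the corpus from the same call.
#' @return named list label -> character vector of item names.
#' @export
synonym_label_map <- function(truth, corpus) {
  all_names <- unlist(lapply(corpus, function(m)
    vapply(m$items, `[[`, "", "name")))
  out <- lapply(seq_len(nrow(truth)), function(i) {
    base_toks <- sort(strsplit(normalize_name(truth$base_name[i]), " ")[[1]])
    unique(all_names[vapply(all_names, function(nm) {
      toks <- strsplit(normalize_name(nm), " ")[[1]]
      all(base_toks %in% toks)
    }, logical(1))])
  })
  names(out) <- truth$cluster
  out
}

#' Write a fixture corpus to disk
#'
#' Materializes a generated fixture as self-contained text artifacts: one ODM
#' XML file per model, `vocabulary.tsv`, and `label_map.json`. Regenerating
#' with the same arguments is byte-identical.
#'
#' @param kind `"table1"` (five-element demonstration corpus) or `"synonym"`.
#' @param out_dir output directory (created if needed).
#' @param seed seed for `"synonym"` generation.
#' @return invisibly, the vector of files written.
#' @export
write_fixture_dir <- function(kind = c("table1", "synonym"), out_dir, seed = 1L) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "table1") {
    corpus <- make_table1_fixture()
    vocab <- make_toy_vocabulary()
    label_map <- table1_label_map()
  } else {
    syn <- make_synonym_corpus(seed = seed)
    corpus <- syn$corpus
    vocab <- syn$vocab
    label_map <- synonym_label_map(syn$truth, syn$corpus)
  }
  files <- character(0)
  for (m in corpus) {
    f <- file.path(out_dir, paste0(m$model_id, ".xml"))
    write_odm(m, path = f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "vocabulary.tsv")
  save_vocabulary(vocab, f)
  files <- c(files, f)
  f <- file.path(out_dir, "label_map.json")
  writeLines(as.character(jsonlite::toJSON(label_map)), f, useBytes = TRUE)
  files <- c(files, f)
  invisible(files)
}
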