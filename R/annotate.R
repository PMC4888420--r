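#' Annotation workflow configuration
#'
#' Bundles the tunable parameters of the annotation workflow. The defaults
#' are deliberately conservative: a similarity threshold of 0.6 keeps
#' suggestions explainable (over half of the tokens or characters agree), a
#' limit of 20 keeps review lists readable, `"UMLS"` is the `Alias` context
#' label used for annotations in the ODM XML, and code-list entries are
#' counted as annotation targets because value domains carry meaning too.
#'
#' @param similarity_threshold minimum name similarity in \[0, 1\].
#' @param suggestion_limit maximum suggestions per target (>= 1).
#' @param alias_context ODM `Alias` context string marking annotations.
#' @param count_codelist_entries index/propose code-list entries as targets?
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(similarity_threshold = 0.6,
                              suggestion_limit = 20L,
                              alias_context = "UMLS",
                              count_codelist_entries = TRUE) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            suggestion_limit >= 1)
  structure(list(similarity_threshold = similarity_threshold,
                 suggestion_limit = as.integer(suggestion_limit),
                 alias_context = alias_context,
                 count_codelist_entries = isTRUE(count_codelist_entries)),
            class = "annotation_config")
}

#' Propose suggestions for every unannotated target
#'
#' Runs [suggest()] for each unannotated item and (optionally) code-list
#' entry of the model; already-annotated targets are excluded. This is the
#' machine half of the semi-automatic workflow — a human decision is still
#' required to commit any suggestion.
#'
#' @param model an [odm_model].
#' @param index a [term_index].
#' @param vocab an `odm_vocabulary`.
#' @param config an [annotation_config()].
#' @return named list mapping target OID to a `suggestion_list`.
#' @export
propose_all <- function(model, index, vocab, config = annotation_config()) {
  targets <- unannotated_targets(model)
  if (!config$count_codelist_entries) {
    targets <- targets[targets %in% names(model$items)]
  }
  out <- lapply(targets, function(oid) {
    suggest(index, vocab, target_name(model, oid),
            threshold = config$similarity_threshold,
            limit = config$suggestion_limit)
  })
  names(out) <- targets
  out
}

#' Read / write a batch decisions table
#'
#' The decisions TSV captures the human expert's rulings, one per line:
#' `target_oid \t action \t codes \t note`, with `action` one of `reuse`
#' (take a curated signature from the index), `vocabulary` (take a fallback
#' code), `postcoordinate` (combine several codes), or `skip` (no suitable
#' code exists yet). `codes` is a `+`-joined code list, empty for `skip`.
#'
#' @param path TSV file; `load` alternatively accepts literal `text`.
#' @param text literal TSV text.
#' @return `read_decisions()` returns a data frame with columns `target_oid`,
#'   `action`, `codes`, `note`.
#' @export
read_decisions <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(target_oid = character(0), action = character(0),
                      codes = character(0), note = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("target_oid", "action", "codes"))) {
    odm_error("format", "decisions TSV must start with header: target_oid, action, codes, note")
  }
  if (length(lines) == 1L) return(empty)
  cells <- lapply(strsplit(lines[-1L], "\t", fixed = TRUE), function(x) {
    length(x) <- 4L
    x
  })
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- c("target_oid", "action", "codes", "note")
  df$codes[is.na(df$codes)] <- ""
  df$note[is.na(df$note)] <- ""
  bad <- !df$action %in% c("reuse", "vocabulary", "postcoordinate", "skip")
  if (any(bad)) {
    odm_error("format", sprintf("unknown action %s", sQuote(df$action[bad][1L])))
  }
  if (any(df$action != "skip" & !nzchar(df$codes))) {
    odm_error("format", "non-skip decisions must carry at least one code")
  }
  df
}

#' @rdname read_decisions
#' @param decisions data frame as returned by `read_decisions()`.
#' @export
write_decisions <- function(decisions, path = NULL) {
  lines <- c("target_oid\taction\tcodes\tnote",
             sprintf("%s\t%s\t%s\t%s", decisions$target_oid, decisions$action,
                     decisions$codes, decisions$note))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(paste(lines, collapse = "\n")))
  }
  paste(lines, collapse = "\n")
}

#' Apply a batch of annotation decisions
#'
#' Each non-skip decision sets the canonicalized signature on its target
#' (replacing any previous one); skipped targets stay unannotated and are
#' listed in the report, because some concepts simply have no suitable code
#' yet. Afterwards the term index is refreshed with the modified model via
#' [update_index()], so the new annotations are available for re-use by the
#' very next model — the feedback loop that drives uniform coding. A `reuse`
#' decision whose signature is absent from the index is applied but recorded
#' as a warning in the report (it is curation drift, not an error).
#'
#' @param model an [odm_model].
#' @param decisions data frame from [read_decisions()].
#' @param index a [term_index].
#' @param vocab an `odm_vocabulary` (strict code check for
#'   vocabulary/postcoordinate actions).
#' @param config an [annotation_config()].
#' @return list with elements `model` (annotated), `index` (updated),
#'   `report` (class `annotation_report`: action counts, coverage
#'   before/after, new index entries, skipped targets, warnings).
#' @export
apply_decisions <- function(model, decisions, index, vocab,
                            config = annotation_config()) {
  cov_before <- coverage(model)
  actions <- c(reuse = 0L, vocabulary = 0L, postcoordinate = 0L, skip = 0L)
  warnings <- character(0)
  skipped <- character(0)
  known_targets <- c(names(model$items),
                     unlist(lapply(model$codelists, function(cl)
                       entry_oid(cl$oid, cl$entries$coded_value))))
  entries_before <- index_entries(index)
  for (i in seq_len(nrow(decisions))) {
    oid <- decisions$target_oid[i]
    action <- decisions$action[i]
    if (!oid %in% known_targets) {
      odm_error("lookup", sprintf("decision %d targets unknown OID %s", i, sQuote(oid)))
    }
    if (action == "skip") {
      actions[["skip"]] <- actions[["skip"]] + 1L
      skipped <- c(skipped, oid)
      next
    }
    codes <- signature_codes(decisions$codes[i])
    sig <- make_signature(vocab, codes,
                          strict = action %in% c("vocabulary", "postcoordinate"))
    if (action == "reuse") {
      known_sigs <- index_entries(index)$signature
      if (!sig %in% known_sigs) {
        warnings <- c(warnings, sprintf(
          "reuse decision for %s: signature %s not found in index", oid, sig))
      }
    }
    model <- set_annotation(model, oid, sig)
    actions[[action]] <- actions[[action]] + 1L
  }
  index <- update_index(index, model)
  entries_after <- index_entries(index)
  new_keys <- setdiff(index_key(entries_after$name, entries_after$signature),
                      index_key(entries_before$name, entries_before$signature))
  report <- structure(list(
    actions = actions,
    coverage_before = cov_before,
    coverage_after = coverage(model),
    new_index_entries = length(new_keys),
    skipped_targets = skipped,
    warnings = warnings
  ), class = "annotation_report")
  list(model = model, index = index, report = report)
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> reuse %d, vocabulary %d, postcoordinate %d, skip %d\n",
              x$actions[["reuse"]], x$actions[["vocabulary"]],
              x$actions[["postcoordinate"]], x$actions[["skip"]]))
  cat(sprintf("  coverage %.3f -> %.3f; %d new index entries; %d warning(s)\n",
              x$coverage_before, x$coverage_after, x$new_index_entries,
              length(x$warnings)))
  invisible(x)
}

#' Annotate a corpus under a fixed policy
#'
#' Simulates an annotator working through a corpus model by model, useful for
#' studying how annotation policy affects coding uniformity:
#'
#' * `"reuse_first"` — for every unannotated target, take the top repository
#'   suggestion when one exists, otherwise the top vocabulary suggestion, and
#'   feed each finished model back into the index. This is the workflow's
#'   intended policy: after the first model fixes a code choice, every later
#'   synonymous item inherits it, so coding converges to one variant per
#'   concept.
#' * `"independent"` — annotate every model straight from the vocabulary,
#'   never consulting the index. `vocab_chooser(model_number, n_candidates)`
#'   picks which candidate code each model uses (default: alternate between
#'   the two best by model parity), emulating sites that code in isolation
#'   and thereby produce coding variants.
#'
#' @param corpus list of [odm_model] objects (annotations are overwritten).
#' @param vocab an `odm_vocabulary`.
#' @param policy `"reuse_first"` or `"independent"`.
#' @param index starting [term_index] (reuse_first only).
#' @param config an [annotation_config()].
#' @param vocab_chooser function(model_number, n_candidates) -> index in
#'   1..n_candidates (independent policy only).
#' @return list with `corpus` (annotated models) and `index`.
#' @export
annotate_corpus <- function(corpus, vocab,
                            policy = c("reuse_first", "independent"),
                            index = term_index(),
                            config = annotation_config(),
                            vocab_chooser = function(m, k) ((m - 1L) %% min(2L, k)) + 1L) {
  policy <- match.arg(policy)
  out <- vector("list", length(corpus))
  for (m in seq_along(corpus)) {
    model <- corpus[[m]]
    if (policy == "reuse_first") {
      for (oid in unannotated_targets(model)) {
        sl <- suggest(index, vocab, target_name(model, oid),
                      threshold = config$similarity_threshold,
                      limit = config$suggestion_limit)
        if (nrow(sl$suggestions) > 0L) {
          model <- set_annotation(model, oid, sl$suggestions$signature[1L])
        }
        # keep intra-model choices visible to later items of the same model
        index <- update_index(index, model)
      }
    } else {
      for (oid in unannotated_targets(model)) {
        cand <- find_concepts(vocab, target_name(model, oid))
        if (nrow(cand) > 0L) {
          pick <- vocab_chooser(m, nrow(cand))
          model <- set_annotation(model, oid, cand$code[pick])
        }
      }
    }
    if (policy == "reuse_first") index <- update_index(index, model)
    out[[m]] <- model
  }
  if (policy == "independent") index <- build_index(out)
  list(corpus = out, index = index)
}
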