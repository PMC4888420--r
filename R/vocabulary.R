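#' Concept vocabulary (UMLS-style fallback table)
#'
#' A flat concept table standing in for a licensed metathesaurus: one record
#' per concept code with a preferred term, optional synonyms and a semantic
#' type. It serves as the fallback when no curated annotation can be re-used
#' from the term index. No hierarchy or semantic-network relations are
#' modelled — code re-use, not ontology reasoning, is what drives uniform
#' annotation here. Any table with the same four-column TSV contract can be
#' plugged in (including a real UMLS extract).
#'
#' @param records list of records, each
#'   `list(code, preferred_term, synonyms, semantic_type)`.
#' @return object of class `odm_vocabulary`.
#' @seealso [load_vocabulary()], [find_concepts()], [get_concept()],
#'   [make_signature()]
#' @export
vocabulary <- function(records = list()) {
  names(records) <- vapply(records, `[[`, "", "code")
  records <- records[order(names(records), method = "radix")]
  structure(list(records = records), class = "odm_vocabulary")
}

concept_record <- function(code, preferred_term, synonyms = character(),
                           semantic_type = "(unspecified)") {
  check_codes(code)
  if (!nzchar(preferred_term)) {
    odm_error("format", sprintf("concept %s has an empty preferred term", code))
  }
  list(code = code, preferred_term = preferred_term,
       synonyms = as.character(synonyms), semantic_type = semantic_type)
}

#' Load / save a vocabulary TSV
#'
#' The table has a header row and four columns:
#' `code \t term \t term_type \t semantic_type`, with `term_type` either
#' `preferred` or `synonym`. Each code must have exactly one preferred term;
#' duplicate (code, term) rows are rejected. `load_vocabulary(save_vocabulary(v))`
#' reproduces `v` exactly.
#'
#' @param path TSV file; for `load_vocabulary` alternatively `text` with the
#'   literal table.
#' @param text literal TSV text (used when `path` is `NULL`).
#' @return `load_vocabulary()` returns an `odm_vocabulary`.
#' @export
load_vocabulary <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(vocabulary())
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:4], c("code", "term", "term_type", "semantic_type"))) {
    odm_error("format", "vocabulary TSV must start with header: code, term, term_type, semantic_type")
  }
  if (length(lines) == 1L) return(vocabulary())
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 4L)
  if (length(bad) > 0L) {
    odm_error("format", sprintf("vocabulary line %d does not have 4 columns", bad[1L] + 1L))
  }
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- c("code", "term", "term_type", "semantic_type")
  if (!all(df$term_type %in% c("preferred", "synonym"))) {
    odm_error("format", "term_type must be 'preferred' or 'synonym'")
  }
  if (anyDuplicated(df[c("code", "term")])) {
    odm_error("format", "duplicate (code, term) row in vocabulary")
  }
  records <- lapply(split(df, df$code), function(g) {
    pref <- g$term[g$term_type == "preferred"]
    if (length(pref) != 1L) {
      odm_error("format", sprintf("code %s has %d preferred terms (need exactly 1)",
                                  g$code[1L], length(pref)))
    }
    concept_record(g$code[1L], pref,
                   synonyms = sort(g$term[g$term_type == "synonym"], method = "radix"),
                   semantic_type = g$semantic_type[1L])
  })
  vocabulary(unname(records))
}

#' @rdname load_vocabulary
#' @param vocab an `odm_vocabulary`.
#' @export
save_vocabulary <- function(vocab, path = NULL) {
  rows <- unlist(lapply(vocab$records, function(r) {
    c(paste(r$code, r$preferred_term, "preferred", r$semantic_type, sep = "\t"),
      if (length(r$synonyms) > 0L)
        paste(r$code, r$synonyms, "synonym", r$semantic_type, sep = "\t"))
  }), use.names = FALSE)
  lines <- c("code\tterm\tterm_type\tsemantic_type", rows)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(paste(lines, collapse = "\n")))
  }
  paste(lines, collapse = "\n")
}

#' Search concepts by term
#'
#' Token-containment search: a record matches when every normalized query
#' token occurs among the tokens of its preferred term or of any synonym.
#' Results are ranked by similarity of the preferred term to the query
#' (descending), ties broken by code ascending, so output is deterministic
#' and independent of record insertion order.
#'
#' @param vocab an `odm_vocabulary`.
#' @param query free-text query (normalized internally).
#' @return data frame with columns `code`, `preferred_term`, `semantic_type`,
#'   `similarity`.
#' @export
find_concepts <- function(vocab, query) {
  q <- normalize_name(query)
  q_tokens <- strsplit(q, " ", fixed = TRUE)[[1]]
  q_tokens <- q_tokens[nzchar(q_tokens)]
  hits <- Filter(function(r) {
    terms <- normalize_name(c(r$preferred_term, r$synonyms))
    any(vapply(strsplit(terms, " ", fixed = TRUE),
               function(tok) all(q_tokens %in% tok), logical(1)))
  }, vocab$records)
  df <- data.frame(
    code = vapply(hits, `[[`, "", "code"),
    preferred_term = vapply(hits, `[[`, "", "preferred_term"),
    semantic_type = vapply(hits, `[[`, "", "semantic_type"),
    stringsAsFactors = FALSE
  )
  df$similarity <- if (nrow(df) == 0L) numeric(0) else {
    similarity_to(q, normalize_name(df$preferred_term))
  }
  df <- df[order(-df$similarity, df$code, method = "radix"), , drop = FALSE]
  row.names(df) <- NULL
  df
}

#' Retrieve one concept record
#'
#' @param vocab an `odm_vocabulary`.
#' @param code concept code.
#' @return the record `list(code, preferred_term, synonyms, semantic_type)`.
#' @export
get_concept <- function(vocab, code) {
  r <- vocab$records[[code]]
  if (is.null(r)) {
    odm_error("unknown_code", sprintf("concept code %s not in vocabulary", sQuote(code)))
  }
  r
}

#' Build a canonical signature, optionally vocabulary-checked
#'
#' Canonicalizes a set of concept codes into an annotation signature
#' (duplicates collapse, codes sorted, joined with `"+"`). Postcoordination
#' is simply passing more than one code. With `strict = TRUE` every code must
#' exist in the vocabulary.
#'
#' @param vocab an `odm_vocabulary` (only consulted when `strict`).
#' @param codes non-empty character vector of concept codes.
#' @param strict require all codes to be known to the vocabulary.
#' @return canonical signature string.
#' @export
make_signature <- function(vocab, codes, strict = FALSE) {
  if (length(codes) == 0L) {
    odm_error("empty_signature", "cannot build a signature from zero codes")
  }
  if (strict) for (code in codes) get_concept(vocab, code)
  canonical_signature(codes)
}

#' Human-readable terms for a signature's codes
#'
#' @param vocab an `odm_vocabulary`.
#' @param signature canonical signature string.
#' @return character vector of `"CODE term"` fragments in canonical order;
#'   codes missing from the vocabulary render as bare codes.
#' @export
signature_terms <- function(vocab, signature) {
  vapply(signature_codes(signature), function(code) {
    r <- vocab$records[[code]]
    if (is.null(r)) code else paste(code, r$preferred_term)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.odm_vocabulary <- function(x, ...) {
  cat(sprintf("<odm_vocabulary> %d concepts\n", length(x$records)))
  invisible(x)
}
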