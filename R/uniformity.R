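#' Group annotation occurrences per data element
#'
#' The uniformity analyzer: data elements are identified by an explicit
#' label-to-name-patterns map (automatic concept identity being exactly the
#' unsolved problem the annotation workflow addresses), and for every label
#' all matching annotated occurrences across the corpus are tallied per
#' annotation signature. One signature per element means uniform coding; more
#' signatures mean coding variants that will hinder data integration.
#'
#' @param corpus list of [odm_model] objects.
#' @param element_map named list: element label -> character vector of item
#'   names (matched by normalized-name equality). A normalized name may
#'   belong to at most one label.
#' @param count_codelist_entries include annotated code-list entries?
#' @return object of class `uniformity_report`: a list of rows, each with
#'   `element_label`, `variants` (data frame `signature`, `count`, sorted by
#'   count descending then signature), `total_occurrences`, `variant_count`,
#'   `unannotated_occurrences`.
#' @export
group_elements <- function(corpus, element_map, count_codelist_entries = TRUE) {
  labels <- names(element_map)
  pat_norm <- lapply(element_map, function(p) unique(normalize_name(p)))
  all_pats <- unlist(pat_norm, use.names = FALSE)
  dup <- unique(all_pats[duplicated(all_pats)])
  if (length(dup) > 0L) {
    odm_error("ambiguous_mapping", sprintf(
      "name pattern(s) mapped to more than one element label: %s",
      paste(sQuote(dup), collapse = ", ")))
  }
  label_of <- stats::setNames(rep(labels, lengths(pat_norm)), all_pats)

  occ <- lapply(corpus, function(m) {
    items <- data.frame(
      name = vapply(m$items, `[[`, "", "name"),
      signature = vapply(m$items, function(it)
        if (is.null(it$annotation)) NA_character_ else it$annotation, character(1)),
      stringsAsFactors = FALSE
    )
    entries <- if (count_codelist_entries) {
      do.call(rbind, lapply(m$codelists, function(cl)
        data.frame(name = cl$entries$decode, signature = cl$entries$annotation,
                   stringsAsFactors = FALSE)))
    }
    rbind(items, entries)
  })
  occ <- do.call(rbind, occ)
  if (is.null(occ)) {
    occ <- data.frame(name = character(0), signature = character(0),
                      stringsAsFactors = FALSE)
  }
  occ$label <- unname(label_of[normalize_name(occ$name)])

  rows <- lapply(labels, function(lab) {
    sub <- occ[!is.na(occ$label) & occ$label == lab, , drop = FALSE]
    ann <- sub$signature[!is.na(sub$signature)]
    variants <- if (length(ann) == 0L) {
      data.frame(signature = character(0), count = integer(0),
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(ann)
      v <- data.frame(signature = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
      v <- v[order(-v$count, v$signature, method = "radix"), , drop = FALSE]
      row.names(v) <- NULL
      v
    }
    list(element_label = lab, variants = variants,
         total_occurrences = sum(variants$count),
         variant_count = nrow(variants),
         unannotated_occurrences = sum(is.na(sub$signature)))
  })
  structure(rows, class = "uniformity_report")
}

#' Summarize a uniformity report
#'
#' @param rows a `uniformity_report` from [group_elements()].
#' @return list with `by_variant_count` (named integer vector: variant count
#'   -> number of elements), `uniform_elements` (elements with exactly one
#'   variant), `max_variant_count`, `n_elements`.
#' @export
summarize_uniformity <- function(rows) {
  vc <- vapply(rows, `[[`, integer(1), "variant_count")
  tab <- table(vc)
  list(
    by_variant_count = stats::setNames(as.integer(tab), names(tab)),
    uniform_elements = sum(vc == 1L),
    max_variant_count = if (length(vc) == 0L) 0L else max(vc),
    n_elements = length(vc)
  )
}

#' Render a uniformity report
#'
#' `format = "text"` mirrors the review presentation — one block per data
#' element with `"<count>x <signature> <terms>"` lines; `format = "tsv"`
#' emits a machine-readable table (`element_label \t total \t variant_count
#' \t unannotated \t variants`, variants as `;`-joined `"<count>x
#' <signature>"` fragments) that [parse_report_tsv()] re-parses to identical
#' rows.
#'
#' @param rows a `uniformity_report`.
#' @param format `"tsv"` or `"text"`.
#' @param vocab optional vocabulary used to append preferred terms in text
#'   format.
#' @return a single string.
#' @export
report_table <- function(rows, format = c("tsv", "text"), vocab = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c("element_label\ttotal\tvariant_count\tunannotated\tvariants",
               vapply(rows, function(r) {
                 frag <- sprintf("%dx %s", r$variants$count, r$variants$signature)
                 paste(r$element_label, r$total_occurrences, r$variant_count,
                       r$unannotated_occurrences, paste(frag, collapse = ";"),
                       sep = "\t")
               }, character(1)))
    return(paste(lines, collapse = "\n"))
  }
  blocks <- vapply(rows, function(r) {
    head <- sprintf("%s: %d occurrence(s), %d variant(s)",
                    r$element_label, r$total_occurrences, r$variant_count)
    lines <- vapply(seq_len(nrow(r$variants)), function(i) {
      sig <- r$variants$signature[i]
      terms <- if (is.null(vocab)) sig else paste(signature_terms(vocab, sig),
                                                  collapse = " ")
      sprintf("  %dx %s", r$variants$count[i], terms)
    }, character(1))
    paste(c(head, lines), collapse = "\n")
  }, character(1))
  paste(blocks, collapse = "\n")
}

#' @rdname report_table
#' @param text TSV text produced by `report_table(format = "tsv")`.
#' @export
parse_report_tsv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L ||
      !identical(lines[1L], "element_label\ttotal\tvariant_count\tunannotated\tvariants")) {
    odm_error("format", "not a uniformity report TSV (bad header)")
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(cells) <- 5L
    if (is.na(cells[1L])) {
      odm_error("format", sprintf("malformed report line %d", i))
    }
    variants <- if (is.na(cells[5L]) || !nzchar(cells[5L])) {
      data.frame(signature = character(0), count = integer(0),
                 stringsAsFactors = FALSE)
    } else {
      frags <- strsplit(cells[5L], ";", fixed = TRUE)[[1]]
      mt <- regmatches(frags, regexec("^([0-9]+)x (.+)$", frags))
      if (any(lengths(mt) != 3L)) {
        odm_error("format", sprintf("malformed variant fragment on line %d", i))
      }
      data.frame(signature = vapply(mt, `[[`, "", 3L),
                 count = as.integer(vapply(mt, `[[`, "", 2L)),
                 stringsAsFactors = FALSE)
    }
    list(element_label = cells[1L], variants = variants,
         total_occurrences = as.integer(cells[2L]),
         variant_count = as.integer(cells[3L]),
         unannotated_occurrences = as.integer(cells[4L]))
  })
  structure(rows, class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(report_table(x, format = "text"), "\n")
  invisible(x)
}
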