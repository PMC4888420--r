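#' Item-name normalization
#'
#' Folds an item name to the form used as the term-index key and for all
#' similarity comparisons: lowercase, diacritics transliterated to base
#' letters through a fixed table (so behaviour does not depend on the
#' platform's iconv), punctuation replaced by spaces, whitespace collapsed
#' and trimmed. The function is idempotent.
#'
#' The transliteration table maps Latin-1/Latin Extended letters to ASCII:
#' a-umlaut to "a", o-umlaut to "o", u-umlaut to "u", sharp s to "ss",
#' ae-ligature to "ae", o-slash to "o", accented vowels to their base vowel,
#' c-cedilla to "c", n-tilde to "n". Digraph alternates (e.g. "oe" for
#' o-umlaut) are deliberately not produced: one input, one output.
#'
#' @param x character vector of raw item names.
#' @return character vector of normalized names.
#' @examples
#' normalize_name("Height")
#' normalize_name("Größe (cm)")
#' @export
normalize_name <- function(x) {
  x <- tolower(as.character(x))
  # multi-character replacements first
  for (i in seq_along(.translit_multi)) {
    x <- gsub(names(.translit_multi)[i], .translit_multi[[i]], x, fixed = TRUE)
  }
  x <- chartr(paste(names(.translit_single), collapse = ""),
              paste(unlist(.translit_single), collapse = ""), x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

# \u escapes keep the source ASCII-only and locale-proof.
.translit_multi <- c("ss", "ae", "oe")
names(.translit_multi) <- c("\u00df", "\u00e6", "\u0153") # sharp-s, ae, oe ligatures

.translit_single <- c(
  "a", "o", "u",           # umlauts
  "a", "a", "a", "a", "a", # accented a
  "e", "e", "e", "e",
  "i", "i", "i", "i",
  "o", "o", "o", "o", "o",
  "u", "u", "u",
  "c", "n", "y"
)
names(.translit_single) <- c(
  "\u00e4", "\u00f6", "\u00fc",
  "\u00e1", "\u00e0", "\u00e2", "\u00e3", "\u00e5",
  "\u00e9", "\u00e8", "\u00ea", "\u00eb",
  "\u00ed", "\u00ec", "\u00ee", "\u00ef",
  "\u00f3", "\u00f2", "\u00f4", "\u00f5", "\u00f8",
  "\u00fa", "\u00f9", "\u00fb",
  "\u00e7", "\u00f1", "\u00fd"
)

#' Similarity between two normalized names
#'
#' Returns `max(J, L)` where `J` is the Jaccard similarity of the two token
#' sets and `L = 1 - levenshtein(a, b) / max(nchar(a), nchar(b))`. Combining
#' the two makes the measure robust both to token reordering ("Marker, Serum"
#' vs "serum marker") and to small spelling edits. Equal strings — including
#' two empty strings — score 1; the measure is symmetric and lies in [0, 1].
#' Inputs are expected to be already normalized (see [normalize_name()]).
#'
#' @param a,b normalized name strings (scalars).
#' @return a number in \[0, 1\].
#' @examples
#' name_similarity("height", "height")
#' name_similarity("body weight", "weight")
#' @export
name_similarity <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (identical(a, b)) return(1)
  ta <- strsplit(a, " ", fixed = TRUE)[[1]]
  tb <- strsplit(b, " ", fixed = TRUE)[[1]]
  ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
  u <- length(union(ta, tb))
  jac <- if (u == 0L) 1 else length(intersect(ta, tb)) / u
  lev <- 1 - utils::adist(a, b)[1L, 1L] / max(nchar(a), nchar(b))
  max(jac, lev)
}

# Vectorized similarity of one query against many candidate names.
similarity_to <- function(query, names) {
  vapply(names, name_similarity, numeric(1), a = query, USE.NAMES = FALSE)
}

#' Similar-name search over a term index
#'
#' Finds index entries whose normalized name is similar to the query name —
#' the first step of the annotation workflow, where curated annotations of
#' like-named items are offered for re-use. Entries scoring at least
#' `threshold` are ranked by similarity (descending), then usage count
#' (descending), then canonical signature (ascending), and truncated to
#' `limit`.
#'
#' @param index a [term_index] object.
#' @param name raw query name (normalized internally).
#' @param threshold minimum similarity in \[0, 1\].
#' @param limit maximum number of entries returned.
#' @return a data frame with columns `name`, `signature`, `count`,
#'   `similarity`, ordered by rank.
#' @export
search_similar <- function(index, name, threshold = 0.6, limit = 20L) {
  stopifnot(threshold >= 0, threshold <= 1, limit >= 1)
  df <- index_entries(index)
  if (nrow(df) == 0L) {
    return(cbind(df, data.frame(similarity = numeric(0))))
  }
  q <- normalize_name(name)
  df$similarity <- similarity_to(q, df$name)
  df <- df[df$similarity >= threshold, , drop = FALSE]
  ord <- order(-df$similarity, -df$count, df$signature, df$name, method = "radix")
  df <- df[ord, , drop = FALSE]
  row.names(df) <- NULL
  utils::head(df, limit)
}

#' Ranked annotation suggestions for one item name
#'
#' Implements the "re-use first" policy: curated repository entries similar to
#' the query are always listed before vocabulary concepts, regardless of raw
#' string similarity, because re-used codes are what keeps annotation uniform
#' across models. Vocabulary-origin suggestions (from [find_concepts()]) are
#' appended only when fewer than `limit` repository suggestions exist. An
#' empty result signals that the reviewer must postcoordinate manually.
#'
#' Repository entries sharing a signature under different names are merged
#' into one suggestion (best similarity, summed count, all example names).
#'
#' @param index a [term_index].
#' @param vocab a vocabulary (see [load_vocabulary()]).
#' @param item_name raw item name to annotate.
#' @param threshold,limit as in [search_similar()].
#' @return an object of class `suggestion_list`: list with `query_name` and a
#'   data frame `suggestions` (`rank`, `origin`, `signature`, `similarity`,
#'   `count`, `example_names`; names `|`-joined).
#' @export
suggest <- function(index, vocab, item_name, threshold = 0.6, limit = 20L) {
  hits <- search_similar(index, item_name, threshold = threshold, limit = limit)
  repo <- NULL
  if (nrow(hits) > 0L) {
    sp <- split(hits, hits$signature)
    repo <- do.call(rbind, lapply(sp, function(g) {
      data.frame(
        origin = "repository",
        signature = g$signature[1L],
        similarity = max(g$similarity),
        count = sum(g$count),
        example_names = paste(unique(g$name), collapse = "|"),
        stringsAsFactors = FALSE
      )
    }))
    ord <- order(-repo$similarity, -repo$count, repo$signature, method = "radix")
    repo <- utils::head(repo[ord, , drop = FALSE], limit)
  }
  n_repo <- if (is.null(repo)) 0L else nrow(repo)
  voc <- NULL
  if (n_repo < limit) {
    recs <- find_concepts(vocab, item_name)
    if (nrow(recs) > 0L) {
      q <- normalize_name(item_name)
      voc <- data.frame(
        origin = "vocabulary",
        signature = recs$code,
        similarity = similarity_to(q, normalize_name(recs$preferred_term)),
        count = 0L,
        example_names = recs$preferred_term,
        stringsAsFactors = FALSE
      )
      voc <- voc[!voc$signature %in% repo$signature, , drop = FALSE]
      voc <- utils::head(voc, limit - n_repo)
    }
  }
  out <- rbind(repo, voc)
  if (is.null(out)) {
    out <- data.frame(
      origin = character(0), signature = character(0),
      similarity = numeric(0), count = integer(0),
      example_names = character(0), stringsAsFactors = FALSE
    )
  }
  out <- cbind(data.frame(rank = seq_len(nrow(out))), out)
  row.names(out) <- NULL
  structure(list(query_name = item_name, suggestions = out),
            class = "suggestion_list")
}

#' @export
print.suggestion_list <- function(x, ...) {
  cat(sprintf("Suggestions for %s (%d)\n", sQuote(x$query_name), nrow(x$suggestions)))
  if (nrow(x$suggestions) > 0L) print(x$suggestions, row.names = FALSE)
  invisible(x)
}
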