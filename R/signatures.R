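#' Concept codes and annotation signatures
#'
#' A concept code is a non-empty token without whitespace, typically a
#' UMLS-style CUI (`"C"` followed by seven digits, e.g. `"C0005890"` for body
#' height). An annotation signature is the canonical rendering of a non-empty
#' set of concept codes attached to one data element: codes are deduplicated,
#' sorted ascending and joined with `"+"`. Postcoordination — representing one
#' meaning by a combination of codes when no single code exists — is therefore
#' just a multi-code signature, and any permutation of the same code set yields
#' the same canonical string. The signature is the unit of "uniform coding":
#' two elements mean the same thing exactly when they carry the same signature.
#'
#' @param codes character vector of concept codes.
#' @return `canonical_signature()` returns the canonical signature string;
#'   `signature_codes()` splits a signature back into its sorted code vector;
#'   `is_concept_code()` / `is_cui()` return logical vectors.
#' @examples
#' canonical_signature(c("C0027361", "C0005615", "C0011008"))
#' signature_codes("C0005615+C0011008+C0027361")
#' @name signatures
NULL

#' @rdname signatures
#' @export
is_concept_code <- function(codes) {
  nzchar(codes) & !grepl("[[:space:]]", codes) & !grepl("+", codes, fixed = TRUE)
}

#' @rdname signatures
#' @export
is_cui <- function(codes) {
  grepl("^C[0-9]{7}$", codes)
}

check_codes <- function(codes) {
  codes <- as.character(codes)
  bad <- !is_concept_code(codes)
  if (length(codes) == 0L) {
    odm_error("empty_signature", "an annotation signature needs at least one concept code")
  }
  if (any(bad | is.na(codes))) {
    odm_error("format", sprintf(
      "invalid concept code(s): %s (must be non-empty, no whitespace, no '+')",
      paste(sQuote(codes[bad | is.na(codes)]), collapse = ", ")
    ))
  }
  codes
}

#' @rdname signatures
#' @export
canonical_signature <- function(codes) {
  codes <- check_codes(codes)
  paste(sort(unique(codes), method = "radix"), collapse = "+")
}

#' @rdname signatures
#' @param signature a canonical signature string.
#' @export
signature_codes <- function(signature) {
  strsplit(signature, "+", fixed = TRUE)[[1]]
}

# TRUE iff `signature` is already in canonical form.
is_canonical_signature <- function(signature) {
  if (length(signature) != 1L || is.na(signature) || !nzchar(signature)) return(FALSE)
  codes <- strsplit(signature, "+", fixed = TRUE)[[1]]
  all(is_concept_code(codes)) &&
    !anyDuplicated(codes) &&
    identical(codes, sort(codes, method = "radix"))
}
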