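ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

#' Read ODM 1.3 study metadata
#'
#' Parses the metadata subset of a CDISC ODM 1.3 file into an [odm_model]:
#' FormDef / ItemGroupDef / ItemDef / CodeList definitions, measurement-unit
#' names, range checks, and semantic-annotation `Alias` elements. All `Alias`
#' elements on one item (or code-list entry) whose `Context` equals `context`
#' are combined into a single postcoordinated annotation signature. Clinical
#' data sections are ignored. Multilingual questions keep the first translated
#' text together with its language tag.
#'
#' @param x XML text or path to an ODM file.
#' @param context the `Alias` context label that marks semantic annotations.
#' @return an [odm_model].
#' @section Errors: malformed XML raises a parse error (`odmsem_parse`); a
#'   missing/empty metadata section raises `odmsem_empty_model`; dangling OID
#'   references raise `odmsem_integrity` naming the reference.
#' @export
read_odm <- function(x, context = "UMLS") {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) odm_error("parse", paste("malformed ODM XML:",
                                                               conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  study <- xml2::xml_find_first(doc, "./Study")
  if (inherits(study, "xml_missing")) {
    odm_error("empty_model", "ODM file contains no Study element")
  }
  model_id <- xml2::xml_attr(doc, "FileOID")
  if (is.na(model_id)) model_id <- xml2::xml_attr(study, "OID")
  study_name <- xml2::xml_text(xml2::xml_find_first(study, "./GlobalVariables/StudyName"))
  if (is.na(study_name)) study_name <- model_id

  units <- list()
  for (mu in xml2::xml_find_all(study, "./BasicDefinitions/MeasurementUnit")) {
    units[[xml2::xml_attr(mu, "OID")]] <- xml2::xml_attr(mu, "Name")
  }

  mdv <- xml2::xml_find_first(study, "./MetaDataVersion")
  if (inherits(mdv, "xml_missing")) {
    odm_error("empty_model", "ODM file contains no MetaDataVersion")
  }
  item_nodes <- xml2::xml_find_all(mdv, "./ItemDef")
  if (length(item_nodes) == 0L) {
    odm_error("empty_model", sprintf("model %s defines no items", sQuote(model_id)))
  }

  forms <- lapply(xml2::xml_find_all(mdv, "./FormDef"), function(fd) {
    odm_form(xml2::xml_attr(fd, "OID"), xml2::xml_attr(fd, "Name"),
             xml2::xml_attr(xml2::xml_find_all(fd, "./ItemGroupRef"), "ItemGroupOID"))
  })
  groups <- lapply(xml2::xml_find_all(mdv, "./ItemGroupDef"), function(gd) {
    odm_group(xml2::xml_attr(gd, "OID"), xml2::xml_attr(gd, "Name"),
              xml2::xml_attr(xml2::xml_find_all(gd, "./ItemRef"), "ItemOID"))
  })
  items <- lapply(item_nodes, function(nd) parse_item(nd, context, units))
  codelists <- lapply(xml2::xml_find_all(mdv, "./CodeList"),
                      function(nd) parse_codelist(nd, context))

  model <- odm_model(model_id, study_name, forms = forms, groups = groups,
                     items = items, codelists = codelists)
  issues <- validate_model(model)
  dangling <- issues[issues$rule == "dangling-ref", , drop = FALSE]
  if (nrow(dangling) > 0L) {
    odm_error("integrity", paste(dangling$message, collapse = "; "))
  }
  model
}

alias_signature <- function(node, context) {
  aliases <- xml2::xml_find_all(node, "./Alias")
  aliases <- aliases[xml2::xml_attr(aliases, "Context") == context]
  if (length(aliases) == 0L) return(NULL)
  canonical_signature(xml2::xml_attr(aliases, "Name"))
}

first_translated_text <- function(node, xpath) {
  tt <- xml2::xml_find_first(node, paste0("./", xpath, "/TranslatedText"))
  if (inherits(tt, "xml_missing")) return(list(text = NULL, lang = NULL))
  lang <- xml2::xml_attr(tt, "lang")
  list(text = xml2::xml_text(tt), lang = if (is.na(lang)) NULL else lang)
}

parse_item <- function(nd, context, units) {
  q <- first_translated_text(nd, "Question")
  d <- first_translated_text(nd, "Description")
  rmin <- rmax <- NULL
  for (rc in xml2::xml_find_all(nd, "./RangeCheck")) {
    val <- as.numeric(xml2::xml_text(xml2::xml_find_first(rc, "./CheckValue")))
    cmp <- xml2::xml_attr(rc, "Comparator")
    if (identical(cmp, "GE")) rmin <- val
    if (identical(cmp, "LE")) rmax <- val
  }
  unit <- NULL
  mur <- xml2::xml_find_first(nd, "./MeasurementUnitRef")
  if (!inherits(mur, "xml_missing")) {
    unit <- units[[xml2::xml_attr(mur, "MeasurementUnitOID")]]
  }
  clref <- xml2::xml_attr(xml2::xml_find_first(nd, "./CodeListRef"), "CodeListOID")
  odm_item(
    oid = xml2::xml_attr(nd, "OID"), name = xml2::xml_attr(nd, "Name"),
    data_type = xml2::xml_attr(nd, "DataType"),
    description = d$text, question = q$text, question_lang = q$lang,
    range_min = rmin, range_max = rmax, unit = unit,
    codelist_ref = if (is.na(clref)) NULL else clref,
    annotation = alias_signature(nd, context)
  )
}

parse_codelist <- function(nd, context) {
  entries <- lapply(xml2::xml_find_all(nd, "./CodeListItem"), function(ci) {
    sig <- alias_signature(ci, context)
    data.frame(
      coded_value = xml2::xml_attr(ci, "CodedValue"),
      decode = xml2::xml_text(xml2::xml_find_first(ci, "./Decode/TranslatedText")),
      annotation = if (is.null(sig)) NA_character_ else sig,
      stringsAsFactors = FALSE
    )
  })
  entries <- if (length(entries) == 0L) {
    data.frame(coded_value = character(0), decode = character(0),
               annotation = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, entries)
  odm_codelist(xml2::xml_attr(nd, "OID"), xml2::xml_attr(nd, "Name"), entries)
}

#' Write ODM 1.3 study metadata
#'
#' Serializes an [odm_model] to ODM 1.3 XML. Every annotation signature is
#' written as one `Alias` element per concept code, in canonical code order,
#' with the configured `Context`. Output is deterministic: element order
#' follows model order and the creation timestamp is fixed, so two calls on
#' the same model are byte-identical and version-control-friendly.
#'
#' @param model an [odm_model]; must pass [validate_model()].
#' @param path optional file to write to (UTF-8).
#' @param context the `Alias` context label for annotations.
#' @return the XML text, invisibly when `path` is given.
#' @export
write_odm <- function(model, path = NULL, context = "UMLS") {
  issues <- validate_model(model)
  if (nrow(issues) > 0L) {
    odm_error("integrity",
              paste0("model fails validation: ",
                     paste(issues$message, collapse = "; ")))
  }
  doc <- xml2::xml_new_root(
    "ODM", xmlns = ODM_NS, FileOID = model$model_id, FileType = "Snapshot",
    ODMVersion = "1.3", CreationDateTime = "1970-01-01T00:00:00"
  )
  study <- xml2::xml_add_child(doc, "Study", OID = model$model_id)
  gv <- xml2::xml_add_child(study, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", model$study_name)

  unit_names <- unique(unlist(lapply(model$items, `[[`, "unit")))
  if (length(unit_names) > 0L) {
    bd <- xml2::xml_add_child(study, "BasicDefinitions")
    for (u in unit_names) {
      mu <- xml2::xml_add_child(bd, "MeasurementUnit", OID = unit_oid(u), Name = u)
      sym <- xml2::xml_add_child(mu, "Symbol")
      xml2::xml_add_child(sym, "TranslatedText", u)
    }
  }

  mdv <- xml2::xml_add_child(study, "MetaDataVersion", OID = "MDV.1",
                             Name = model$study_name)
  for (f in model$forms) {
    fd <- xml2::xml_add_child(mdv, "FormDef", OID = f$oid, Name = f$name,
                              Repeating = "No")
    for (i in seq_along(f$group_refs)) {
      xml2::xml_add_child(fd, "ItemGroupRef", ItemGroupOID = f$group_refs[i],
                          OrderNumber = as.character(i), Mandatory = "No")
    }
  }
  for (g in model$groups) {
    gd <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = g$oid, Name = g$name,
                              Repeating = "No")
    for (i in seq_along(g$item_refs)) {
      xml2::xml_add_child(gd, "ItemRef", ItemOID = g$item_refs[i],
                          OrderNumber = as.character(i), Mandatory = "No")
    }
  }
  for (it in model$items) write_item(mdv, it, context)
  for (cl in model$codelists) write_codelist(mdv, cl, context)

  txt <- as.character(doc)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(txt), con)
    return(invisible(txt))
  }
  txt
}

unit_oid <- function(unit) paste0("MU.", gsub("[^A-Za-z0-9]+", "_", unit))

write_item <- function(mdv, it, context) {
  nd <- xml2::xml_add_child(mdv, "ItemDef", OID = it$oid, Name = it$name,
                            DataType = it$data_type)
  if (!is.null(it$description)) {
    de <- xml2::xml_add_child(nd, "Description")
    xml2::xml_add_child(de, "TranslatedText", it$description)
  }
  if (!is.null(it$question)) {
    qu <- xml2::xml_add_child(nd, "Question")
    tt <- xml2::xml_add_child(qu, "TranslatedText", it$question)
    if (!is.null(it$question_lang)) {
      xml2::xml_set_attr(tt, "xml:lang", it$question_lang)
    }
  }
  if (!is.null(it$unit)) {
    xml2::xml_add_child(nd, "MeasurementUnitRef", MeasurementUnitOID = unit_oid(it$unit))
  }
  if (!is.null(it$range_min)) {
    rc <- xml2::xml_add_child(nd, "RangeCheck", Comparator = "GE", SoftHard = "Soft")
    xml2::xml_add_child(rc, "CheckValue", num_chr(it$range_min))
  }
  if (!is.null(it$range_max)) {
    rc <- xml2::xml_add_child(nd, "RangeCheck", Comparator = "LE", SoftHard = "Soft")
    xml2::xml_add_child(rc, "CheckValue", num_chr(it$range_max))
  }
  if (!is.null(it$codelist_ref)) {
    xml2::xml_add_child(nd, "CodeListRef", CodeListOID = it$codelist_ref)
  }
  write_aliases(nd, it$annotation, context)
}

write_codelist <- function(mdv, cl, context) {
  nd <- xml2::xml_add_child(mdv, "CodeList", OID = cl$oid, Name = cl$name,
                            DataType = "text")
  for (i in seq_len(nrow(cl$entries))) {
    ci <- xml2::xml_add_child(nd, "CodeListItem",
                              CodedValue = cl$entries$coded_value[i])
    de <- xml2::xml_add_child(ci, "Decode")
    xml2::xml_add_child(de, "TranslatedText", cl$entries$decode[i])
    ann <- cl$entries$annotation[i]
    if (!is.na(ann)) write_aliases(ci, ann, context)
  }
}

write_aliases <- function(nd, signature, context) {
  if (is.null(signature) || is.na(signature)) return(invisible(NULL))
  for (code in signature_codes(signature)) {
    xml2::xml_add_child(nd, "Alias", Context = context, Name = code)
  }
}

# 15 significant digits round-trips doubles used for range checks.
num_chr <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
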