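# Core containers shared by every pipeline stage, plus the token-level
# standoff interchange format (JSON) that chains them. All character spans
# are 0-based half-open intervals. Text cleaning is length-preserving, so
# processed-text coordinates coincide with original-report coordinates; the
# offset map records the correspondence explicitly.

T_LEVELS <- c("Tx", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T3", "T4")
FORMAT_TAGS <- c("CT", "PET", "PET-CT", "unknown")
CONCEPT_CATEGORIES <- c("tumor_mass", "lymph_node", "involvement_target",
                        "presence_finding", "anatomic_location", "blacklist_term")
MODIFIER_CATEGORIES <- c("negation", "uncertainty", "historical", "termination", "pseudo")
MODIFIER_DIRECTIONS <- c("forward", "backward", "bidirectional")
SECTION_CATEGORIES <- c("history", "comparison", "technique", "findings", "head",
                        "neck", "chest", "mediastinum", "abdomen", "pelvis",
                        "bones", "musculoskeletal", "other")
LOBES <- c("RUL", "RML", "RLL", "LUL", "LLL", "unknown")
LATERALITIES <- c("left", "right", "unknown")
FINDING_ROLES <- c("primary", "satellite_same_lobe", "nodule_ipsilateral_other_lobe", "other")
PRESENCE_KINDS <- c("post_obstructive_atelectasis", "main_bronchus",
                    "satellite_same_lobe", "nodule_ipsilateral_other_lobe")
PIPELINE_STAGES <- c("preprocess", "concepts", "context", "measurements", "classify")

#' T-substage labels in staging order
#'
#' The total order `Tx < T1a < T1b < T1c < T2 < T2a < T2b < T3 < T4` used
#' wherever component maxima are taken. The bare `T2` class is kept distinct
#' from `T2a`/`T2b`: it is emitted when a T2 criterion fires but no tumor
#' size is available to resolve the substage.
#'
#' @return Character vector of the nine labels, lowest first.
#' @export
stage_levels <- function() T_LEVELS

#' @describeIn stage_levels Integer rank of a label within the staging order.
#' @param label character vector of T labels.
#' @export
stage_rank <- function(label) {
  r <- match(label, T_LEVELS)
  if (anyNA(r) && !anyNA(label)) stop("unknown T label: ", paste(label[is.na(r)], collapse = ", "))
  r
}

#' @describeIn stage_levels Maximum of a set of labels under the staging
#'   order; `NA_character_` for an empty (or all-`NA`) set.
#' @param labels character vector of T labels (may contain `NA`).
#' @export
stage_max <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  T_LEVELS[max(stage_rank(labels))]
}

# substring by a 0-based half-open span
span_text <- function(text, start, end) substring(text, start + 1L, end)

#' Construct a raw report
#'
#' @param report_id opaque identifier, unique within a batch.
#' @param text report free text; must be non-empty after whitespace strip.
#' @param format_tag one of `"CT"`, `"PET"`, `"PET-CT"`, `"unknown"`.
#' @return A list of class `raw_report`.
#' @export
raw_report <- function(report_id, text, format_tag = "unknown") {
  stopifnot(is.character(report_id), length(report_id) == 1L, nzchar(report_id))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty report: text must be non-empty after whitespace strip")
  format_tag <- match.arg(format_tag, FORMAT_TAGS)
  structure(list(report_id = report_id, text = text, format_tag = format_tag),
            class = "raw_report")
}

# ---- table schemas ---------------------------------------------------------
# Each annotation table has a fixed schema; constructors below are the single
# place those schemas are defined, so pipeline stages and the deserializer
# always produce byte-identical structures.

.coerce_df <- function(df, schema) {
  out <- lapply(names(schema), function(nm) {
    v <- if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
    switch(schema[[nm]],
           int = as.integer(v), num = as.numeric(v),
           chr = as.character(v), lgl = as.logical(v))
  })
  names(out) <- names(schema)
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

TOKEN_SCHEMA <- list(index = "int", text = "chr", start = "int", end = "int")
SENTENCE_SCHEMA <- list(index = "int", start = "int", end = "int",
                        token_start = "int", token_end = "int",
                        section = "int", is_heading = "lgl")
SECTION_SCHEMA <- list(index = "int", heading_raw = "chr", category = "chr",
                       start = "int", end = "int", heading_end = "int",
                       in_scope = "lgl")
CONCEPT_SCHEMA <- list(index = "int", concept_id = "chr", snomed_code = "chr",
                       category = "chr", start = "int", end = "int",
                       sentence = "int", negated = "lgl", uncertain = "lgl",
                       historical = "lgl", suppressed = "lgl",
                       suppress_reason = "chr")
MODIFIER_SCHEMA <- list(index = "int", category = "chr", direction = "chr",
                        start = "int", end = "int", sentence = "int")
MEASUREMENT_SCHEMA <- list(index = "int", mag1 = "num", mag2 = "num", mag3 = "num",
                           unit = "chr", max_dim_mm = "num", start = "int",
                           end = "int", sentence = "int", suppressed = "lgl",
                           suppress_reason = "chr")
LINK_SCHEMA <- list(measurement = "int", concept = "int", category = "chr",
                    laterality = "chr", lobe = "chr")
INVOLVEMENT_SCHEMA <- list(structure = "chr", snomed_code = "chr", tier = "chr",
                           source = "int")
PRESENCE_SCHEMA <- list(kind = "chr", qualifier_size_mm = "num", source = "int")

empty_table <- function(schema) .coerce_df(data.frame(), schema)
as_table <- function(df, schema) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) return(empty_table(schema))
  .coerce_df(as.data.frame(df, stringsAsFactors = FALSE), schema)
}

#' Construct a consolidated tumor finding
#'
#' @param role `"primary"`, `"satellite_same_lobe"`,
#'   `"nodule_ipsilateral_other_lobe"` or `"other"`.
#' @param laterality,lobe site of the finding (`"unknown"` when unstated).
#' @param descriptor free-text lexeme that anchored the finding.
#' @param size_mm largest dimension in millimetres, or `NA` when unsized.
#' @param involvement data frame of involved structures
#'   (`structure`, `snomed_code`, `tier`, `source`).
#' @param presence data frame of presence items
#'   (`kind`, `qualifier_size_mm`, `source`).
#' @return A list of class `tumor_finding`.
#' @export
tumor_finding <- function(role = "primary", laterality = "unknown", lobe = "unknown",
                          descriptor = "", size_mm = NA_real_,
                          involvement = NULL, presence = NULL) {
  role <- match.arg(role, FINDING_ROLES)
  laterality <- match.arg(laterality, LATERALITIES)
  lobe <- match.arg(lobe, LOBES)
  if (!is.na(size_mm) && size_mm <= 0) stop("size_mm must be positive")
  structure(list(role = role, laterality = laterality, lobe = lobe,
                 descriptor = as.character(descriptor), size_mm = as.numeric(size_mm),
                 involvement = as_table(involvement, INVOLVEMENT_SCHEMA),
                 presence = as_table(presence, PRESENCE_SCHEMA)),
            class = "tumor_finding")
}

tstage_result <- function(label, size_component = NA_character_,
                          involvement_component = NA_character_,
                          presence_component = NA_character_,
                          rationale = character(0)) {
  if (!is.character(label) || length(label) != 1L || !label %in% T_LEVELS)
    stop("unknown stage label: ", label)
  for (comp in c(size_component, involvement_component, presence_component))
    if (!is.na(comp) && !comp %in% T_LEVELS) stop("invalid component label: ", comp)
  structure(list(label = label,
                 size_component = as.character(size_component),
                 involvement_component = as.character(involvement_component),
                 presence_component = as.character(presence_component),
                 rationale = as.character(rationale)),
            class = "tstage_result")
}

#' Create an (empty) annotation document for a report
#'
#' An `annotation_document` is the standoff record a report accumulates as
#' it moves through the pipeline: tokens, sentences, sections, concept and
#' modifier mentions, measurements, measurement-to-concept links,
#' consolidated tumor findings and the final stage, all as spans into the
#' report text.
#'
#' @param report a [raw_report()], or a single string (given an automatic id).
#' @return A list of class `annotation_document`.
#' @export
annotation_document <- function(report) {
  if (is.character(report)) report <- raw_report("report-1", report)
  stopifnot(inherits(report, "raw_report"))
  structure(list(
    report = report,
    text_processed = NA_character_,
    offset_map = integer(0),
    stages_done = character(0),
    tokens = empty_table(TOKEN_SCHEMA),
    sentences = empty_table(SENTENCE_SCHEMA),
    sections = empty_table(SECTION_SCHEMA),
    concepts = empty_table(CONCEPT_SCHEMA),
    modifiers = empty_table(MODIFIER_SCHEMA),
    measurements = empty_table(MEASUREMENT_SCHEMA),
    links = empty_table(LINK_SCHEMA),
    findings = list(),
    result = NULL,
    log = character(0)
  ), class = "annotation_document")
}

# ---- validation ------------------------------------------------------------

.check <- function(ok, where, msg) if (!ok) stop("invalid document [", where, "]: ", msg, call. = FALSE)

#' Validate an annotation document against its invariants
#'
#' Checks that every span resolves against the report text, tokens are
#' non-overlapping and strictly increasing, sections partition the text,
#' concept spans lie within their sentence, enums lie in their domains,
#' blacklist mentions carry no context flags, and at most one finding has
#' the primary role.
#'
#' @param doc an `annotation_document`.
#' @return `doc`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "annotation_document"))
  rep <- doc$report
  .check(nzchar(trimws(rep$text)), "report", "empty text")
  .check(rep$format_tag %in% FORMAT_TAGS, "report", "unknown format_tag")
  n <- nchar(doc$text_processed)
  if (is.na(doc$text_processed)) return(invisible(doc))  # not yet preprocessed
  .check(n == nchar(rep$text), "text", "processed text length differs from original")
  .check(length(doc$offset_map) == n, "offset_map", "length mismatch")

  tk <- doc$tokens
  if (nrow(tk)) {
    .check(all(tk$index == seq_len(nrow(tk)) - 1L), "tokens", "indices not ordinal")
    .check(all(tk$start < tk$end) && all(tk$end <= n) && all(tk$start >= 0L),
           "tokens", "span out of bounds")
    .check(all(diff(tk$start) > 0) && all(tk$start[-1] >= tk$end[-nrow(tk)]),
           "tokens", "spans overlap or not increasing")
    .check(identical(tk$text, span_text(doc$text_processed, tk$start, tk$end)),
           "tokens", "text does not equal substring at span")
  }
  sc <- doc$sections
  if (nrow(sc)) {
    .check(all(sc$category %in% SECTION_CATEGORIES), "sections", "unknown category")
    .check(sc$start[1] == 0L && sc$end[nrow(sc)] == n &&
             all(sc$start[-1] == sc$end[-nrow(sc)]),
           "sections", "sections do not partition the text")
  }
  st <- doc$sentences
  if (nrow(st)) {
    .check(all(st$section >= 0L & st$section < nrow(sc)), "sentences", "bad section ref")
    secs <- sc[st$section + 1L, ]
    .check(all(st$start >= secs$start & st$end <= secs$end),
           "sentences", "sentence crosses section boundary")
    .check(all(st$token_start <= st$token_end) && all(st$token_end <= nrow(tk)),
           "sentences", "token_range out of bounds")
  }
  cp <- doc$concepts
  if (nrow(cp)) {
    .check(all(cp$category %in% CONCEPT_CATEGORIES), "concepts", "unknown category")
    .check(all(cp$sentence >= 0L & cp$sentence < nrow(st)), "concepts", "bad sentence ref")
    sen <- st[cp$sentence + 1L, ]
    .check(all(cp$start >= sen$start & cp$end <= sen$end),
           "concepts", "span outside its sentence")
    bl <- cp$category == "blacklist_term"
    .check(!any(bl & (cp$negated | cp$uncertain | cp$historical)),
           "concepts", "blacklist mention carries context flags")
  }
  md <- doc$modifiers
  if (nrow(md)) {
    .check(all(md$category %in% MODIFIER_CATEGORIES), "modifiers", "unknown category")
    .check(all(md$direction %in% MODIFIER_DIRECTIONS), "modifiers", "unknown direction")
    .check(all(md$end <= n), "modifiers", "span out of bounds")
  }
  ms <- doc$measurements
  if (nrow(ms)) {
    .check(all(ms$unit %in% c("mm", "cm")), "measurements", "unknown unit")
    .check(all(ms$mag1 > 0), "measurements", "non-positive magnitude")
    mags <- pmax(ms$mag1, ms$mag2, ms$mag3, na.rm = TRUE)
    fac <- ifelse(ms$unit == "cm", 10, 1)
    .check(all(abs(ms$max_dim_mm - mags * fac) < 1e-9),
           "measurements", "max_dim_mm inconsistent with magnitudes/unit")
  }
  if (length(doc$findings)) {
    roles <- vapply(doc$findings, `[[`, "", "role")
    .check(all(roles %in% FINDING_ROLES), "findings", "unknown role")
    .check(sum(roles == "primary") <= 1L, "findings", "more than one primary finding")
  }
  if (!is.null(doc$result)) {
    .check(doc$result$label %in% T_LEVELS, "result", paste0("unknown label ", doc$result$label))
    comps <- c(doc$result$size_component, doc$result$involvement_component,
               doc$result$presence_component)
    .check(all(is.na(comps) | comps %in% T_LEVELS), "result", "unknown component label")
  }
  invisible(doc)
}

# ---- interchange (JSON) ----------------------------------------------------

.df_records <- function(df) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

.measurement_records <- function(ms) {
  if (!nrow(ms)) return(list())
  lapply(seq_len(nrow(ms)), function(i) {
    mags <- c(ms$mag1[i], ms$mag2[i], ms$mag3[i])
    list(index = ms$index[i], magnitudes = mags[!is.na(mags)], unit = ms$unit[i],
         max_dim_mm = ms$max_dim_mm[i], start = ms$start[i], end = ms$end[i],
         sentence = ms$sentence[i], suppressed = ms$suppressed[i],
         suppress_reason = ms$suppress_reason[i])
  })
}

.finding_record <- function(f) {
  list(role = f$role, laterality = f$laterality, lobe = f$lobe,
       descriptor = f$descriptor, size_mm = f$size_mm,
       involvement = .df_records(f$involvement),
       presence = .df_records(f$presence))
}

#' Serialize an annotation document to interchange JSON
#'
#' The interchange format is a self-contained standoff record: UTF-8 JSON
#' with stable key order, one object per document, spans kept as 0-based
#' half-open `[start, end)` intervals so token alignment is preserved across
#' consumers (e.g. a highlighting front end).
#'
#' @param doc a validated `annotation_document`.
#' @param path optional file path; when given the JSON is written there.
#' @return The JSON as a single string (invisibly when `path` is given).
#' @export
serialize_document <- function(doc, path = NULL) {
  validate_document(doc)
  obj <- list(
    schema = "pulmostage-annotation/1",
    report = unclass(doc$report),
    text_processed = doc$text_processed,
    offset_map = doc$offset_map,
    stages_done = doc$stages_done,
    tokens = .df_records(doc$tokens),
    sentences = .df_records(doc$sentences),
    sections = .df_records(doc$sections),
    concepts = .df_records(doc$concepts),
    modifiers = .df_records(doc$modifiers),
    measurements = .measurement_records(doc$measurements),
    links = .df_records(doc$links),
    findings = lapply(doc$findings, .finding_record),
    result = if (is.null(doc$result)) NULL else unclass(doc$result),
    log = doc$log
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", null = "null",
                           digits = NA, pretty = FALSE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

.records_df <- function(records, schema) {
  if (!length(records)) return(empty_table(schema))
  rows <- lapply(records, function(r) {
    r <- r[names(schema)]
    names(r) <- names(schema)
    r[vapply(r, is.null, TRUE)] <- NA
    r
  })
  as_table(do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE))),
           schema)
}

.null_na <- function(x, mode = "character") {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x)))
    return(switch(mode, character = NA_character_, numeric = NA_real_, integer = NA_integer_))
  x
}

#' Deserialize interchange JSON to an annotation document
#'
#' All invariants are re-validated on load: spans must resolve within the
#' text, enum fields must lie in their domains (an unknown stage label such
#' as `"T5"` is rejected), and the result is bit-identical to the document
#' that produced the stream.
#'
#' @param json a JSON string, or the path of a file containing one document.
#' @return An `annotation_document`.
#' @export
deserialize_document <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj$schema, "pulmostage-annotation/1"))
    stop("validation error: unknown interchange schema")
  rep <- raw_report(obj$report$report_id, obj$report$text, obj$report$format_tag)
  doc <- annotation_document(rep)
  doc$text_processed <- .null_na(obj$text_processed)
  doc$offset_map <- as.integer(unlist(obj$offset_map))
  doc$stages_done <- as.character(unlist(obj$stages_done))
  doc$tokens <- .records_df(obj$tokens, TOKEN_SCHEMA)
  doc$sentences <- .records_df(obj$sentences, SENTENCE_SCHEMA)
  doc$sections <- .records_df(obj$sections, SECTION_SCHEMA)
  doc$concepts <- .records_df(obj$concepts, CONCEPT_SCHEMA)
  doc$modifiers <- .records_df(obj$modifiers, MODIFIER_SCHEMA)
  if (length(obj$measurements)) {
    ms <- lapply(obj$measurements, function(r) {
      mags <- as.numeric(unlist(r$magnitudes))
      if (!length(mags) || length(mags) > 3L)
        stop("validation error: measurement must carry 1-3 magnitudes")
      data.frame(index = r$index, mag1 = mags[1],
                 mag2 = if (length(mags) >= 2) mags[2] else NA_real_,
                 mag3 = if (length(mags) >= 3) mags[3] else NA_real_,
                 unit = r$unit, max_dim_mm = r$max_dim_mm, start = r$start,
                 end = r$end, sentence = r$sentence, suppressed = r$suppressed,
                 suppress_reason = r$suppress_reason, stringsAsFactors = FALSE)
    })
    doc$measurements <- as_table(do.call(rbind, ms), MEASUREMENT_SCHEMA)
  }
  doc$links <- .records_df(obj$links, LINK_SCHEMA)
  doc$findings <- lapply(obj$findings, function(f) {
    tumor_finding(role = f$role, laterality = f$laterality, lobe = f$lobe,
                  descriptor = f$descriptor, size_mm = .null_na(f$size_mm, "numeric"),
                  involvement = .records_df(f$involvement, INVOLVEMENT_SCHEMA),
                  presence = .records_df(f$presence, PRESENCE_SCHEMA))
  })
  if (!is.null(obj$result)) {
    r <- obj$result
    doc$result <- tstage_result(r$label, .null_na(r$size_component),
                                .null_na(r$involvement_component),
                                .null_na(r$presence_component),
                                as.character(unlist(r$rationale)))
  }
  doc$log <- as.character(unlist(obj$log))
  validate_document(doc)
  doc
}

#' @export
print.annotation_document <- function(x, ...) {
  cat("<annotation_document> report", x$report$report_id,
      sprintf("(%s, %d chars)\n", x$report$format_tag, nchar(x$report$text)))
  cat("  stages:", if (length(x$stages_done)) paste(x$stages_done, collapse = " > ") else "(none)", "\n")
  cat(sprintf("  %d tokens, %d sentences, %d sections, %d concepts, %d modifiers, %d measurements\n",
              nrow(x$tokens), nrow(x$sentences), nrow(x$sections),
              nrow(x$concepts), nrow(x$modifiers), nrow(x$measurements)))
  if (!is.null(x$result)) {
    cat("  T stage:", x$result$label, "\n")
    for (r in x$result$rationale) cat("   -", r, "\n")
  }
  invisible(x)
}

#' @export
print.tstage_result <- function(x, ...) {
  comp <- function(v) if (is.na(v)) "-" else v
  cat("T stage:", x$label,
      sprintf("(size %s, involvement %s, presence %s)\n",
              comp(x$size_component), comp(x$involvement_component),
              comp(x$presence_component)))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}
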