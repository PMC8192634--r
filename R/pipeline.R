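# Pipeline orchestration: the five stages (preprocess, concepts, context,
# measurements, classify) run fused or as separately chained calls over the
# same interchange document; both routes give identical results.

#' Stage a single report end to end
#'
#' Runs preprocess -> concept matching -> context validation ->
#' measurement extraction/linking/consolidation -> T-stage classification.
#'
#' @param report a [raw_report()], or a single string.
#' @param lexicon,modifiers,policy,table pipeline resources (defaults:
#'   shipped resources).
#' @return A fully annotated `annotation_document` with `result` set.
#' @examples
#' doc <- stage_report("There is a 2.5 cm mass in the right upper lobe.")
#' doc$result$label  # "T1c"
#' @export
stage_report <- function(report, lexicon = default_lexicon(),
                         modifiers = default_modifiers(),
                         policy = load_section_policy(),
                         table = default_tnm_table()) {
  doc <- pulmo_preprocess(report, policy)
  doc <- pulmo_concepts(doc, lexicon)
  doc <- pulmo_context(doc, modifiers)
  doc <- pulmo_measurements(doc, table)
  pulmo_classify(doc, table)
}

#' Run a prefix of the pipeline stage chain
#'
#' The canonical stage order is `preprocess`, `concepts`, `context`,
#' `measurements`, `classify`. `stages` must be a prefix of that order
#' (continuing from whatever the document has already completed); each
#' stage consumes and returns the interchange document, and running stages
#' separately equals running the fused pipeline. Stages are idempotent:
#' re-running a completed stage recomputes the same outputs.
#'
#' @param doc an `annotation_document` (or report accepted by
#'   [annotation_document()]).
#' @param stages character vector of stage names.
#' @param lexicon,modifiers,policy,table pipeline resources.
#' @return The updated document.
#' @export
run_stages <- function(doc, stages, lexicon = default_lexicon(),
                       modifiers = default_modifiers(),
                       policy = load_section_policy(),
                       table = default_tnm_table()) {
  if (!inherits(doc, "annotation_document")) doc <- annotation_document(doc)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("usage error: unknown stage(s) ", paste(bad, collapse = ", "))
  done <- length(doc$stages_done)
  want <- match(stages, PIPELINE_STAGES)
  if (!isTRUE(all(diff(want) == 1L)) || want[1] > done + 1L)
    stop("usage error: stages must be requested in canonical order (",
         paste(PIPELINE_STAGES, collapse = " > "), ") without gaps")
  for (s in stages) {
    doc <- switch(s,
                  preprocess = pulmo_preprocess(doc, policy),
                  concepts = pulmo_concepts(doc, lexicon),
                  context = pulmo_context(doc, modifiers),
                  measurements = pulmo_measurements(doc, table),
                  classify = pulmo_classify(doc, table))
  }
  doc
}

#' Stage a batch of reports
#'
#' @param reports data frame with columns `report_id` and `text` (optional
#'   `format_tag`), or a list of [raw_report()] objects.
#' @param lexicon,modifiers,policy,table pipeline resources, loaded once
#'   for the whole batch.
#' @param progress print a dot every 25 documents.
#' @return A list with `documents` (named list of annotated documents, in
#'   input order) and `predictions` (named character vector of T labels).
#' @export
stage_corpus <- function(reports, lexicon = default_lexicon(),
                         modifiers = default_modifiers(),
                         policy = load_section_policy(),
                         table = default_tnm_table(), progress = FALSE) {
  if (is.data.frame(reports)) {
    stopifnot(all(c("report_id", "text") %in% names(reports)))
    fmt <- if ("format_tag" %in% names(reports)) reports$format_tag
           else rep("unknown", nrow(reports))
    reports <- lapply(seq_len(nrow(reports)), function(i)
      raw_report(reports$report_id[i], reports$text[i], fmt[i]))
  }
  ids <- vapply(reports, `[[`, "", "report_id")
  if (anyDuplicated(ids)) stop("report_id must be unique within a batch")
  docs <- vector("list", length(reports))
  for (i in seq_along(reports)) {
    docs[[i]] <- stage_report(reports[[i]], lexicon, modifiers, policy, table)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  names(docs) <- ids
  preds <- vapply(docs, function(d) d$result$label, "")
  list(documents = docs, predictions = preds)
}
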