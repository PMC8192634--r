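# Context validation in the ConText/NegEx style: trigger terms with a
# direction (forward/backward/bidirectional) set negation, uncertainty or
# historical flags on concept mentions within sentence scope; termination
# terms cut a scope short; pseudo triggers block contained true triggers.
# Scope is purely positional — no dependency parsing, by design.

#' Load a modifier lexicon
#'
#' UTF-8 TSV with columns `category` (negation, uncertainty, historical,
#' termination, pseudo), `direction` (forward, backward, bidirectional) and
#' `pattern` (case-insensitive regular expression, word-boundary anchored
#' when matched).
#'
#' @param path TSV resource; defaults to the inventory shipped with the
#'   package.
#' @return A list of class `modifier_lexicon`.
#' @export
load_modifiers <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "modifiers.tsv", package = "pulmostage")
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("category", "direction", "pattern")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("modifier load error: missing column(s) ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("modifier load error: no entries")
  bad <- setdiff(unique(df$category), MODIFIER_CATEGORIES)
  if (length(bad)) stop("modifier load error: unknown category ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$direction), MODIFIER_DIRECTIONS)
  if (length(bad)) stop("modifier load error: unknown direction ", paste(bad, collapse = ", "))
  df$compiled <- vapply(df$pattern, .compile_pattern, "", USE.NAMES = FALSE)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ grepl(df$compiled[i], "probe", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("modifier load error: pattern does not compile at row ", i)
  }
  structure(list(entries = df, path = path), class = "modifier_lexicon")
}

#' @rdname load_modifiers
#' @export
default_modifiers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_modifiers()
    cache
  }
})

#' Match context modifiers in one sentence
#'
#' Longest match wins among overlapping hits (any category), so the pseudo
#' trigger "no change" swallows the shorter negation trigger "no" it
#' contains; pseudo hits are then dropped — they flag nothing themselves
#' and exist only to block their contained true triggers.
#'
#' @param sentence_text text of one sentence.
#' @param modifiers a [load_modifiers()] object.
#' @param sentence_index 0-based sentence ordinal.
#' @param offset document-level offset of the sentence start.
#' @return Data frame of modifier mentions (document-level spans).
#' @export
match_modifiers <- function(sentence_text, modifiers = default_modifiers(),
                            sentence_index = 0L, offset = 0L) {
  en <- modifiers$entries
  out <- list()
  for (i in seq_len(nrow(en))) {
    h <- .find_all(en$compiled[i], sentence_text)
    if (is.null(h)) next
    h$category <- en$category[i]
    h$direction <- en$direction[i]
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(empty_table(MODIFIER_SCHEMA))
  hits <- do.call(rbind, out)
  # longest-match-wins across all modifier categories
  hits <- hits[order(-(hits$end - hits$start), hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    contained <- hits$start >= hits$start[i] & hits$end <= hits$end[i] &
      (hits$end - hits$start) < (hits$end[i] - hits$start[i])
    keep[contained] <- FALSE
  }
  hits <- hits[keep & hits$category != "pseudo", , drop = FALSE]
  if (!nrow(hits)) return(empty_table(MODIFIER_SCHEMA))
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$index <- seq_len(nrow(hits)) - 1L
  hits$start <- hits$start + offset
  hits$end <- hits$end + offset
  hits$sentence <- sentence_index
  as_table(hits, MODIFIER_SCHEMA)
}

# scope of one flag-bearing modifier within its sentence, as a half-open
# character interval; truncated at the nearest termination modifier or the
# next flag-bearing modifier in the travel direction
.modifier_scope <- function(mod, all_mods, sent_start, sent_end) {
  flagging <- all_mods$category %in% c("negation", "uncertainty", "historical")
  cuts_fwd <- all_mods$start[(all_mods$category == "termination" | flagging) &
                               all_mods$start >= mod$end &
                               !(all_mods$start == mod$start & all_mods$end == mod$end)]
  cuts_bwd <- all_mods$end[(all_mods$category == "termination" | flagging) &
                             all_mods$end <= mod$start &
                             !(all_mods$start == mod$start & all_mods$end == mod$end)]
  fwd <- c(mod$end, if (length(cuts_fwd)) min(cuts_fwd) else sent_end)
  bwd <- c(if (length(cuts_bwd)) max(cuts_bwd) else sent_start, mod$start)
  switch(mod$direction,
         forward = list(fwd),
         backward = list(bwd),
         bidirectional = list(fwd, bwd))
}

#' Assign modifier scopes to concept mentions
#'
#' Forward modifiers flag concepts after them up to the sentence end;
#' backward modifiers flag concepts before them back to the sentence start;
#' bidirectional modifiers do both. Any scope is truncated at the nearest
#' termination trigger or at the next flag-bearing modifier in that
#' direction. Flags are monotone — a concept once flagged stays flagged —
#' and blacklist mentions never carry flags.
#'
#' @param sentence row of the sentence table (needs `start`, `end`, `index`).
#' @param modifiers modifier mentions of that sentence.
#' @param concepts concept mentions of that sentence.
#' @return `concepts` with `negated`/`uncertain`/`historical` updated.
#' @export
assign_modifier_scopes <- function(sentence, modifiers, concepts) {
  if (!nrow(modifiers) || !nrow(concepts)) return(concepts)
  flag_col <- c(negation = "negated", uncertainty = "uncertain", historical = "historical")
  for (i in seq_len(nrow(modifiers))) {
    mod <- modifiers[i, ]
    if (!mod$category %in% names(flag_col)) next
    scopes <- .modifier_scope(mod, modifiers, sentence$start, sentence$end)
    for (sp in scopes) {
      inside <- concepts$start >= sp[1] & concepts$end <= sp[2] &
        concepts$category != "blacklist_term"
      concepts[[flag_col[[mod$category]]]] <- concepts[[flag_col[[mod$category]]]] | inside
    }
  }
  concepts
}

#' Pipeline stage: context validation over a whole document
#'
#' Matches modifiers per sentence and assigns their scopes to the concept
#' mentions already extracted.
#'
#' @param doc document after concept matching.
#' @param modifiers a [load_modifiers()] object.
#' @return The updated document.
#' @export
pulmo_context <- function(doc, modifiers = default_modifiers()) {
  stopifnot(inherits(doc, "annotation_document"), "concepts" %in% doc$stages_done)
  st <- doc$sentences
  out <- list()
  for (i in seq_len(nrow(st))) {
    if (st$is_heading[i]) next
    md <- match_modifiers(span_text(doc$text_processed, st$start[i], st$end[i]),
                          modifiers, sentence_index = st$index[i], offset = st$start[i])
    if (nrow(md)) out[[length(out) + 1L]] <- md
  }
  mds <- if (length(out)) do.call(rbind, out) else empty_table(MODIFIER_SCHEMA)
  if (nrow(mds)) mds$index <- seq_len(nrow(mds)) - 1L
  doc$modifiers <- as_table(mds, MODIFIER_SCHEMA)
  cp <- doc$concepts
  # reset flags so the stage is idempotent, then reassign
  if (nrow(cp)) { cp$negated <- FALSE; cp$uncertain <- FALSE; cp$historical <- FALSE }
  if (nrow(cp) && nrow(mds)) {
    for (sidx in unique(mds$sentence)) {
      srow <- st[st$index == sidx, ]
      sel <- cp$sentence == sidx
      if (!any(sel)) next
      cp[sel, ] <- assign_modifier_scopes(srow, mds[mds$sentence == sidx, , drop = FALSE],
                                          cp[sel, , drop = FALSE])
    }
  }
  doc$concepts <- as_table(cp, CONCEPT_SCHEMA)
  doc$stages_done <- union(doc$stages_done, "context")
  validate_document(doc)
}
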