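# Concept lexicon: SNOMED-CT-coded synonym patterns matched per sentence,
# lymph-node/mass disambiguation, and sentence-level blacklist suppression.

# word-boundary-safe, case-insensitive wrapper around a lexicon pattern;
# boundary assertions are only attached next to word characters so pure
# punctuation triggers (the ";" termination) still match after a word
.compile_pattern <- function(pattern) {
  pre <- if (grepl("^[A-Za-z0-9(]", pattern)) "(?<![A-Za-z0-9])" else ""
  post <- if (grepl("[A-Za-z0-9)?]$", pattern)) "(?![A-Za-z0-9])" else ""
  sprintf("(?i)%s(?:%s)%s", pre, pattern, post)
}

#' Load a concept lexicon
#'
#' The resource is a UTF-8 TSV with columns `concept_id`, `snomed_code`,
#' `category`, `pattern`, `notes` — one entry per row, patterns are
#' case-insensitive regular expressions anchored at word boundaries when
#' matched. SNOMED-CT codes are carried as labels only.
#'
#' @param path TSV resource; defaults to the curated lexicon shipped with
#'   the package.
#' @return A list of class `lexicon` with an `entries` data frame.
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "lexicon.tsv", package = "pulmostage")
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("concept_id", "snomed_code", "category", "pattern")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("lexicon load error: missing column(s) ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("lexicon load error: no entries")
  dup <- df$concept_id[duplicated(df$concept_id)]
  if (length(dup)) stop("lexicon load error: duplicate concept_id ", paste(unique(dup), collapse = ", "))
  bad_cat <- setdiff(unique(df$category), CONCEPT_CATEGORIES)
  if (length(bad_cat)) stop("lexicon load error: unknown category ", paste(bad_cat, collapse = ", "))
  if (any(!nzchar(df$pattern))) stop("lexicon load error: empty pattern at row ",
                                     which(!nzchar(df$pattern))[1])
  df$compiled <- vapply(df$pattern, .compile_pattern, "", USE.NAMES = FALSE)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ grepl(df$compiled[i], "probe", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("lexicon load error: pattern does not compile at row ", i,
                  " (", df$concept_id[i], ")")
  }
  if (!"notes" %in% names(df)) df$notes <- ""
  structure(list(entries = df, version = "1", path = path), class = "lexicon")
}

#' @rdname load_lexicon
#' @export
default_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_lexicon()
    cache
  }
})

# nodal lexemes whose in-sentence presence recategorizes a mass as a node
LYMPH_CONTEXT_RE <- "(?i)(?<![A-Za-z0-9])(?:lymph\\w*|node|nodes|nodal|adenopathy)(?![A-Za-z0-9])"

# adjectives that mark gravity-dependent (non-obstructive) atelectasis
ATELECTASIS_EXCLUDER_RE <- paste0(
  "(?i)(?<![A-Za-z0-9])(?:basal|basilar|bibasilar|bibasal|bilateral|",
  "subsegmental|dependent|gravity[- ]dependent|plate[- ]?like|discoid|linear|passive)",
  "(?![A-Za-z0-9])")

.find_all <- function(rx, text) {
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# longest-match-wins among overlapping hits of the same category
.resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-(hits$end - hits$start), hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[j]) next
      if (hits$category[i] == hits$category[j] &&
          hits$start[j] < hits$end[i] && hits$start[i] < hits$end[j] &&
          (hits$end[j] - hits$start[j]) <= (hits$end[i] - hits$start[i]))
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

#' Match lexicon concepts in one sentence
#'
#' Longest match wins among overlapping hits of the same category. A
#' tumor-mass lexeme accompanied in-sentence by an explicit nodal lexeme
#' ("lymph", "node", "nodal", ...) is recategorized as `lymph_node`
#' ("a (lymphnodal) subcarinal mass" describes a node); a nodal-station
#' word alone (e.g. "hilar") does not flip a mass, since "a perihilar mass"
#' usually is the tumor. Context flags start out false.
#'
#' @param sentence_text text of one sentence.
#' @param lexicon a [load_lexicon()] object.
#' @param sentence_index 0-based sentence ordinal recorded on each mention.
#' @param offset document-level character offset of the sentence start.
#' @return Data frame of concept mentions (document-level spans).
#' @export
match_concepts <- function(sentence_text, lexicon = default_lexicon(),
                           sentence_index = 0L, offset = 0L) {
  en <- lexicon$entries
  out <- list()
  for (i in seq_len(nrow(en))) {
    h <- .find_all(en$compiled[i], sentence_text)
    if (is.null(h)) next
    h$concept_id <- en$concept_id[i]
    h$snomed_code <- en$snomed_code[i]
    h$category <- en$category[i]
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(empty_table(CONCEPT_SCHEMA))
  hits <- .resolve_overlaps(do.call(rbind, out))
  if (nrow(hits) && any(hits$category == "tumor_mass") &&
      grepl(LYMPH_CONTEXT_RE, sentence_text, perl = TRUE))
    hits$category[hits$category == "tumor_mass"] <- "lymph_node"
  hits$index <- seq_len(nrow(hits)) - 1L
  hits$start <- hits$start + offset
  hits$end <- hits$end + offset
  hits$sentence <- sentence_index
  hits$negated <- FALSE; hits$uncertain <- FALSE; hits$historical <- FALSE
  hits$suppressed <- FALSE; hits$suppress_reason <- ""
  as_table(hits, CONCEPT_SCHEMA)
}

#' Pipeline stage: match concepts over a whole document
#'
#' Runs [match_concepts()] per non-heading sentence and stores all mentions.
#'
#' @param doc a preprocessed `annotation_document`.
#' @param lexicon a [load_lexicon()] object.
#' @return The updated document.
#' @export
pulmo_concepts <- function(doc, lexicon = default_lexicon()) {
  stopifnot(inherits(doc, "annotation_document"), "preprocess" %in% doc$stages_done)
  st <- doc$sentences
  out <- list()
  for (i in seq_len(nrow(st))) {
    if (st$is_heading[i]) next
    cp <- match_concepts(span_text(doc$text_processed, st$start[i], st$end[i]),
                         lexicon, sentence_index = st$index[i], offset = st$start[i])
    if (nrow(cp)) out[[length(out) + 1L]] <- cp
  }
  cps <- if (length(out)) do.call(rbind, out) else empty_table(CONCEPT_SCHEMA)
  if (nrow(cps)) cps$index <- seq_len(nrow(cps)) - 1L
  doc$concepts <- as_table(cps, CONCEPT_SCHEMA)
  doc$stages_done <- union(doc$stages_done, "concepts")
  validate_document(doc)
}

#' Apply blacklist and scope suppression
#'
#' Suppresses tumor-mass mentions and measurements in (1) sentences that
#' contain a blacklist term (kidney, liver, cyst, ...) — so a "benign cyst
#' in the right kidney measuring 2,3 cm" never becomes a tumor-size
#' candidate — and (2) sentences inside out-of-scope sections (abdomen,
#' bones, ...). Involvement-target mentions always survive. Additionally,
#' generic atelectasis presence mentions are suppressed when the sentence
#' carries a gravity-type adjective (basal, bilateral, subsegmental, ...),
#' which marks non-obstructive atelectasis; an explicitly post-obstructive
#' phrase is never suppressed by this rule.
#'
#' Suppression is recorded as a flag plus reason; suppressed records stay in
#' the document for inspection but are ignored downstream.
#'
#' @param doc document with concepts and measurements extracted.
#' @return The updated document.
#' @export
apply_blacklist <- function(doc) {
  stopifnot(inherits(doc, "annotation_document"))
  cp <- doc$concepts; ms <- doc$measurements; st <- doc$sentences; sc <- doc$sections
  if (!nrow(st)) return(doc)
  for (i in seq_len(nrow(st))) {
    sidx <- st$index[i]
    in_scope <- sc$in_scope[st$section[i] + 1L]
    ccur <- which(cp$sentence == sidx)
    mcur <- if (nrow(ms)) which(ms$sentence == sidx) else integer(0)
    has_blacklist <- any(cp$category[ccur] == "blacklist_term")
    reason <- if (has_blacklist) "blacklist term in sentence"
              else if (!in_scope) "out-of-scope section"
              else NULL
    if (!is.null(reason)) {
      tmi <- ccur[cp$category[ccur] == "tumor_mass" & !cp$suppressed[ccur]]
      cp$suppressed[tmi] <- TRUE; cp$suppress_reason[tmi] <- reason
      mi <- mcur[!ms$suppressed[mcur]]
      ms$suppressed[mi] <- TRUE; ms$suppress_reason[mi] <- reason
    }
    gen <- ccur[cp$concept_id[ccur] == "pres.atelectasis_generic" & !cp$suppressed[ccur]]
    if (length(gen)) {
      sent_text <- span_text(doc$text_processed, st$start[i], st$end[i])
      if (grepl(ATELECTASIS_EXCLUDER_RE, sent_text, perl = TRUE)) {
        cp$suppressed[gen] <- TRUE
        cp$suppress_reason[gen] <- "gravity-type atelectasis adjective"
      }
    }
  }
  doc$concepts <- as_table(cp, CONCEPT_SCHEMA)
  doc$measurements <- as_table(ms, MEASUREMENT_SCHEMA)
  doc
}
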