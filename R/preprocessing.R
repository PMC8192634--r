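# Preprocessing: length-preserving text cleaning, subheading-based section
# detection with a configurable scope policy, section-bounded sentence
# segmentation, and whitespace/separator tokenization.

TOKEN_RE <- "\\d+[.,]\\d+|\\d+|[A-Za-z]+|[^A-Za-z0-9\\s]"

#' Clean raw report text
#'
#' Normalizes line endings (`\r\n`, lone `\r`), non-breaking spaces, tabs and
#' other control characters to plain spaces/newlines. The transformation is
#' length-preserving and never deletes letters, digits or punctuation, so
#' every processed index maps to the same original index; the accompanying
#' offset map makes that correspondence explicit for consumers that
#' highlight spans on the original text.
#'
#' @param raw a single string.
#' @return A list with `text` (processed string) and `offset_map` (integer
#'   vector; `offset_map[i + 1]` is the original 0-based index of processed
#'   index `i`).
#' @export
clean_text <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("empty report: input text is empty or whitespace-only")
  x <- gsub("\r\n", " \n", raw, fixed = TRUE)
  x <- gsub("\r", "\n", x, fixed = TRUE)
  x <- gsub("\u00a0", " ", x, fixed = TRUE)
  x <- gsub("\t", " ", x, fixed = TRUE)
  x <- gsub("[\\x01-\\x08\\x0b\\x0c\\x0e-\\x1f]", " ", x, perl = TRUE)
  stopifnot(nchar(x) == nchar(raw))
  list(text = x, offset_map = seq_len(nchar(x)) - 1L)
}

#' Load a section policy
#'
#' A section policy maps heading patterns (matched case-insensitively at
#' line starts, optionally followed by `:`) to section categories and gives
#' the per-category scope decision. Out-of-scope sections are excluded as
#' sources of tumor-mass and tumor-size candidates.
#'
#' @param path YAML resource; defaults to the policy shipped with the package.
#' @return A list of class `section_policy`.
#' @export
load_section_policy <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "sections.yaml", package = "pulmostage")
  pol <- yaml::read_yaml(path)
  cats <- names(pol$categories)
  missing <- setdiff(SECTION_CATEGORIES, cats)
  if (length(missing)) stop("section policy missing categories: ", paste(missing, collapse = ", "))
  scope <- vapply(pol$categories, function(c) isTRUE(c$in_scope), TRUE)
  patterns <- lapply(pol$categories, function(c) as.character(unlist(c$patterns)))
  structure(list(patterns = patterns, scope = scope,
                 default_in_scope = isTRUE(pol$default_in_scope)),
            class = "section_policy")
}

#' Detect report sections from subheadings
#'
#' Headings are matched at line starts only, so mid-sentence anatomic words
#' (e.g. "chest") never open a section. Each section spans from its heading
#' to the next heading (or the end of the text); text before the first
#' heading, or a report with no recognized heading at all, becomes a single
#' `other` section, which is in scope.
#'
#' @param text processed report text.
#' @param policy a [load_section_policy()] object.
#' @return Data frame of sections (0-based half-open spans).
#' @export
detect_sections <- function(text, policy = load_section_policy()) {
  n <- nchar(text)
  hits <- list()
  for (cat in names(policy$patterns)) {
    pats <- policy$patterns[[cat]]
    if (!length(pats)) next
    rx <- sprintf("(?im)^[ \t]*(?:%s)[ \t]*(?::|$)", paste(pats, collapse = "|"))
    m <- gregexpr(rx, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      s <- as.integer(m[k]) - 1L
      e <- s + attr(m, "match.length")[k]
      hits[[length(hits) + 1L]] <- list(start = s, end = e, category = cat)
    }
  }
  secs <- empty_table(SECTION_SCHEMA)
  if (length(hits)) {
    h <- do.call(rbind, lapply(hits, as.data.frame, stringsAsFactors = FALSE))
    # at equal start the longest heading match wins (e.g. "Findings PET-CT")
    h <- h[order(h$start, -(h$end - h$start)), , drop = FALSE]
    h <- h[!duplicated(h$start), , drop = FALSE]
    # drop headings nested inside an earlier, longer heading match
    keep <- rep(TRUE, nrow(h))
    last_end <- -1L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] < last_end) keep[i] <- FALSE else last_end <- h$end[i]
    }
    h <- h[keep, , drop = FALSE]
    starts <- h$start; hends <- h$end; cats <- h$category
    rows <- list()
    if (starts[1] > 0L)
      rows[[1]] <- data.frame(heading_raw = "", category = "other", start = 0L,
                              end = starts[1], heading_end = 0L, stringsAsFactors = FALSE)
    for (i in seq_along(starts)) {
      send <- if (i < length(starts)) starts[i + 1L] else n
      raw <- trimws(sub(":\\s*$", "", span_text(text, starts[i], hends[i])))
      rows[[length(rows) + 1L]] <- data.frame(heading_raw = raw, category = cats[i],
                                              start = starts[i], end = send,
                                              heading_end = hends[i],
                                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df$index <- seq_len(nrow(df)) - 1L
    df$in_scope <- ifelse(df$category %in% names(policy$scope),
                          unname(policy$scope[df$category]), policy$default_in_scope)
    secs <- as_table(df, SECTION_SCHEMA)
  } else {
    secs <- as_table(data.frame(index = 0L, heading_raw = "", category = "other",
                                start = 0L, end = n, heading_end = 0L,
                                in_scope = TRUE, stringsAsFactors = FALSE),
                     SECTION_SCHEMA)
  }
  secs
}

# split points inside a body region: newlines, and whitespace after .!?
.sentence_spans <- function(text, from, to) {
  body <- span_text(text, from, to)
  if (!nzchar(trimws(body))) return(NULL)
  m <- gregexpr("(?<=[.!?])[ \t]+|\n+", body, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  lens <- if (m[1] == -1L) integer(0) else attr(m, "match.length")
  starts <- c(0L, cuts + lens)
  ends <- c(cuts, nchar(body))
  out <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e <= s) next
    seg <- substring(body, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (e2 > s2) out[[length(out) + 1L]] <- c(from + s2, from + e2)
  }
  out
}

#' Segment a report into sentences
#'
#' Sentences never cross section boundaries. Splitting happens at newlines
#' and at whitespace following `.`, `!` or `?`; a decimal point inside a
#' measurement (`3.1 cm`) is never a split point because it is not followed
#' by whitespace. A section body without a terminal period yields a single
#' sentence. The heading line of a section becomes its own sentence, marked
#' `is_heading`, and is skipped by concept matching.
#'
#' @param text processed report text.
#' @param sections data frame from [detect_sections()].
#' @return Data frame of sentences (token ranges filled by [tokenize_document()]).
#' @export
segment_sentences <- function(text, sections) {
  rows <- list()
  for (i in seq_len(nrow(sections))) {
    sec <- sections[i, ]
    if (sec$heading_end > sec$start) {
      hs <- .sentence_spans(text, sec$start, sec$heading_end)
      for (sp in hs) rows[[length(rows) + 1L]] <-
        data.frame(start = sp[1], end = sp[2], section = sec$index,
                   is_heading = TRUE, stringsAsFactors = FALSE)
    }
    body_from <- max(sec$start, sec$heading_end)
    for (sp in .sentence_spans(text, body_from, sec$end))
      rows[[length(rows) + 1L]] <-
        data.frame(start = sp[1], end = sp[2], section = sec$index,
                   is_heading = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_table(SENTENCE_SCHEMA))
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  df$index <- seq_len(nrow(df)) - 1L
  df$token_start <- 0L; df$token_end <- 0L
  as_table(df, SENTENCE_SCHEMA)
}

#' Tokenize text
#'
#' Tokens cover all non-whitespace characters. Numbers with a decimal comma
#' or point (`8,6`, `3.1`) are single tokens; dimension separators (`x`,
#' `×`) and other punctuation are separate single-character tokens.
#'
#' @param text a string (typically one sentence).
#' @return Data frame of tokens with 0-based half-open spans into `text`.
#' @export
tokenize <- function(text) {
  if (!nzchar(text)) return(empty_table(TOKEN_SCHEMA))
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_table(TOKEN_SCHEMA))
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  as_table(data.frame(index = seq_along(starts) - 1L,
                      text = span_text(text, starts, ends),
                      start = starts, end = ends, stringsAsFactors = FALSE),
           TOKEN_SCHEMA)
}

# tokenize every sentence, assigning document-level spans and token ranges
tokenize_document <- function(doc) {
  st <- doc$sentences
  tokens <- list(); idx <- 0L
  for (i in seq_len(nrow(st))) {
    tk <- tokenize(span_text(doc$text_processed, st$start[i], st$end[i]))
    st$token_start[i] <- idx
    if (nrow(tk)) {
      tk$index <- idx + seq_len(nrow(tk)) - 1L
      tk$start <- tk$start + st$start[i]
      tk$end <- tk$end + st$start[i]
      idx <- idx + nrow(tk)
      tokens[[length(tokens) + 1L]] <- tk
    }
    st$token_end[i] <- idx
  }
  doc$tokens <- if (length(tokens)) as_table(do.call(rbind, tokens), TOKEN_SCHEMA)
                else empty_table(TOKEN_SCHEMA)
  doc$sentences <- as_table(st, SENTENCE_SCHEMA)
  doc
}

#' Pipeline stage: preprocess a report
#'
#' Cleans the text, detects sections, segments sentences and tokenizes,
#' producing a document ready for concept matching. Idempotent: outputs are
#' recomputed deterministically from the report.
#'
#' @param doc an `annotation_document` or anything accepted by
#'   [annotation_document()].
#' @param policy section policy (default: shipped resource).
#' @return The updated document.
#' @export
pulmo_preprocess <- function(doc, policy = load_section_policy()) {
  if (!inherits(doc, "annotation_document")) doc <- annotation_document(doc)
  cl <- clean_text(doc$report$text)
  doc$text_processed <- cl$text
  doc$offset_map <- cl$offset_map
  doc$sections <- detect_sections(cl$text, policy)
  doc$sentences <- segment_sentences(cl$text, doc$sections)
  doc <- tokenize_document(doc)
  doc$stages_done <- union(doc$stages_done, "preprocess")
  validate_document(doc)
}
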