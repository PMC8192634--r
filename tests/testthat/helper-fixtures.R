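# Shared fixtures: resources are loaded once per test run; small corpora are
# generated in code under fixed seeds.

LEX <- default_lexicon()
MODS <- default_modifiers()
POLICY <- load_section_policy()
TNM <- default_tnm_table()

small_corpus <- function(n = 30, seed = 101, clean = FALSE) {
  spec <- if (clean) synth_spec(n, seed, distractor_rates = 0) else synth_spec(n, seed)
  generate_corpus(spec)
}

# derive a literal example string from one of the lexicon's restricted
# regex patterns (first alternative, optional groups kept)
sample_pattern <- function(p) {
  chars <- strsplit(p, "")[[1]]
  depth <- 0L; cls <- FALSE; cut <- nchar(p) + 1L; i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\") { i <- i + 2L; next }
    if (cls) { if (ch == "]") cls <- FALSE }
    else if (ch == "[") cls <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "|" && depth == 0L) { cut <- i; break }
    i <- i + 1L
  }
  s <- substr(p, 1L, cut - 1L)
  for (k in 1:5) {
    s <- gsub("\\(\\?:([^()|]*)(?:\\|[^()]*)?\\)\\?", "\\1", s)
    s <- gsub("\\(\\?:([^()|]*)(?:\\|[^()]*)?\\)", "\\1", s)
  }
  s <- gsub("\\[([^]])[^]]*\\]", "\\1", s)
  s <- gsub("([A-Za-z -])\\?", "\\1", s)
  s
}

# scope-assignment oracle: literal restatement of the direction/termination
# rules, enumerating (modifier, concept) pairs
oracle_flags <- function(sentence, modifiers, concepts) {
  flags <- data.frame(negated = rep(FALSE, nrow(concepts)),
                      uncertain = FALSE, historical = FALSE)
  colmap <- c(negation = "negated", uncertainty = "uncertain",
              historical = "historical")
  for (i in seq_len(nrow(modifiers))) {
    m <- modifiers[i, ]
    if (!m$category %in% names(colmap)) next
    others <- modifiers[-i, , drop = FALSE]
    cutters <- others[others$category %in% c("termination", "negation",
                                             "uncertainty", "historical"), ,
                      drop = FALSE]
    regions <- list()
    if (m$direction %in% c("forward", "bidirectional")) {
      ends <- cutters$start[cutters$start >= m$end]
      regions[[length(regions) + 1L]] <-
        c(m$end, if (length(ends)) min(ends) else sentence$end)
    }
    if (m$direction %in% c("backward", "bidirectional")) {
      starts <- cutters$end[cutters$end <= m$start]
      regions[[length(regions) + 1L]] <-
        c(if (length(starts)) max(starts) else sentence$start, m$start)
    }
    for (r in regions) {
      hit <- concepts$start >= r[1] & concepts$end <= r[2] &
        concepts$category != "blacklist_term"
      flags[[colmap[[m$category]]]] <- flags[[colmap[[m$category]]]] | hit
    }
  }
  flags
}
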