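# Measurement extraction: dimensioned sizes with a mandatory unit,
# normalized to millimetres; linking of each size to the nearest concept
# mention and to a lobe; consolidation of linked sizes into tumor findings.

.NUM_RE <- "\\d+(?:[.,]\\d+)?"
.AXIS_RE <- "(?:\\s*\\([A-Za-z]{1,4}\\))?"
.SEP_RE <- "\\s*[x×]\\s*"
MEASUREMENT_RE <- paste0(
  "(?<![A-Za-z0-9.,])",
  "(", .NUM_RE, ")", .AXIS_RE,
  "(?:", .SEP_RE, "(", .NUM_RE, ")", .AXIS_RE,
  "(?:", .SEP_RE, "(", .NUM_RE, ")", .AXIS_RE, ")?)?",
  "\\s*(mm|cm)(?![A-Za-z0-9])")

.parse_magnitude <- function(x) as.numeric(sub(",", ".", x, fixed = TRUE))

# map anatomic_location concept ids to (laterality, lobe)
LOC_MAP <- list(
  loc.rul = c("right", "RUL"), loc.rml = c("right", "RML"), loc.rll = c("right", "RLL"),
  loc.lul = c("left", "LUL"), loc.lll = c("left", "LLL"),
  loc.lingula = c("left", "unknown"),
  loc.right_lung = c("right", "unknown"), loc.left_lung = c("left", "unknown"))

#' Extract dimensioned measurements from one sentence
#'
#' Recognizes single values (`3 cm`, `14 mm`), decimal comma and point
#' (`8,6 cm`, `3.1 cm`), two/three-dimension tuples with `x`/`×` separators
#' sharing one trailing unit (`3.1 x 2.4 x 1.8 cm`) and axis-labelled
#' tuples (`2.1 (AP) × 3.0 (TVR) × 1.8 (SI) cm`). A number with no unit in
#' the measurement expression is never emitted — the unit requirement is a
#' deliberate precision guard. Ranges (`1-2 cm`) are skipped as ambiguous.
#' `max_dim_mm` is the largest dimension converted to millimetres.
#'
#' @param sentence_text text of one sentence.
#' @param sentence_index 0-based sentence ordinal.
#' @param offset document-level offset of the sentence start.
#' @return Data frame of measurements (document-level spans).
#' @export
extract_measurements <- function(sentence_text, sentence_index = 0L, offset = 0L) {
  m <- gregexec(MEASUREMENT_RE, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_table(MEASUREMENT_SCHEMA))
  starts <- as.integer(m[1, ]) - 1L
  lens <- attr(m, "match.length")[1, ]
  groups <- regmatches(sentence_text, list(m))[[1]]
  rows <- list()
  for (k in seq_along(starts)) {
    before <- substring(sentence_text, 1L, starts[k])
    if (grepl("[0-9][ \t]*[-–][ \t]*$", before, perl = TRUE)) next  # range, e.g. 1-2 cm
    g <- groups[, k]
    mags <- .parse_magnitude(g[2:4][nzchar(g[2:4])])
    if (!length(mags) || any(mags <= 0)) next
    unit <- g[5]
    rows[[length(rows) + 1L]] <- data.frame(
      mag1 = mags[1], mag2 = if (length(mags) >= 2) mags[2] else NA_real_,
      mag3 = if (length(mags) >= 3) mags[3] else NA_real_,
      unit = unit, max_dim_mm = max(mags) * if (unit == "cm") 10 else 1,
      start = starts[k] + offset, end = starts[k] + lens[k] + offset,
      sentence = sentence_index, suppressed = FALSE, suppress_reason = "",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_table(MEASUREMENT_SCHEMA))
  df <- do.call(rbind, rows)
  df$index <- seq_len(nrow(df)) - 1L
  as_table(df, MEASUREMENT_SCHEMA)
}

#' Link measurements to concept mentions
#'
#' Each unsuppressed measurement is linked to the nearest unflagged
#' tumor-mass, lymph-node or involvement-target mention in its sentence —
#' preferring the nearest preceding mention, falling back to the nearest
#' following one. Laterality and lobe come from the nearest
#' anatomic-location mention in the sentence. A measurement linked to a
#' lymph node or involvement target never becomes a tumor size; a
#' measurement with no linkable mention is left unlinked and logged.
#'
#' @param doc document with concepts and measurements extracted and the
#'   blacklist applied.
#' @return The updated document (fills the `links` table).
#' @export
link_measurements <- function(doc) {
  cp <- doc$concepts; ms <- doc$measurements
  links <- list()
  for (k in seq_len(nrow(ms))) {
    if (ms$suppressed[k]) next
    cand <- which(cp$sentence == ms$sentence[k] &
                    cp$category %in% c("tumor_mass", "lymph_node", "involvement_target") &
                    !cp$suppressed & !cp$negated & !cp$uncertain)
    if (!length(cand)) {
      doc$log <- c(doc$log, sprintf("unlinked measurement (%s mm) in sentence %d",
                                    format(ms$max_dim_mm[k]), ms$sentence[k]))
      next
    }
    prec <- cand[cp$end[cand] <= ms$start[k]]
    foll <- cand[cp$start[cand] >= ms$end[k]]
    tgt <- if (length(prec)) prec[which.max(cp$end[prec])]
           else if (length(foll)) foll[which.min(cp$start[foll])]
           else cand[1]
    locs <- which(cp$sentence == ms$sentence[k] & cp$category == "anatomic_location")
    lat <- "unknown"; lobe <- "unknown"
    if (length(locs)) {
      d <- pmin(abs(cp$start[locs] - cp$end[tgt]), abs(cp$end[locs] - cp$start[tgt]))
      best <- locs[which.min(d)]
      info <- LOC_MAP[[cp$concept_id[best]]]
      if (!is.null(info)) { lat <- info[1]; lobe <- info[2] }
    }
    links[[length(links) + 1L]] <- data.frame(
      measurement = ms$index[k], concept = cp$index[tgt],
      category = cp$category[tgt], laterality = lat, lobe = lobe,
      stringsAsFactors = FALSE)
  }
  doc$links <- if (length(links)) as_table(do.call(rbind, links), LINK_SCHEMA)
               else empty_table(LINK_SCHEMA)
  doc
}

.lobe_laterality <- function(lobe) {
  if (lobe %in% c("RUL", "RML", "RLL")) "right"
  else if (lobe %in% c("LUL", "LLL")) "left"
  else "unknown"
}

# presence kind implied by a presence_finding concept id
.presence_kind <- function(concept_id) {
  switch(concept_id,
         pres.post_obstructive_atelectasis = ,
         pres.obstructive_pneumonitis = ,
         pres.atelectasis_generic = "post_obstructive_atelectasis",
         pres.satellite = "satellite_same_lobe",
         NA_character_)
}

#' Consolidate linked sizes and mentions into tumor findings
#'
#' The largest tumor-linked size becomes the primary finding. A second
#' sized tumor mention in the same lobe (or with unknown site) is treated
#' as a repeated description of the same tumor: the larger size is kept and
#' a warning is logged when the sizes differ. A sized tumor in a different
#' ipsilateral lobe becomes a `nodule_ipsilateral_other_lobe` finding and a
#' presence item carrying its size; contralateral nodules are outside the T
#' domain and only logged. Unflagged, unsuppressed involvement and presence
#' mentions attach to the primary (tiers taken from the decision table, not
#' from the mention). When no sized tumor exists but tumor, involvement or
#' presence mentions do, a primary with absent size is created so criteria
#' that need no size can still stage the report.
#'
#' @param doc document with measurements linked.
#' @param table decision table from [load_tnm_table()].
#' @return The updated document (fills `findings`).
#' @export
consolidate_findings <- function(doc, table = default_tnm_table()) {
  cp <- doc$concepts; ms <- doc$measurements; lk <- doc$links
  doc$findings <- list()
  tumor_links <- lk[lk$category == "tumor_mass", , drop = FALSE]
  sized <- list()
  if (nrow(tumor_links)) {
    for (i in seq_len(nrow(tumor_links))) {
      mrow <- ms[ms$index == tumor_links$measurement[i], ]
      crow <- cp[cp$index == tumor_links$concept[i], ]
      sized[[i]] <- data.frame(size = mrow$max_dim_mm,
                               laterality = tumor_links$laterality[i],
                               lobe = tumor_links$lobe[i],
                               descriptor = span_text(doc$text_processed, crow$start, crow$end),
                               stringsAsFactors = FALSE)
    }
  }
  inv_idx <- which(cp$category == "involvement_target" &
                     !cp$suppressed & !cp$negated & !cp$uncertain)
  pres_idx <- which(cp$category == "presence_finding" &
                      !cp$suppressed & !cp$negated & !cp$uncertain)
  tumor_idx <- which(cp$category == "tumor_mass" &
                       !cp$suppressed & !cp$negated & !cp$uncertain)
  involvement <- if (length(inv_idx)) data.frame(
    structure = sub("^inv\\.", "", cp$concept_id[inv_idx]),
    snomed_code = cp$snomed_code[inv_idx],
    tier = NA_character_, source = cp$index[inv_idx], stringsAsFactors = FALSE)
    else NULL
  if (!is.null(involvement)) {
    involvement <- involvement[!duplicated(involvement$structure), , drop = FALSE]
    involvement$tier <- vapply(involvement$structure, function(s)
      involvement_tier(s, table), "")
  }
  presence_rows <- list()
  for (j in pres_idx) {
    kind <- .presence_kind(cp$concept_id[j])
    if (is.na(kind)) next
    presence_rows[[length(presence_rows) + 1L]] <- data.frame(
      kind = kind, qualifier_size_mm = NA_real_, source = cp$index[j],
      stringsAsFactors = FALSE)
  }

  findings <- list()
  if (length(sized)) {
    sz <- do.call(rbind, sized)
    ord <- order(-sz$size)
    sz <- sz[ord, , drop = FALSE]
    prim <- sz[1, ]
    merged_size <- prim$size
    secondaries <- list()
    if (nrow(sz) > 1) for (i in 2:nrow(sz)) {
      row <- sz[i, ]
      same_site <- (row$lobe == prim$lobe && row$laterality == prim$laterality) ||
        row$lobe == "unknown" || prim$lobe == "unknown"
      if (same_site) {
        if (row$size != merged_size)
          doc$log <- c(doc$log, sprintf(
            "different sizes for the same tumor (%g mm vs %g mm); larger used",
            merged_size, row$size))
      } else if (row$laterality == prim$laterality || row$laterality == "unknown") {
        secondaries[[length(secondaries) + 1L]] <- row
      } else {
        doc$log <- c(doc$log, sprintf(
          "contralateral nodule (%g mm, %s) ignored for T staging", row$size, row$lobe))
      }
    }
    for (s in secondaries) {
      presence_rows[[length(presence_rows) + 1L]] <- data.frame(
        kind = "nodule_ipsilateral_other_lobe", qualifier_size_mm = s$size,
        source = NA_integer_, stringsAsFactors = FALSE)
    }
    presence <- if (length(presence_rows)) do.call(rbind, presence_rows) else NULL
    findings[[1]] <- tumor_finding("primary", prim$laterality, prim$lobe,
                                   prim$descriptor, merged_size,
                                   involvement = involvement, presence = presence)
    for (s in secondaries)
      findings[[length(findings) + 1L]] <-
        tumor_finding("nodule_ipsilateral_other_lobe", s$laterality, s$lobe,
                      s$descriptor, s$size)
  } else if (length(tumor_idx) || length(inv_idx) || length(presence_rows)) {
    desc <- if (length(tumor_idx))
      span_text(doc$text_processed, cp$start[tumor_idx[1]], cp$end[tumor_idx[1]]) else ""
    presence <- if (length(presence_rows)) do.call(rbind, presence_rows) else NULL
    findings[[1]] <- tumor_finding("primary", descriptor = desc, size_mm = NA_real_,
                                   involvement = involvement, presence = presence)
    if (length(tumor_idx) && !length(sized))
      doc$log <- c(doc$log, "tumor mention without a dimensioned size; size component absent")
  }
  doc$findings <- findings
  doc
}

#' Pipeline stage: measurements, blacklist, linking and consolidation
#'
#' @param doc document after context validation.
#' @param table decision table from [load_tnm_table()].
#' @return The updated document.
#' @export
pulmo_measurements <- function(doc, table = default_tnm_table()) {
  stopifnot(inherits(doc, "annotation_document"), "context" %in% doc$stages_done)
  doc$log <- character(0)  # this stage owns the per-document warning log
  st <- doc$sentences
  out <- list()
  for (i in seq_len(nrow(st))) {
    if (st$is_heading[i]) next
    m <- extract_measurements(span_text(doc$text_processed, st$start[i], st$end[i]),
                              sentence_index = st$index[i], offset = st$start[i])
    if (nrow(m)) out[[length(out) + 1L]] <- m
  }
  mss <- if (length(out)) do.call(rbind, out) else empty_table(MEASUREMENT_SCHEMA)
  if (nrow(mss)) mss$index <- seq_len(nrow(mss)) - 1L
  doc$measurements <- as_table(mss, MEASUREMENT_SCHEMA)
  doc <- apply_blacklist(doc)
  doc <- link_measurements(doc)
  doc <- consolidate_findings(doc, table)
  doc$stages_done <- union(doc$stages_done, "measurements")
  validate_document(doc)
}
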