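# T-substage decision table (AJCC/TNM 8th edition descriptors for lung) and
# the classifier that maps (size, involvement, presence) to the final
# T substage as the maximum of the three component stages.

#' Load a T-stage decision table
#'
#' The table is a versioned YAML resource holding the size breakpoints in
#' millimetres (each class is "> lower, <= upper"; above the last
#' breakpoint is T4), the involvement tier map (structure -> minimum T
#' tier), the presence map, and the minimum size for a nodule in a
#' different ipsilateral lobe to count as T4 (10 mm — the classification
#' itself leaves this open, so the threshold is an explicit, configurable
#' rule). Shipping the table as a resource lets future TNM editions be
#' swapped in for restaging historical reports.
#'
#' @param path YAML resource; defaults to the AJCC8 table shipped with the
#'   package.
#' @return A list of class `tnm_table`.
#' @export
load_tnm_table <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "tnm_ajcc8.yaml", package = "pulmostage")
  tab <- yaml::read_yaml(path)
  bp <- unlist(tab$size_breakpoints_mm)
  if (is.unsorted(bp, strictly = TRUE)) stop("size breakpoints must be strictly increasing")
  tiers <- tab$involvement_tiers
  all_structures <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(all_structures))
    stop("an involvement structure appears in more than one tier")
  tier_of <- character(0)
  for (tier in names(tiers)) tier_of[unlist(tiers[[tier]])] <- tier
  structure(list(version = tab$version, breakpoints = bp, tier_of = tier_of,
                 presence_map = unlist(tab$presence_map),
                 nodule_min_size_mm = as.numeric(tab$nodule_min_size_mm)),
            class = "tnm_table")
}

#' @rdname load_tnm_table
#' @export
default_tnm_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_tnm_table()
    cache
  }
})

#' Size component of the T stage
#'
#' Boundary values are inclusive on the lower class: 10 mm is T1a, 30 mm is
#' T1c. An absent size yields an absent component.
#'
#' @param size_mm largest tumor dimension in millimetres, or `NA`.
#' @param table a [load_tnm_table()] object.
#' @return A T label or `NA_character_`.
#' @export
size_to_t <- function(size_mm, table = default_tnm_table()) {
  if (is.null(size_mm) || is.na(size_mm)) return(NA_character_)
  if (size_mm <= 0) stop("size_mm must be positive")
  bp <- table$breakpoints
  i <- which(size_mm <= bp)
  if (length(i)) names(bp)[i[1]] else "T4"
}

# tier of one involvement structure; unknown structures are a configuration
# error (the lexicon and the decision table must agree)
involvement_tier <- function(structure, table = default_tnm_table()) {
  tier <- table$tier_of[structure]
  if (is.na(tier)) stop("configuration error: unknown involvement structure '",
                        structure, "'")
  unname(tier)
}

#' Involvement component of the T stage
#'
#' The component is the highest tier among the involved structures; the
#' items must already be certain (non-negated, non-uncertain) — context
#' filtering happens upstream.
#'
#' @param structures character vector of involved structure names.
#' @param table a [load_tnm_table()] object.
#' @return A T label or `NA_character_` for an empty set.
#' @export
involvement_to_t <- function(structures, table = default_tnm_table()) {
  structures <- unique(structures[!is.na(structures)])
  if (!length(structures)) return(NA_character_)
  stage_max(vapply(structures, involvement_tier, "", table = table))
}

#' Presence component of the T stage
#'
#' Post-obstructive atelectasis and main-bronchus presence map to T2, a
#' satellite nodule in the same lobe to T3 (no minimum size), and a nodule
#' in a different ipsilateral lobe to T4 only when larger than the table's
#' minimum (default 10 mm) — a smaller or unsized nodule contributes
#' nothing. Gravity-type atelectasis must be excluded upstream.
#'
#' @param presence data frame with columns `kind` and `qualifier_size_mm`
#'   (or a character vector of kinds, all unsized).
#' @param table a [load_tnm_table()] object.
#' @return A T label or `NA_character_` for an empty set.
#' @export
presence_to_t <- function(presence, table = default_tnm_table()) {
  if (is.character(presence)) {
    if (!length(presence)) return(NA_character_)
    presence <- data.frame(kind = presence, qualifier_size_mm = NA_real_,
                           stringsAsFactors = FALSE)
  }
  if (is.null(presence) || !nrow(presence)) return(NA_character_)
  bad <- setdiff(presence$kind, PRESENCE_KINDS)
  if (length(bad)) stop("unknown presence kind: ", paste(bad, collapse = ", "))
  labels <- character(0)
  for (i in seq_len(nrow(presence))) {
    kind <- presence$kind[i]
    if (kind == "nodule_ipsilateral_other_lobe") {
      q <- presence$qualifier_size_mm[i]
      if (!is.na(q) && q > table$nodule_min_size_mm)
        labels <- c(labels, unname(table$presence_map[kind]))
    } else {
      labels <- c(labels, unname(table$presence_map[kind]))
    }
  }
  stage_max(labels)
}

# classifier core on plain component inputs; returns the label only
stage_components <- function(size_mm, structures, presence, table = default_tnm_table()) {
  sc <- size_to_t(size_mm, table)
  ic <- involvement_to_t(structures, table)
  pc <- presence_to_t(presence, table)
  label <- stage_max(c(sc, ic, pc))
  if (is.na(label)) label <- "Tx"
  if (label == "T2" && !is.na(size_mm)) {
    # a bare-T2 criterion with a known size resolves to the size substage
    label <- if (size_mm <= table$breakpoints[["T2a"]]) "T2a"
             else if (size_mm <= table$breakpoints[["T2b"]]) "T2b"
             else label
  }
  list(label = label, size = sc, involvement = ic, presence = pc)
}

#' Classify the T stage of consolidated findings
#'
#' The final label is the maximum of the size, involvement and presence
#' components under the order `Tx < T1a < T1b < T1c < T2 < T2a < T2b < T3 <
#' T4`. A bare T2 criterion (e.g. main-bronchus involvement) combined with
#' a known size resolves to T2a (size <= 40 mm) or T2b (size <= 50 mm);
#' without a size the bare `T2` label stands. `Tx` is emitted when all
#' components are absent — i.e. no tumor evidence was extracted.
#'
#' @param findings list of [tumor_finding()] objects (or a single one).
#' @param table a [load_tnm_table()] object.
#' @return A `tstage_result` with per-component labels and human-readable
#'   rationale strings.
#' @export
classify_t <- function(findings, table = default_tnm_table()) {
  if (inherits(findings, "tumor_finding")) findings <- list(findings)
  size_mm <- NA_real_
  structures <- character(0)
  pres_parts <- list()
  for (f in findings) {
    if (f$role == "primary") size_mm <- f$size_mm
    structures <- c(structures, f$involvement$structure)
    if (nrow(f$presence)) pres_parts[[length(pres_parts) + 1L]] <- f$presence
  }
  pres <- if (!length(pres_parts)) NULL
          else if (length(pres_parts) == 1L) pres_parts[[1]]
          else do.call(rbind, pres_parts)
  comp <- stage_components(size_mm, structures, pres, table)
  rationale <- character(0)
  if (!is.na(comp$size))
    rationale <- c(rationale, sprintf("size %g mm -> %s", size_mm, comp$size))
  if (!is.na(comp$involvement))
    rationale <- c(rationale, sprintf("involvement {%s} -> %s",
                                      paste(unique(structures), collapse = ", "),
                                      comp$involvement))
  if (!is.na(comp$presence))
    rationale <- c(rationale, sprintf("presence {%s} -> %s",
                                      paste(unique(pres$kind), collapse = ", "),
                                      comp$presence))
  sub <- if (is.null(pres)) integer(0)
         else which(pres$kind == "nodule_ipsilateral_other_lobe" &
                      (is.na(pres$qualifier_size_mm) |
                         pres$qualifier_size_mm <= table$nodule_min_size_mm))
  if (length(sub))
    rationale <- c(rationale, sprintf(
      "ipsilateral other-lobe nodule at or below %g mm: no T4 contribution",
      table$nodule_min_size_mm))
  if (comp$label == "Tx")
    rationale <- c(rationale, "no tumor evidence extracted")
  tstage_result(comp$label, comp$size, comp$involvement, comp$presence, rationale)
}

#' Pipeline stage: classify the document
#'
#' @param doc document with consolidated findings.
#' @param table a [load_tnm_table()] object.
#' @return The updated document with `result` set.
#' @export
pulmo_classify <- function(doc, table = default_tnm_table()) {
  stopifnot(inherits(doc, "annotation_document"), "measurements" %in% doc$stages_done)
  doc$result <- classify_t(doc$findings, table)
  doc$stages_done <- union(doc$stages_done, "classify")
  validate_document(doc)
}
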