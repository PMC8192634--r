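# Seeded generator of English staging reports with gold T-substage labels
# and planted findings. Reports follow a template grammar with lexical
# variation sampled from the concept lexicon itself, which guarantees that
# the gold label is computable from the planted findings; three report
# formats are emulated (plain CT, blended PET-CT, sectioned PET-CT), and
# configurable distractor constructs exercise the pipeline defenses
# (blacklist, gravity-atelectasis adjectives, negation/uncertainty scope,
# the unit requirement, nodal-station lymph nodes).

DISTRACTOR_KINDS <- c("benign_cyst", "gravity_atelectasis", "negated_involvement",
                      "uncertain_involvement", "lymph_node_station", "unitless_size")
DIALECT_KINDS <- c("decimal_comma", "triple_dimension", "axis_labels")

#' Specification for a synthetic corpus
#'
#' Defaults emulate the composition of a staging cohort: the substage
#' weights follow the training-cohort distribution (T1a under-represented,
#' T1c/T2a/T3 common), the format mix is roughly half plain CT reports with
#' the rest PET-based, and distractor/dialect rates reflect how often the
#' corresponding constructs plausibly occur in clinical dictation.
#'
#' @param n number of reports.
#' @param seed integer seed; the corpus is a pure function of the spec.
#' @param format_mix named proportions over CT, PET, PET-CT.
#' @param substage_distribution named non-negative weights over T labels.
#' @param distractor_rates named probabilities per distractor kind, or a
#'   single number recycled to all kinds (0 disables all distractors).
#' @param dialect_rates named probabilities for decimal-comma sizes,
#'   three-dimension tuples and axis-labelled tuples.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n, seed = 1L,
                       format_mix = c(CT = 0.53, PET = 0.385, "PET-CT" = 0.085),
                       substage_distribution = c(T1a = 4, T1b = 27, T1c = 42,
                                                 T2 = 6, T2a = 32, T2b = 27,
                                                 T3 = 33, T4 = 29),
                       distractor_rates = c(benign_cyst = 0.30,
                                            gravity_atelectasis = 0.35,
                                            negated_involvement = 0.25,
                                            uncertain_involvement = 0.25,
                                            lymph_node_station = 0.40,
                                            unitless_size = 0.15),
                       dialect_rates = c(decimal_comma = 0.20,
                                         triple_dimension = 0.30,
                                         axis_labels = 0.10)) {
  stopifnot(n >= 0, length(seed) == 1L)
  if (length(distractor_rates) == 1L && is.null(names(distractor_rates)))
    distractor_rates <- stats::setNames(rep(distractor_rates, length(DISTRACTOR_KINDS)),
                                        DISTRACTOR_KINDS)
  stopifnot(setequal(names(distractor_rates), DISTRACTOR_KINDS),
            all(distractor_rates >= 0 & distractor_rates <= 1),
            setequal(names(dialect_rates), DIALECT_KINDS),
            all(dialect_rates >= 0 & dialect_rates <= 1),
            all(substage_distribution >= 0), sum(substage_distribution) > 0,
            all(names(substage_distribution) %in% T_LEVELS),
            setequal(names(format_mix), c("CT", "PET", "PET-CT")))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 format_mix = format_mix / sum(format_mix),
                 substage_distribution = substage_distribution,
                 distractor_rates = distractor_rates[DISTRACTOR_KINDS],
                 dialect_rates = dialect_rates[DIALECT_KINDS]),
            class = "synth_spec")
}

.TUMOR_SYNONYMS <- c("mass", "nodule", "lesion", "tumor")
.T2_CRITERIA <- list(list(inv = "main_bronchus"), list(inv = "visceral_pleura"),
                     list(pres = "post_obstructive_atelectasis"))
.T3_STRUCTURES <- c("chest_wall", "parietal_pericardium", "phrenic_nerve")
.T4_STRUCTURES <- c("mediastinum", "diaphragm", "vertebral_body", "carina", "esophagus")
.LOBE_PHRASE <- c(RUL = "right upper lobe", RML = "right middle lobe",
                  RLL = "right lower lobe", LUL = "left upper lobe",
                  LLL = "left lower lobe")
.STRUCTURE_PHRASE <- c(
  main_bronchus = "the main bronchus", visceral_pleura = "the visceral pleura",
  chest_wall = "the adjacent chest wall",
  parietal_pericardium = "the parietal pericardium",
  phrenic_nerve = "the phrenic nerve", mediastinum = "the mediastinum",
  diaphragm = "the diaphragm", heart = "the heart",
  great_vessels = "the great vessels", trachea = "the trachea",
  carina = "the carina", esophagus = "the esophagus",
  recurrent_laryngeal_nerve = "the recurrent laryngeal nerve",
  vertebral_body = "the adjacent vertebral body")

.snomed_of <- function(structure) {
  en <- default_lexicon()$entries
  code <- en$snomed_code[en$concept_id == paste0("inv.", structure)]
  if (length(code)) code else ""
}

.rint <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1))
.pick <- function(x) x[[.rint(1, length(x))]]
.flip <- function(p) stats::runif(1) < p

# ---- gold plans ------------------------------------------------------------

# build the planted findings for one report; self-consistency with the gold
# label is asserted by the caller
.build_plan <- function(label, table) {
  lobe <- .pick(names(.LOBE_PHRASE))
  lat <- .lobe_laterality(lobe)
  size <- NA_real_; structures <- character(0); pres_kinds <- character(0)
  nodule <- NULL
  switch(label,
    T1a = { size <- .rint(6, 10) },
    T1b = { size <- .rint(11, 20) },
    T1c = { size <- .rint(21, 30) },
    T2a = {
      if (.flip(0.6)) size <- .rint(31, 40)
      else {
        size <- .rint(15, 30)
        crit <- .pick(.T2_CRITERIA)
        if (!is.null(crit$inv)) structures <- crit$inv else pres_kinds <- crit$pres
      }
    },
    T2b = {
      size <- .rint(41, 50)
      if (.flip(0.3)) {
        crit <- .pick(.T2_CRITERIA)
        if (!is.null(crit$inv)) structures <- crit$inv else pres_kinds <- crit$pres
      }
    },
    T2 = {
      crit <- .pick(.T2_CRITERIA)
      if (!is.null(crit$inv)) structures <- crit$inv else pres_kinds <- crit$pres
    },
    T3 = {
      u <- stats::runif(1)
      if (u < 0.45) size <- .rint(51, 70)
      else if (u < 0.80) { size <- .rint(15, 45); structures <- .pick(.T3_STRUCTURES) }
      else { size <- .rint(15, 45); pres_kinds <- "satellite_same_lobe" }
    },
    T4 = {
      u <- stats::runif(1)
      if (u < 0.40) size <- .rint(71, 95)
      else if (u < 0.75) { size <- .rint(20, 60); structures <- .pick(.T4_STRUCTURES) }
      else {
        size <- .rint(25, 60)
        nodule <- list(size = .rint(12, min(24, size - 1)),
                       lobe = .pick(setdiff(names(.LOBE_PHRASE)[
                         vapply(names(.LOBE_PHRASE), .lobe_laterality, "") == lat], lobe)))
      }
    },
    stop("plan error: no template for label ", label)
  )
  involvement <- if (length(structures)) data.frame(
    structure = structures, snomed_code = vapply(structures, .snomed_of, ""),
    tier = vapply(structures, involvement_tier, "", table = table),
    source = NA_integer_, stringsAsFactors = FALSE) else NULL
  presence <- NULL
  pres_rows <- list()
  for (k in pres_kinds)
    pres_rows[[length(pres_rows) + 1L]] <- data.frame(
      kind = k, qualifier_size_mm = NA_real_, source = NA_integer_,
      stringsAsFactors = FALSE)
  if (!is.null(nodule))
    pres_rows[[length(pres_rows) + 1L]] <- data.frame(
      kind = "nodule_ipsilateral_other_lobe", qualifier_size_mm = nodule$size,
      source = NA_integer_, stringsAsFactors = FALSE)
  if (length(pres_rows)) presence <- do.call(rbind, pres_rows)
  findings <- list(tumor_finding("primary", lat, lobe,
                                 size_mm = if (is.na(size)) NA_real_ else size,
                                 involvement = involvement, presence = presence))
  if (!is.null(nodule))
    findings[[2]] <- tumor_finding("nodule_ipsilateral_other_lobe", lat, nodule$lobe,
                                   size_mm = nodule$size)
  list(label = label, lobe = lobe, laterality = lat, size = size,
       structures = structures, pres_kinds = pres_kinds, nodule = nodule,
       findings = findings)
}

# ---- text realization ------------------------------------------------------

.fmt_size <- function(size_mm, dialect) {
  stopifnot(size_mm > 0)
  comma <- function(s) if (dialect[["decimal_comma"]]) gsub(".", ",", s, fixed = TRUE) else s
  as_cm <- function(v) comma(sprintf("%.1f", v / 10))
  if (dialect[["triple_dimension"]] && size_mm >= 10) {
    d2 <- max(1, size_mm - .rint(1, min(9, size_mm - 1)))
    d3 <- max(1, d2 - .rint(0, min(5, d2 - 1)))
    dims <- c(size_mm, d2, d3)
    if (dialect[["axis_labels"]]) {
      ax <- c("AP", "TVR", "SI")
      paste0(paste(sprintf("%s (%s)", vapply(dims, as_cm, ""), ax), collapse = " x "),
             " cm")
    } else paste0(paste(vapply(dims, as_cm, ""), collapse = " x "), " cm")
  } else if (.flip(0.5)) {
    paste0(size_mm, " mm")
  } else {
    paste0(as_cm(size_mm), " cm")
  }
}

.tumor_sentence <- function(plan, dialect) {
  syn <- .pick(.TUMOR_SYNONYMS)
  if (is.na(plan$size)) {
    .pick(list(
      sprintf("There is a large %s hilar %s.", plan$laterality, syn),
      sprintf("A bulky central %s is present in the %s lung.", syn, plan$laterality)))
  } else {
    size <- .fmt_size(plan$size, dialect)
    lobe <- .LOBE_PHRASE[[plan$lobe]]
    .pick(list(
      sprintf("There is a %s spiculated %s in the %s.", size, syn, lobe),
      sprintf("A %s %s is seen in the %s.", size, syn, lobe),
      sprintf("%s %s measuring %s.", paste0(toupper(substring(lobe, 1, 1)),
                                            substring(lobe, 2)), syn, size),
      sprintf("Within the %s there is an irregular %s measuring %s.", lobe, syn, size)))
  }
}

.involvement_sentence <- function(structure) {
  np <- .STRUCTURE_PHRASE[[structure]]
  .pick(list(
    sprintf("The mass invades %s.", np),
    sprintf("There is direct invasion of %s.", np),
    sprintf("Tumor infiltrates %s.", np)))
}

.presence_sentence <- function(kind, plan) {
  switch(kind,
    post_obstructive_atelectasis = .pick(list(
      "There is associated postobstructive atelectasis.",
      sprintf("Post-obstructive atelectasis of the %s is present.",
              .LOBE_PHRASE[[plan$lobe]]))),
    satellite_same_lobe = .pick(list(
      "A satellite nodule is noted within the same lobe.",
      "There is an adjacent satellite nodule.")),
    stop("no sentence template for presence kind ", kind))
}

.nodule_sentence <- function(nodule, dialect) {
  single <- dialect; single[["triple_dimension"]] <- FALSE
  sprintf("There is a separate %s nodule in the %s.",
          .fmt_size(nodule$size, single), .LOBE_PHRASE[[nodule$lobe]])
}

.distractor_sentence <- function(kind, plan, dialect) {
  single <- dialect; single[["triple_dimension"]] <- FALSE
  switch(kind,
    benign_cyst = sprintf("There is a benign cyst in the %s kidney measuring %s.",
                          .pick(c("right", "left")), .fmt_size(.rint(15, 45), single)),
    gravity_atelectasis = .pick(list(
      "Bibasilar subsegmental atelectasis.",
      "There is dependent atelectasis at the lung bases.",
      "Mild bilateral basal atelectasis is noted.")),
    negated_involvement = sprintf("There is no invasion of %s.",
                                  .STRUCTURE_PHRASE[[.pick(setdiff(names(.STRUCTURE_PHRASE),
                                                                   plan$structures))]]),
    uncertain_involvement = sprintf("The mass is abutting %s.",
                                    .STRUCTURE_PHRASE[[.pick(setdiff(names(.STRUCTURE_PHRASE),
                                                                     plan$structures))]]),
    lymph_node_station = sprintf("There is an enlarged %s lymph node measuring %s.",
                                 .pick(c("subcarinal", "paratracheal", "right hilar",
                                         "supraclavicular")),
                                 .fmt_size(.rint(8, 24), single)),
    unitless_size = "A second tiny nodule adjacent to the fissure measures 4.",
    stop("unknown distractor kind ", kind))
}

.CHEST_FILLERS <- c("The central airways are patent.",
                    "The remaining lungs are clear.",
                    "No pneumothorax or effusion.",
                    "No focal consolidation elsewhere.")
.MEDI_FILLERS <- c("No enlarged mediastinal lymph nodes.",
                   "Normal cardiomediastinal silhouette.")
.ABD_FILLERS <- c("No acute abnormality in the upper abdomen.",
                  "The adrenal glands are unremarkable.")

.assemble_report <- function(format_tag, chest, medi, abd, pet_lines) {
  chest_block <- paste(chest, collapse = " ")
  medi_block <- paste(medi, collapse = " ")
  abd_block <- paste(abd, collapse = " ")
  pet_block <- paste(pet_lines, collapse = " ")
  switch(format_tag,
    CT = paste0("Clinical History: Lung cancer staging.\n",
                "Comparison: None available.\n",
                "Technique: Contrast-enhanced CT of the chest.\n",
                "Findings:\n",
                "Chest:\n", chest_block, "\n",
                "Mediastinum:\n", medi_block, "\n",
                "Abdomen:\n", abd_block, "\n",
                "Bones:\nNo aggressive osseous abnormality.\n"),
    PET = paste0("Indication: Initial staging of lung cancer.\n",
                 "Technique: Whole-body FDG PET-CT.\n",
                 "Findings:\n",
                 chest_block, " ", pet_block, " ", medi_block, " ", abd_block, "\n"),
    "PET-CT" = paste0("Indication: Staging.\n",
                      "Findings CT:\n",
                      "Chest:\n", chest_block, "\n",
                      "Mediastinum:\n", medi_block, "\n",
                      "Abdomen:\n", abd_block, "\n",
                      "Findings PET:\n", pet_block, "\n"))
}

#' Generate a single synthetic report with its gold record
#'
#' The planted primary tumor sentence encodes size and lobe; involvement,
#' presence and distractor sentences follow the gold plan, under the
#' subheadings of the chosen report format. The gold record is
#' self-consistent by construction: [classify_t()] over the planted
#' findings must reproduce the gold label, otherwise generation aborts with
#' a plan error (e.g. a T1a plan cannot carry involvement).
#'
#' @param spec a [synth_spec()] (rates and dialects are read from it).
#' @param label gold T-substage label to plant.
#' @param format_tag one of CT, PET, PET-CT.
#' @param report_id identifier for the report.
#' @param table decision table used for the self-consistency check.
#' @return A list with `report` ([raw_report()]) and `gold` (list of class
#'   `gold_record`: `report_id`, `label`, `planted` findings, `distractors`).
#' @export
generate_report <- function(spec, label, format_tag = "CT", report_id = "synth-1",
                            table = default_tnm_table()) {
  plan <- .build_plan(label, table)
  check <- classify_t(plan$findings, table)
  if (check$label != label)
    stop("plan error: planted findings classify as ", check$label,
         " but gold label is ", label)
  dialect <- list(decimal_comma = .flip(spec$dialect_rates[["decimal_comma"]]),
                  triple_dimension = .flip(spec$dialect_rates[["triple_dimension"]]),
                  axis_labels = .flip(spec$dialect_rates[["axis_labels"]]))
  drawn <- DISTRACTOR_KINDS[vapply(DISTRACTOR_KINDS, function(k)
    .flip(spec$distractor_rates[[k]]), TRUE)]
  chest <- c(.tumor_sentence(plan, dialect))
  for (s in plan$structures) chest <- c(chest, .involvement_sentence(s))
  for (k in plan$pres_kinds) chest <- c(chest, .presence_sentence(k, plan))
  if (!is.null(plan$nodule)) chest <- c(chest, .nodule_sentence(plan$nodule, dialect))
  chest <- c(chest, .pick(.CHEST_FILLERS))
  medi <- .pick(.MEDI_FILLERS)
  abd <- .pick(.ABD_FILLERS)
  for (k in drawn) {
    s <- .distractor_sentence(k, plan, dialect)
    if (k == "benign_cyst") abd <- c(abd, s)
    else if (k == "lymph_node_station") medi <- c(medi, s)
    else chest <- c(chest, s)
  }
  pet_lines <- if (format_tag != "CT")
    c("The dominant pulmonary abnormality demonstrates intense FDG uptake with SUVmax 9.1.",
      "No other suspicious FDG-avid foci.") else character(0)
  text <- .assemble_report(format_tag, chest, medi, abd, pet_lines)
  gold <- structure(list(report_id = report_id, label = label,
                         planted = plan$findings,
                         distractors = drawn), class = "gold_record")
  list(report = raw_report(report_id, text, format_tag), gold = gold)
}

#' Generate a synthetic corpus
#'
#' Deterministic under the spec's seed: two runs with the same spec yield
#' byte-identical reports and identical gold records. Labels are sampled
#' from the substage weights, formats from the format mix.
#'
#' @param spec a [synth_spec()].
#' @param table decision table for plan self-consistency checks.
#' @return A list with `reports` (data frame `report_id`, `text`,
#'   `format_tag`), `gold` (list of gold records) and `gold_labels` (named
#'   character vector).
#' @export
generate_corpus <- function(spec, table = default_tnm_table()) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  labels <- if (spec$n > 0)
    sample(names(spec$substage_distribution), spec$n, replace = TRUE,
           prob = spec$substage_distribution) else character(0)
  formats <- if (spec$n > 0)
    sample(names(spec$format_mix), spec$n, replace = TRUE, prob = spec$format_mix)
    else character(0)
  reports <- vector("list", spec$n)
  gold <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    out <- generate_report(spec, labels[i], formats[i],
                           report_id = sprintf("synth-%04d", i), table = table)
    reports[[i]] <- out$report
    gold[[i]] <- out$gold
  }
  df <- data.frame(report_id = vapply(reports, `[[`, "", "report_id"),
                   text = vapply(reports, `[[`, "", "text"),
                   format_tag = vapply(reports, `[[`, "", "format_tag"),
                   stringsAsFactors = FALSE)
  gl <- stats::setNames(vapply(gold, `[[`, "", "label"), df$report_id)
  list(reports = df, gold = gold, gold_labels = gl)
}
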