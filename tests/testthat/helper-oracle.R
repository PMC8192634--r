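# Independent brute-force oracle for the T-substage decision rules, written
# as a literal transcription of the AJCC-8 descriptor table plus the
# package's documented custom thresholds. Kept deliberately separate from
# the implementation path it checks.

ORACLE_ORDER <- c("Tx", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T3", "T4")

ORACLE_TIERS <- c(
  main_bronchus = "T2", visceral_pleura = "T2",
  chest_wall = "T3", parietal_pericardium = "T3", phrenic_nerve = "T3",
  mediastinum = "T4", diaphragm = "T4", heart = "T4", great_vessels = "T4",
  trachea = "T4", carina = "T4", esophagus = "T4",
  recurrent_laryngeal_nerve = "T4", vertebral_body = "T4")

oracle_size_stage <- function(size_mm) {
  if (is.na(size_mm)) return(NA_character_)
  if (size_mm <= 10) "T1a"
  else if (size_mm <= 20) "T1b"
  else if (size_mm <= 30) "T1c"
  else if (size_mm <= 40) "T2a"
  else if (size_mm <= 50) "T2b"
  else if (size_mm <= 70) "T3"
  else "T4"
}

oracle_classify <- function(size_mm, structures = character(0),
                            pres_kinds = character(0), nodule_size_mm = NA) {
  labs <- character(0)
  s <- oracle_size_stage(size_mm)
  if (!is.na(s)) labs <- c(labs, s)
  for (st in structures) labs <- c(labs, ORACLE_TIERS[[st]])
  for (k in pres_kinds) {
    if (k %in% c("post_obstructive_atelectasis", "main_bronchus")) labs <- c(labs, "T2")
    if (k == "satellite_same_lobe") labs <- c(labs, "T3")
  }
  if (!is.na(nodule_size_mm) && nodule_size_mm > 10) labs <- c(labs, "T4")
  if (!length(labs)) return("Tx")
  lab <- ORACLE_ORDER[max(match(labs, ORACLE_ORDER))]
  if (lab == "T2" && !is.na(size_mm))
    lab <- if (size_mm <= 40) "T2a" else if (size_mm <= 50) "T2b" else lab
  lab
}

# finding constructor for grid tests: one primary carrying everything
make_finding <- function(size_mm, structures = character(0),
                         pres_kinds = character(0), nodule_size_mm = NA) {
  inv <- if (length(structures))
    data.frame(structure = structures, snomed_code = "", tier = NA_character_,
               source = NA_integer_, stringsAsFactors = FALSE) else NULL
  rows <- list()
  for (k in pres_kinds)
    rows[[length(rows) + 1L]] <- data.frame(kind = k, qualifier_size_mm = NA_real_,
                                            source = NA_integer_, stringsAsFactors = FALSE)
  if (!is.na(nodule_size_mm))
    rows[[length(rows) + 1L]] <- data.frame(kind = "nodule_ipsilateral_other_lobe",
                                            qualifier_size_mm = nodule_size_mm,
                                            source = NA_integer_, stringsAsFactors = FALSE)
  pr <- if (length(rows)) do.call(rbind, rows) else NULL
  tumor_finding("primary", size_mm = if (is.na(size_mm)) NA_real_ else size_mm,
                involvement = inv, presence = pr)
}
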