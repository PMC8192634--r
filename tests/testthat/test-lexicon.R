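test_that("the shipped lexicon loads with full category coverage", {
  expect_gte(nrow(LEX$entries), 40L)
  expect_true(all(c("tumor_mass", "lymph_node", "involvement_target",
                    "presence_finding", "anatomic_location", "blacklist_term")
                  %in% LEX$entries$category))
  # every involvement entry has a tier in the decision table
  inv <- sub("^inv\\.", "", LEX$entries$concept_id[LEX$entries$category == "involvement_target"])
  for (s in inv) expect_true(s %in% names(TNM$tier_of))
})

test_that("malformed lexicon resources are rejected with location info", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("concept_id\tsnomed_code\tcategory\tpattern\tnotes", tmp)
  expect_error(load_lexicon(tmp), "no entries")

  writeLines(c("concept_id\tsnomed_code\tcategory\tpattern\tnotes",
               "a\t1\ttumor_mass\tmass\t",
               "a\t2\ttumor_mass\ttumor\t"), tmp)
  expect_error(load_lexicon(tmp), "duplicate concept_id")

  writeLines(c("concept_id\tsnomed_code\tpattern",
               "a\t1\tmass"), tmp)
  expect_error(load_lexicon(tmp), "missing column")

  writeLines(c("concept_id\tsnomed_code\tcategory\tpattern\tnotes",
               "a\t1\ttumor_mass\tmass(\t"), tmp)
  expect_error(load_lexicon(tmp), "row 1")
})

test_that("every lexicon pattern fires exactly once in a carrier sentence", {
  for (i in seq_len(nrow(LEX$entries))) {
    example <- sample_pattern(LEX$entries$pattern[i])
    carrier <- paste0("There it is a ", example, " here.")
    hits <- match_concepts(carrier, LEX)
    # ignore carrier words and in-example hits of other categories (e.g.
    # "satellite nodules" legitimately also carries a tumor lexeme)
    hits <- hits[hits$start >= 14L & hits$category == LEX$entries$category[i], ,
                 drop = FALSE]
    expect_identical(nrow(hits), 1L,
                     info = paste(LEX$entries$concept_id[i], "->", example))
    expect_identical(hits$snomed_code, LEX$entries$snomed_code[i],
                     info = LEX$entries$concept_id[i])
  }
})

test_that("matching is case-insensitive and word-boundary safe", {
  expect_identical(match_concepts("ENLARGED MASS SEEN", LEX)$concept_id, "tumor.mass")
  # embedded lexemes never fire
  for (w in c("nodemus", "cystoscopy", "remassign", "biomassive"))
    expect_identical(nrow(match_concepts(paste("the", w, "specimen"), LEX)), 0L)
  set.seed(9)
  for (rep in 1:25) {
    pad1 <- paste(sample(letters, 3), collapse = "")
    pad2 <- paste(sample(letters, 3), collapse = "")
    expect_identical(nrow(match_concepts(paste0("a ", pad1, "mass", pad2, " b"), LEX)), 0L)
  }
})

test_that("a mass lexeme with a nodal lexeme in-sentence becomes a lymph node", {
  hits <- match_concepts("a (lymphnodal) subcarinal mass", LEX)
  m <- hits[hits$concept_id == "tumor.mass", ]
  expect_identical(m$category, "lymph_node")
  # a nodal-station word alone does not flip a mass
  hits <- match_concepts("a perihilar mass is seen", LEX)
  expect_identical(hits$category[hits$concept_id == "tumor.mass"], "tumor_mass")
})

test_that("determinism: identical sentence and lexicon give identical mentions", {
  s <- "A 3 cm spiculated mass invades the chest wall near a subcarinal lymph node."
  expect_identical(match_concepts(s, LEX), match_concepts(s, LEX))
})

test_that("blacklist sentences suppress tumor and size candidates only", {
  doc <- stage_report(raw_report("r", paste(
    "There is a 21 mm mass in the left upper lobe.",
    "Benign cyst in the right kidney measuring 2,3 cm.")), LEX, MODS, POLICY, TNM)
  cyst_sentence <- doc$concepts$sentence[doc$concepts$concept_id == "bl.cyst"]
  sup <- doc$concepts[doc$concepts$sentence == cyst_sentence &
                        doc$concepts$category == "tumor_mass", ]
  expect_true(all(sup$suppressed))
  ms <- doc$measurements[doc$measurements$sentence == cyst_sentence, ]
  expect_true(all(ms$suppressed))
  expect_identical(doc$findings[[1]]$size_mm, 21)
  expect_identical(doc$result$label, "T1c")

  # involvement mentions survive a blacklisted sentence
  doc <- stage_report(raw_report("r2", paste(
    "A 15 mm nodule in the right lower lobe.",
    "Cystic change with invasion of the chest wall.")), LEX, MODS, POLICY, TNM)
  inv <- doc$concepts[doc$concepts$category == "involvement_target", ]
  expect_false(any(inv$suppressed))
  expect_identical(doc$result$label, "T3")

  # a clean sentence is left unchanged
  doc <- stage_report("A 15 mm nodule in the right lower lobe.", LEX, MODS, POLICY, TNM)
  expect_false(any(doc$concepts$suppressed))
  expect_false(any(doc$measurements$suppressed))
})

test_that("the documented cyst trade-off suppresses cystic lung tumors too", {
  doc <- stage_report("A cystic mass in the right upper lobe measuring 3 cm.",
                      LEX, MODS, POLICY, TNM)
  expect_identical(doc$result$label, "Tx")
})

test_that("out-of-scope sections never contribute tumor-size candidates", {
  txt <- paste0("Chest:\nNo suspicious pulmonary nodule.\n",
                "Abdomen:\nThere is a 4 cm mass in the pelvis.\n")
  doc <- stage_report(raw_report("r", txt), LEX, MODS, POLICY, TNM)
  expect_identical(doc$result$label, "Tx")
  abd <- doc$concepts[doc$concepts$category == "tumor_mass" &
                        doc$concepts$suppressed, ]
  expect_gte(nrow(abd), 1L)
})

test_that("each enabled distractor leaves a clean plan unharmed", {
  for (kind in c("benign_cyst", "gravity_atelectasis", "negated_involvement",
                 "uncertain_involvement", "lymph_node_station", "unitless_size")) {
    rates <- stats::setNames(rep(0, 6), c("benign_cyst", "gravity_atelectasis",
                                          "negated_involvement", "uncertain_involvement",
                                          "lymph_node_station", "unitless_size"))
    rates[kind] <- 1
    corpus <- generate_corpus(synth_spec(12, seed = 31, distractor_rates = rates))
    out <- stage_corpus(corpus$reports, LEX, MODS, POLICY, TNM)
    expect_identical(unname(out$predictions), unname(corpus$gold_labels),
                     info = kind)
  }
})
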