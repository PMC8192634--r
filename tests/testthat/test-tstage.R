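test_that("size breakpoints follow the descriptor table with inclusive bounds", {
  cases <- list(
    list(1, "T1a"), list(8, "T1a"), list(10, "T1a"),
    list(11, "T1b"), list(18, "T1b"), list(20, "T1b"),
    list(21, "T1c"), list(30, "T1c"),
    list(31, "T2a"), list(35, "T2a"), list(40, "T2a"),
    list(41, "T2b"), list(50, "T2b"),
    list(51, "T3"), list(70, "T3"),
    list(71, "T4"), list(75, "T4"), list(120, "T4"))
  for (cs in cases) {
    expect_identical(size_to_t(cs[[1]], TNM), cs[[2]], info = cs[[1]])
    expect_identical(oracle_size_stage(cs[[1]]), cs[[2]], info = cs[[1]])
  }
  expect_identical(size_to_t(NA, TNM), NA_character_)
  expect_error(size_to_t(0, TNM), "positive")
  expect_error(size_to_t(-5, TNM), "positive")
})

test_that("involvement maps to the highest tier present", {
  expect_identical(involvement_to_t("visceral_pleura", TNM), "T2")
  expect_identical(involvement_to_t("chest_wall", TNM), "T3")
  expect_identical(involvement_to_t(c("mediastinum", "chest_wall"), TNM), "T4")
  expect_identical(involvement_to_t("vertebral_body", TNM), "T4")
  expect_identical(involvement_to_t(character(0), TNM), NA_character_)
  expect_error(involvement_to_t("spleen", TNM), "configuration error")
})

test_that("presence findings map to their tiers with the nodule size gate", {
  expect_identical(presence_to_t("post_obstructive_atelectasis", TNM), "T2")
  expect_identical(presence_to_t("main_bronchus", TNM), "T2")
  expect_identical(presence_to_t("satellite_same_lobe", TNM), "T3")
  nod <- function(q) data.frame(kind = "nodule_ipsilateral_other_lobe",
                                qualifier_size_mm = q)
  expect_identical(presence_to_t(nod(12), TNM), "T4")
  expect_identical(presence_to_t(nod(10), TNM), NA_character_)
  expect_identical(presence_to_t(nod(8), TNM), NA_character_)
  expect_identical(presence_to_t(nod(NA), TNM), NA_character_)
  expect_identical(presence_to_t(character(0), TNM), NA_character_)
  expect_error(presence_to_t("pleural_effusion", TNM), "unknown presence kind")
})

test_that("classification composes components by the maximum rule", {
  expect_identical(classify_t(make_finding(25, "visceral_pleura"), TNM)$label, "T2a")
  expect_identical(classify_t(make_finding(18), TNM)$label, "T1b")
  expect_identical(classify_t(make_finding(NA, "main_bronchus"), TNM)$label, "T2")
  expect_identical(classify_t(make_finding(45, "chest_wall"), TNM)$label, "T3")
  expect_identical(classify_t(make_finding(45, "visceral_pleura"), TNM)$label, "T2b")
  expect_identical(classify_t(make_finding(NA, character(0),
                                           "post_obstructive_atelectasis"), TNM)$label, "T2")
  res <- classify_t(make_finding(32, character(0), character(0), 12), TNM)
  expect_identical(res$label, "T4")
  expect_identical(res$size_component, "T2a")
  expect_identical(res$presence_component, "T4")
  res <- classify_t(list(), TNM)
  expect_identical(res$label, "Tx")
  expect_true(all(is.na(c(res$size_component, res$involvement_component,
                          res$presence_component))))
})

test_that("a sub-threshold other-lobe nodule contributes nothing but is explained", {
  res <- classify_t(make_finding(22, character(0), character(0), 9), TNM)
  expect_identical(res$label, "T1c")
  expect_match(paste(res$rationale, collapse = "; "), "no T4 contribution")
})

test_that("the label dominates its components and is monotone", {
  set.seed(88)
  structures <- names(TNM$tier_of)
  for (rep in 1:150) {
    size <- sample(c(NA, 1:100), 1)
    inv <- sample(structures, sample(0:3, 1))
    pk <- sample(c("post_obstructive_atelectasis", "satellite_same_lobe"),
                 sample(0:2, 1))
    nod <- sample(c(NA, 8, 15), 1)
    res <- classify_t(make_finding(size, inv, pk, nod), TNM)
    comps <- c(res$size_component, res$involvement_component, res$presence_component)
    for (cmp in comps[!is.na(comps)])
      expect_gte(stage_rank(res$label), stage_rank(cmp))
    # adding an involvement never lowers the label
    extra <- sample(setdiff(structures, inv), 1)
    res2 <- classify_t(make_finding(size, c(inv, extra), pk, nod), TNM)
    expect_gte(stage_rank(res2$label), stage_rank(res$label))
    # growing the tumor never lowers the label
    if (!is.na(size)) {
      res3 <- classify_t(make_finding(size + sample(1:30, 1), inv, pk, nod), TNM)
      expect_gte(stage_rank(res3$label), stage_rank(res$label))
    }
  }
})

test_that("a custom decision table can swap thresholds", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: custom", "size_breakpoints_mm: {T1a: 10, T1b: 20, T1c: 30, T2a: 40, T2b: 50, T3: 70}",
               "involvement_tiers: {T2: [visceral_pleura], T3: [chest_wall], T4: [mediastinum]}",
               "presence_map: {post_obstructive_atelectasis: T2, main_bronchus: T2, satellite_same_lobe: T3, nodule_ipsilateral_other_lobe: T4}",
               "nodule_min_size_mm: 20"), tmp)
  tab <- load_tnm_table(tmp)
  expect_identical(classify_t(make_finding(22, character(0), character(0), 15), tab)$label,
                   "T1c")
  expect_identical(classify_t(make_finding(22, character(0), character(0), 25), tab)$label,
                   "T4")
  # a structure in two tiers is rejected
  writeLines(c("version: bad", "size_breakpoints_mm: {T1a: 10, T1b: 20, T1c: 30, T2a: 40, T2b: 50, T3: 70}",
               "involvement_tiers: {T2: [visceral_pleura], T3: [visceral_pleura]}",
               "presence_map: {}", "nodule_min_size_mm: 10"), tmp)
  expect_error(load_tnm_table(tmp), "more than one tier")
})
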