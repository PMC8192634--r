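test_that("a hand-computed 8-case fixture scores exactly", {
  gold <- c(a = "T1b", b = "T1c", c = "T2a", d = "T2a",
            e = "T2b", f = "T3", g = "T4", h = "T2")
  # perfect predictions
  ev <- evaluate_staging(gold, gold)
  expect_identical(ev$accuracy_substage, 1)
  expect_identical(ev$accuracy_stage, 1)
  expect_identical(sum(diag(ev$confusion)), 8L)
  expect_identical(sum(ev$confusion), 8L)

  # two substage errors, one of which survives collapsing:
  #   b: T1c -> T1b (same stage), g: T4 -> T3 (stage error)
  pred <- gold
  pred["b"] <- "T1b"; pred["g"] <- "T3"
  ev <- evaluate_staging(pred, gold)
  expect_identical(ev$accuracy_substage, 6 / 8)
  expect_identical(ev$accuracy_stage, 7 / 8)
  expect_identical(ev$n, 8L)
  # hand counts: T1b predicted twice, one correct -> precision 1/2, recall 1/1
  expect_identical(ev$per_class$T1b$precision, 0.5)
  expect_identical(ev$per_class$T1b$recall, 1)
  expect_identical(ev$per_class$T1b$f1, 2 * 0.5 * 1 / 1.5)
  # T1c: support 1, never predicted -> recall 0, precision undefined (null)
  expect_identical(ev$per_class$T1c$recall, 0)
  expect_true(is.na(ev$per_class$T1c$precision))
  expect_identical(ev$per_class$T1c$support, 1L)
  # confusion row sums equal supports
  expect_identical(unname(rowSums(ev$confusion)["T2a"]), 2)
  json <- eval_report_json(ev)
  expect_match(json, '"precision":null')
})

test_that("a substage error inside one stage keeps stage accuracy perfect", {
  gold <- c(r1 = "T1b", r2 = "T1c", r3 = "T3", r4 = "T4")
  pred <- c(r1 = "T1b", r2 = "T1b", r3 = "T3", r4 = "T4")
  ev <- evaluate_staging(pred, gold)
  expect_identical(ev$accuracy_substage, 0.75)
  expect_identical(ev$accuracy_stage, 1)
})

test_that("per-class metrics equal an independent contingency-count oracle", {
  set.seed(202)
  lv <- stage_levels()
  for (rep in 1:10) {
    ids <- sprintf("c%03d", 1:100)
    gold <- stats::setNames(sample(lv, 100, replace = TRUE), ids)
    pred <- stats::setNames(sample(lv, 100, replace = TRUE), ids)
    ev <- evaluate_staging(pred, gold)
    for (cl in lv) {
      tp <- 0; fp <- 0; fn <- 0
      for (id in ids) {
        if (pred[id] == cl && gold[id] == cl) tp <- tp + 1
        if (pred[id] == cl && gold[id] != cl) fp <- fp + 1
        if (pred[id] != cl && gold[id] == cl) fn <- fn + 1
      }
      m <- ev$per_class[[cl]]
      expect_identical(m$support, as.integer(tp + fn))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp)) else expect_true(is.na(m$precision))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn)) else expect_true(is.na(m$recall))
      expect_identical(unname(ev$confusion[cl, cl]), as.integer(tp))
    }
  }
})

test_that("collapsing never creates errors: substage <= stage accuracy", {
  set.seed(303)
  lv <- stage_levels()
  for (rep in 1:1000) {
    n <- sample(3:30, 1)
    ids <- as.character(seq_len(n))
    gold <- stats::setNames(sample(lv, n, replace = TRUE), ids)
    pred <- stats::setNames(sample(lv, n, replace = TRUE), ids)
    ev <- evaluate_staging(pred, gold)
    expect_lte(ev$accuracy_substage, ev$accuracy_stage)
  }
})

test_that("micro-averaged recall equals substage accuracy", {
  set.seed(404)
  lv <- stage_levels()
  ids <- as.character(1:60)
  gold <- stats::setNames(sample(lv, 60, replace = TRUE), ids)
  pred <- stats::setNames(sample(lv, 60, replace = TRUE), ids)
  ev <- evaluate_staging(pred, gold)
  tp_total <- sum(vapply(lv, function(cl) unname(ev$confusion[cl, cl]), 0L))
  expect_equal(tp_total / ev$n, ev$accuracy_substage)
})

test_that("id mismatches and bad labels are input errors", {
  expect_error(evaluate_staging(c(a = "T1a"), c(b = "T1a")), "id mismatch")
  expect_error(evaluate_staging(c(a = "T1a"), c(a = "T9")), "unknown label")
  empty <- stats::setNames(character(0), character(0))
  expect_error(evaluate_staging(empty, empty), "at least one")
})

test_that("size-only accuracy is rebuilt from the size component", {
  docs <- list(
    a = stage_report("A 25 mm mass in the right upper lobe invades the chest wall.",
                     LEX, MODS, POLICY, TNM),
    b = stage_report("There is a 12 mm nodule in the left upper lobe.",
                     LEX, MODS, POLICY, TNM))
  preds <- lapply(docs, `[[`, "result")
  ev <- evaluate_staging(preds, c(a = "T3", b = "T1b"))
  expect_identical(ev$accuracy_substage, 1)
  # size alone calls case "a" T1c, so the size-only view drops to 1/2
  expect_identical(ev$accuracy_size_only, 0.5)
})

test_that("diff_findings localizes component mismatches", {
  corpus <- small_corpus(5, seed = 71, clean = TRUE)
  out <- stage_corpus(corpus$reports, LEX, MODS, POLICY, TNM)
  g <- corpus$gold[[1]]
  expect_identical(nrow(diff_findings(out$documents[[g$report_id]], g)), 0L)
  # fabricate a pleural-thickening style size confusion: 86 mm vs planted
  doc <- out$documents[[g$report_id]]
  for (i in seq_along(doc$findings))
    if (doc$findings[[i]]$role == "primary") doc$findings[[i]]$size_mm <- 86
  d <- diff_findings(doc, g)
  expect_identical(d$component, "size")
  # a missing involvement item is one involvement discrepancy
  doc2 <- out$documents[[g$report_id]]
  extra <- g
  extra$planted[[1]]$involvement <- data.frame(structure = "chest_wall",
                                               snomed_code = "", tier = "T3",
                                               source = NA_integer_)
  d2 <- diff_findings(doc2, extra)
  expect_true("involvement" %in% d2$component)
})
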