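test_that("measurement micro-suite: units, decimal commas, tuples, axis labels", {
  m <- extract_measurements("pleural thickening of 8,6 cm")
  expect_identical(m$max_dim_mm, 86)
  expect_identical(m$unit, "cm")

  m <- extract_measurements("3.1 x 2.4 x 1.8 cm")
  expect_identical(c(m$mag1, m$mag2, m$mag3), c(3.1, 2.4, 1.8))
  expect_identical(m$max_dim_mm, 31)

  m <- extract_measurements("2.1 (AP) × 3.0 (TVR) × 1.8 (SI) cm")
  expect_identical(nrow(m), 1L)
  expect_identical(m$max_dim_mm, 30)

  expect_identical(nrow(extract_measurements("size 14")), 0L)
  expect_identical(nrow(extract_measurements("a large mass")), 0L)
  expect_identical(extract_measurements("a 14 mm nodule")$max_dim_mm, 14)
  expect_identical(extract_measurements("measures 2 x 1 cm")$max_dim_mm, 20)
})

test_that("no measurement ever lacks a unit (random digit strings)", {
  set.seed(12)
  for (rep in 1:50) {
    nums <- sprintf("%.1f", stats::runif(3, 0.5, 90))
    for (txt in c(paste("size", nums[1]),
                  paste(nums, collapse = " x "),
                  paste("the lesion measures", nums[2], "by", nums[3])))
      expect_identical(nrow(extract_measurements(txt)), 0L, info = txt)
    with_unit <- paste0(paste(nums, collapse = " x "), " cm")
    m <- extract_measurements(with_unit)
    expect_identical(m$max_dim_mm, max(as.numeric(nums)) * 10, info = with_unit)
  }
})

test_that("max_dim_mm is permutation-invariant and cm conversion is exact", {
  set.seed(13)
  for (rep in 1:25) {
    dims <- round(stats::runif(3, 0.4, 9.9), 1)
    perms <- list(dims, rev(dims), dims[c(2, 1, 3)])
    vals <- vapply(perms, function(d)
      extract_measurements(paste0(paste(d, collapse = " x "), " cm"))$max_dim_mm, 0)
    expect_true(all(vals == vals[1]))
    expect_identical(vals[1], max(dims) * 10)
  }
  expect_identical(extract_measurements("0.7 cm nodule")$max_dim_mm, 7)
})

test_that("ranges are not parsed as sizes", {
  expect_identical(nrow(extract_measurements("scattered nodules of 1-2 cm")), 0L)
  expect_identical(nrow(extract_measurements("between 3 - 4 mm")), 0L)
})

test_that("measurements link to the nearest preceding eligible mention", {
  doc <- stage_report("Spiculated mass in the right upper lobe measuring 3.2 x 2.1 cm.",
                      LEX, MODS, POLICY, TNM)
  expect_identical(doc$links$category, "tumor_mass")
  expect_identical(doc$links$lobe, "RUL")
  expect_identical(doc$findings[[1]]$size_mm, 32)
  expect_identical(doc$findings[[1]]$role, "primary")

  # a size at an involvement concept never becomes the tumor size
  doc <- stage_report("There is pleural thickening of 8,6 cm.", LEX, MODS, POLICY, TNM)
  expect_identical(doc$links$category, "involvement_target")
  expect_true(is.na(doc$findings[[1]]$size_mm))

  # lymph-node sizes never become tumor sizes
  doc <- stage_report(raw_report("r", paste(
    "There is a 9 mm nodule in the left lower lobe.",
    "An enlarged subcarinal lymph node measures 1.6 cm.")), LEX, MODS, POLICY, TNM)
  expect_identical(doc$findings[[1]]$size_mm, 9)
  expect_identical(doc$result$label, "T1a")

  # measurement with no linkable mention is unlinked and logged
  doc <- stage_report("The diameter is 4 cm.", LEX, MODS, POLICY, TNM)
  expect_identical(nrow(doc$links), 0L)
  expect_match(paste(doc$log, collapse = "; "), "unlinked")
})

test_that("consolidation picks the largest tumor as primary", {
  doc <- stage_report(raw_report("r", paste(
    "There is a 32 mm mass in the right upper lobe.",
    "There is a separate 12 mm nodule in the right lower lobe.")),
    LEX, MODS, POLICY, TNM)
  roles <- vapply(doc$findings, `[[`, "", "role")
  expect_identical(roles, c("primary", "nodule_ipsilateral_other_lobe"))
  expect_identical(doc$findings[[1]]$size_mm, 32)
  expect_identical(doc$findings[[2]]$size_mm, 12)
  pres <- doc$findings[[1]]$presence
  expect_true("nodule_ipsilateral_other_lobe" %in% pres$kind)
  expect_identical(pres$qualifier_size_mm[pres$kind == "nodule_ipsilateral_other_lobe"], 12)
})

test_that("duplicate sizes for one tumor keep the larger with a warning", {
  doc <- stage_report(raw_report("r", paste(
    "Mass in the right upper lobe measuring 3 cm.",
    "The right upper lobe mass measures 2,8 cm.")), LEX, MODS, POLICY, TNM)
  expect_identical(length(doc$findings), 1L)
  expect_identical(doc$findings[[1]]$size_mm, 30)
  expect_match(paste(doc$log, collapse = "; "), "different sizes")
})

test_that("contralateral nodules are ignored for T and logged", {
  doc <- stage_report(raw_report("r", paste(
    "There is a 45 mm mass in the right upper lobe.",
    "A separate 14 mm nodule is seen in the left lower lobe.")),
    LEX, MODS, POLICY, TNM)
  expect_identical(doc$result$label, "T2b")
  expect_match(paste(doc$log, collapse = "; "), "contralateral")
})

test_that("documents without tumor evidence yield no findings", {
  doc <- stage_report("The lungs are clear. No effusion.", LEX, MODS, POLICY, TNM)
  expect_identical(length(doc$findings), 0L)
  expect_identical(doc$result$label, "Tx")
})

test_that("clean-corpus recovery: planted size is recovered exactly", {
  corpus <- small_corpus(40, seed = 19, clean = TRUE)
  out <- stage_corpus(corpus$reports, LEX, MODS, POLICY, TNM)
  for (i in seq_along(corpus$gold)) {
    g <- corpus$gold[[i]]
    planted <- NA_real_
    for (f in g$planted) if (f$role == "primary") planted <- f$size_mm
    got <- NA_real_
    for (f in out$documents[[g$report_id]]$findings)
      if (f$role == "primary") got <- f$size_mm
    expect_identical(got, planted, info = g$report_id)
    expect_identical(nrow(diff_findings(out$documents[[g$report_id]], g)), 0L,
                     info = g$report_id)
  }
})
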