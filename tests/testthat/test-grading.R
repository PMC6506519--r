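test_that("DDLS staging follows the published RDR and no-rim ranges", {
  expect_equal(ddls_stage(0.35), "S1_2")
  expect_equal(ddls_stage(0.25), "S3")
  expect_equal(ddls_stage(0.15), "S4")
  expect_equal(ddls_stage(0.05), "S5")
  expect_equal(ddls_stage(0, extent = 30), "S6")
  expect_equal(ddls_stage(0, extent = 60), "S7")
  expect_equal(ddls_stage(0, extent = 100), "S8")
  expect_equal(ddls_stage(0, extent = 200), "S9_10")
})

test_that("every band boundary is owned by exactly one band", {
  # RDR side: 0.10, 0.20, 0.30 owned by the milder (higher-RDR rule) stage
  expect_equal(ddls_stage(0.30), "S1_2")
  expect_equal(ddls_stage(0.20), "S3")
  expect_equal(ddls_stage(0.10), "S4")
  # extent side: 45 -> S7, 90 and 180 -> S8, beyond 180 -> S9_10
  expect_equal(ddls_stage(0, extent = 45), "S7")
  expect_equal(ddls_stage(0, extent = 90), "S8")
  expect_equal(ddls_stage(0, extent = 180), "S8")
  expect_equal(ddls_stage(0, extent = 180.0001), "S9_10")
  # exhaustive sweep: exactly one band everywhere on a fine grid
  for (r in seq(0.0001, 0.5, by = 1e-3)) {
    expect_length(ddls_stage(r), 1L)
  }
  for (e in seq(0, 360, by = 0.25)) {
    expect_length(ddls_stage(0, extent = e), 1L)
  }
})

test_that("three-stage severity groups the stages per the printed spans", {
  expect_equal(ddls_three_stage("S1_2"), "normal")
  expect_equal(ddls_three_stage("S4"), "normal")
  expect_equal(ddls_three_stage("S5"), "moderate")
  expect_equal(ddls_three_stage("S7"), "moderate")
  expect_equal(ddls_three_stage("S8"), "severe")
  expect_equal(ddls_three_stage("S9_10"), "severe")
  # the narrow alternative keeps only stages 1-2 normal
  expect_equal(ddls_three_stage("S3", span = "narrow"), "moderate")
  expect_equal(ddls_three_stage("S1_2", span = "narrow"), "normal")
})

test_that("severity is monotone in decreasing RDR and increasing extent", {
  sev_rank <- function(s) match(s, c("normal", "moderate", "severe"))
  rs <- seq(0.49, 0.001, by = -0.004)
  ranks <- vapply(rs, function(r) sev_rank(ddls_three_stage(ddls_stage(r))),
                  numeric(1))
  expect_true(all(diff(ranks) >= 0))
  es <- seq(0, 360, by = 1)
  ranks2 <- vapply(es, function(e) {
    sev_rank(ddls_three_stage(ddls_stage(0, extent = e)))
  }, numeric(1))
  expect_true(all(diff(ranks2) >= 0))
  # the rim-absent branch never grades milder than the worst rim-present stage
  expect_gte(sev_rank(ddls_three_stage(ddls_stage(0, extent = 0))),
             sev_rank(ddls_three_stage(ddls_stage(0.001))))
})

test_that("ICD-9 CDR rule resolves its shared endpoints half-open", {
  expect_equal(icd9_three_stage(0.4), "normal")
  expect_equal(icd9_three_stage(0.5), "normal")
  expect_equal(icd9_three_stage(0.6), "moderate")
  expect_equal(icd9_three_stage(0.8), "moderate")
  expect_equal(icd9_three_stage(0.9), "severe")
  expect_error(icd9_three_stage(1.2), class = "activedisc_invalid_argument")
  expect_error(icd9_three_stage(-0.1), class = "activedisc_invalid_argument")
})

test_that("two-stage collapse sends any damage to glaucomatous", {
  expect_equal(two_stage("normal"), "normal")
  expect_equal(two_stage("moderate"), "glaucomatous")
  expect_equal(two_stage("severe"), "glaucomatous")
})

test_that("a concentric 0.4-fraction cup grades S1_2 normal end to end", {
  spec <- synthetic_spec(cup_radius_fraction_range = c(0.4, 0.4),
                         cup_offset_fraction_range = c(0, 0), seed = 19)
  sf <- generate_fundus_image(spec)
  rep <- grade_image(sf$image, laterality = sf$truth$laterality)
  # truth rdr = (1 - 0.4)/2 = 0.30, the bottom of the S1_2 band
  expect_equal(ddls_stage(clinical_params(sf$truth$disc, sf$truth$cup)), "S1_2")
  expect_equal(rep$ddls_severity, "normal")
  expect_equal(rep$icd9_severity, "normal")
  expect_equal(rep$two_stage, "normal")
})

test_that("advanced cupping with a large offset grades severe", {
  spec <- synthetic_spec(cup_radius_fraction_range = c(1.0, 1.0),
                         cup_offset_fraction_range = c(0.4, 0.4),
                         allow_rim_absence = TRUE, seed = 23)
  sf <- generate_fundus_image(spec)
  tp <- clinical_params(sf$truth$disc, sf$truth$cup)
  expect_gt(tp$rim_absence_extent, 90)
  rep <- grade_image(sf$image, laterality = sf$truth$laterality)
  expect_equal(rep$ddls_severity, "severe")
  expect_equal(rep$two_stage, "glaucomatous")
})

test_that("a uniform image fails structurally at the localization stage", {
  img <- array(0.5, dim = c(96, 96, 3))
  err <- tryCatch(grade_image(img), error = function(e) e)
  expect_s3_class(err, "activedisc_stage_failure")
  expect_equal(err$stage, "localization")
})

test_that("fitted-vs-true DDLS labels agree across a stratified cohort", {
  strata <- severity_strata_specs()
  agree <- c()
  for (nm in names(strata)) {
    coh <- generate_cohort(5, strata[[nm]], seed = match(nm, names(strata)) * 10)
    for (sf in coh) {
      rep <- grade_image(sf$image, laterality = sf$truth$laterality)
      true_sev <- ddls_three_stage(ddls_stage(
        clinical_params(sf$truth$disc, sf$truth$cup, sf$truth$laterality)))
      agree <- c(agree, rep$ddls_severity == true_sev)
    }
  }
  expect_gte(mean(agree), 0.85)
})
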