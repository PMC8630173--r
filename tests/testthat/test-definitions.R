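test_that("built-in specs encode the published rule sets", {
  esc <- builtin_spec("esc2013")
  expect_equal(esc$qrsd_rule, "fixed_120")
  expect_setequal(esc$q_forbidden_leads, c("V5", "V6"))
  expect_setequal(esc$notch_lead_set, c("I", "aVL", "V5", "V6"))
  expect_equal(esc$notch_min_count, 1L)
  expect_false(esc$rwpt_required)

  st <- builtin_spec("strauss")
  expect_equal(st$qrsd_rule, "sex_specific_130F_140M")
  expect_setequal(st$notch_lead_set, c("I", "aVL", "V1", "V2", "V5", "V6"))
  expect_equal(st$notch_min_count, 2L)

  aha <- builtin_spec("aha2009")
  expect_setequal(aha$q_forbidden_leads, c("V5", "V6", "I"))
  expect_equal(aha$notch_min_count, "all")
  expect_true(aha$rwpt_required)

  v <- builtin_spec("aha2009_variant", q_forbidden_leads = c("V5", "V6", "I"),
                    rwpt_required = FALSE)
  expect_setequal(v$q_forbidden_leads, c("V5", "V6", "I"))
  expect_false(v$rwpt_required)
  expect_equal(v$notch_min_count, "all")

  pr <- builtin_spec("proposed")
  expect_setequal(pr$q_forbidden_leads, c("V5", "V6"))  # small q allowed in I/aVL
  expect_equal(pr$notch_min_count, 2L)
  expect_true(pr$axis_ancillary)
  expect_false(pr$rwpt_required)

  expect_error(builtin_spec("nonsense"), "unknown definition")
  expect_error(builtin_spec("aha2009_variant",
                            q_forbidden_leads = c("V5", "V6")),
               "q_forbidden_leads")
})

test_that("definition YAML files round-trip and ship for the built-ins", {
  dir <- system.file("extdata", "definitions", package = "lbbbr")
  files <- list.files(dir, pattern = "\\.yaml$")
  expect_true(all(paste0(c("esc2013", "strauss", "aha2009", "proposed"),
                         ".yaml") %in% files))
  for (f in files) {
    spec <- read_definition_yaml(file.path(dir, f))
    expect_s3_class(spec, "lbbb_definition")
  }
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_definition_yaml(builtin_spec("strauss"), tmp)
  expect_identical(unclass(read_definition_yaml(tmp)),
                   unclass(builtin_spec("strauss")))
})

test_that("broad inclusion rule is QRSD >= 120, QS/rS in V1, no Q in V5/V6", {
  ok <- make_patient("P1", qrsd_ms = 148)
  expect_true(evaluate_inclusion(ok)$overall)
  expect_false(evaluate_inclusion(make_patient("P2", qrsd_ms = 118))$overall)
  expect_false(
    evaluate_inclusion(make_patient("P3", v1_morphology = "other"))$overall)
  expect_false(evaluate_inclusion(make_patient("P4", q = "V5"))$overall)
})

test_that("Strauss QRSD cutoff is sex-specific (130 F / 140 M)", {
  f132 <- make_patient("F1", sex = "F", qrsd_ms = 132, v1_morphology = "QS",
                       notch = c("V5", "V6"))
  m132 <- make_patient("M1", sex = "M", qrsd_ms = 132, v1_morphology = "QS",
                       notch = c("V5", "V6"))
  st <- builtin_spec("strauss")
  expect_true(evaluate_definition(f132, st)$overall)
  expect_false(evaluate_definition(m132, st)$overall)
  expect_true(evaluate_definition(m132, st)$notch)  # only the QRSD rule fails
})

test_that("three-lead notching fails AHA's all-four rule but meets the proximal rule", {
  p <- make_patient("P1", qrsd_ms = 150, notch = c("I", "aVL", "V5"),
                    rwpt_gt60_v5 = TRUE, rwpt_gt60_v6 = TRUE)
  expect_false(evaluate_definition(p, builtin_spec("aha2009"))$overall)
  expect_true(evaluate_definition(p, builtin_spec("proposed"))$overall)
  expect_true(evaluate_definition(p, builtin_spec("esc2013"))$overall)
})

test_that("the axis flag is ancillary: reported, never part of the verdict", {
  left <- make_patient("P1", frontal_axis_deg = -40,
                       notch = c("I", "aVL", "V5", "V6"))
  right <- make_patient("P2", frontal_axis_deg = 80,
                        notch = c("I", "aVL", "V5", "V6"))
  none <- make_patient("P3", frontal_axis_deg = NA,
                       notch = c("I", "aVL", "V5", "V6"))
  pr <- builtin_spec("proposed")
  r <- evaluate_definition(dplyr::bind_rows(left, right, none), pr)
  expect_equal(r$ancillary_axis_leftward, c(TRUE, FALSE, NA))
  expect_equal(r$overall, c(TRUE, TRUE, TRUE))
})

test_that("overall is always the conjunction of its criteria", {
  cohort <- random_cohort(200, seed = 7)
  for (spec in builtin_specs()) {
    r <- evaluate_definition(cohort, spec)
    crit <- setdiff(names(r), c("patient_id", "definition", "overall",
                                "ancillary_axis_leftward"))
    expect_equal(r$overall, Reduce(`&`, r[crit]))
  }
})

test_that("classify_cohort tabulates counts and paper-style percentages", {
  cohort <- make_cohort(
    make_patient("P1", notch = c("I", "aVL", "V5", "V6")),
    make_patient("P2", notch = character()),
    make_patient("P3", notch = "V5")
  )
  cls <- classify_cohort(cohort, builtin_spec("esc2013"))
  expect_equal(cls$summary$n_positive, 2L)
  expect_equal(cls$summary$percent, 67L)
  expect_equal(nrow(tidy(cls)), 3)
  # empty definition list gives an empty summary, not an error
  empty <- classify_cohort(cohort, list())
  expect_equal(nrow(empty$summary), 0)
})

test_that("percentages round half away from zero, matching printed tables", {
  expect_equal(lbbbr:::pct_int(10, 59), 17L)   # 16.95
  expect_equal(lbbbr:::pct_int(56, 59), 95L)   # 94.92
  expect_equal(lbbbr:::pct_int(100, 118), 85L) # 84.75
  expect_equal(lbbbr:::pct_int(8, 118), 7L)    # 6.78
  expect_equal(lbbbr:::pct_int(95, 118), 81L)  # 80.51
  expect_equal(lbbbr:::pct_int(35, 118), 30L)  # 29.66
})

test_that("adding a notch never turns a positive verdict negative", {
  cohort <- random_cohort(150, seed = 11)
  notch_cols <- paste0("notch_", c("I", "aVL", "V1", "V2", "V5", "V6",
                                   "II", "III", "aVF"))
  for (spec in builtin_specs(include_variants = FALSE)) {
    pos <- cohort[evaluate_definition(cohort, spec)$overall, ]
    if (nrow(pos) == 0) next
    for (cc in notch_cols) {
      bumped <- pos
      bumped[[cc]] <- TRUE
      expect_true(all(evaluate_definition(bumped, spec)$overall),
                  info = paste(spec$name, cc))
    }
  }
})
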