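test_that("Frechet pre-check accepts the published control margins", {
  # sex cutoff 95, >=2-of-6 notching 93, their conjunction (Strauss) 80:
  # within [max(0, 95+93-118), min(95, 93)] = [70, 93]
  cs <- lbbb_constraints("ctl", n = 118, sex = c(M = 50, F = 68),
                         constraints = c(sex_qrsd_cutoff = 95,
                                         notch_ge2_any6 = 93,
                                         strauss = 80))
  f <- frechet_feasibility(cs)
  expect_true(attr(f, "feasible"))
})

test_that("Frechet pre-check rejects an impossible intersection", {
  # |A| = 8, |B| = 7, n = 10 force |A & B| >= 5; 4 is impossible
  cs <- lbbb_constraints("toy", n = 10, sex = c(M = 5, F = 5),
                         constraints = c(rwpt_gt60_v5 = 8, rwpt_gt60_v6 = 7,
                                         rwpt_gt60_v56 = 4))
  f <- frechet_feasibility(cs)
  expect_false(attr(f, "feasible"))
  expect_true(any(grepl("frechet|implication", f$check[!f$pass])))
  expect_error(reconstruct_cohort(cs), "infeasible")
})

test_that("forced margins pass the pre-check", {
  cs <- lbbb_constraints("toy", n = 2, sex = c(M = 1, F = 1),
                         constraints = c(rwpt_gt60_v5 = 2, rwpt_gt60_v6 = 2,
                                         rwpt_gt60_v56 = 2))
  expect_true(attr(frechet_feasibility(cs), "feasible"))
})

test_that("all-n constraints produce an all-true feature matrix", {
  cs <- lbbb_constraints("toy", n = 5, sex = c(M = 5, F = 0),
                         constraints = c(notch_lateral_all = 5,
                                         rwpt_gt60_v56 = 5, qrsd_ge_140 = 5))
  cohort <- reconstruct_cohort(cs, seed = 3)
  expect_true(all(cohort$notch_I & cohort$notch_aVL & cohort$notch_V5 &
                    cohort$notch_V6))
  expect_true(all(cohort$rwpt_gt60_v5 & cohort$rwpt_gt60_v6))
  expect_true(all(cohort$qrsd_ms >= 140))
  expect_true(all(cohort$sex == "M"))
})

test_that("reconstruction satisfies every constraint and yields valid patients", {
  for (nm in c("table2_avi", "table2_control", "table3_crt")) {
    cs <- cohort_constraints(nm)
    cohort <- reconstruct_cohort(cs, seed = 1)
    expect_equal(nrow(cohort), cs$n)
    ver <- verify_constraints(cohort, cs)
    expect_true(attr(ver, "all_match"), info = nm)
    expect_equal(nrow(validate_features(cohort)), 0, info = nm)
    expect_true(all(evaluate_inclusion(cohort)$overall), info = nm)
  }
})

test_that("reconstruction is deterministic: same constraints + seed, same bytes", {
  cs <- cohort_constraints("table2_avi", features_only = TRUE)
  a <- reconstruct_cohort(cs, seed = 42)
  b <- reconstruct_cohort(cs, seed = 42)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("definition concordances are forced by feature margins alone", {
  # definition rows withheld: the counts below follow from the feature
  # marginals plus the rule logic, so they test the engines, not the fixture
  avi <- reconstruct_cohort(cohort_constraints("table2_avi",
                                               features_only = TRUE),
                            seed = 5)
  s <- glance(classify_cohort(avi, builtin_specs(include_variants = FALSE)))
  expect_equal(s$n_positive[s$definition == "esc2013"], 59L)
  expect_equal(s$n_positive[s$definition == "strauss"], 56L)
})

test_that("the printed CRT Strauss count is infeasible under the rule logic", {
  cs <- cohort_constraints("table3_crt")
  cs$constraints <- dplyr::bind_rows(cs$constraints,
                                     tibble::tibble(predicate = "strauss",
                                                    count = 32L))
  cs <- lbbb_constraints(cs$label, cs$n, cs$sex, cs$constraints)
  # 32 Strauss positives cannot coexist with 31 meeting the sex-specific
  # QRSD cutoff the definition requires
  expect_false(attr(frechet_feasibility(cs), "feasible"))
  expect_error(reconstruct_cohort(cs), "infeasible")
})

test_that("verification localizes a flipped flag to the affected constraints", {
  cs <- cohort_constraints("table2_avi", features_only = TRUE)
  cohort <- reconstruct_cohort(cs, seed = 1)
  tampered <- cohort
  row <- which(tampered$notch_I)[1]
  tampered$notch_I[row] <- FALSE
  ver <- verify_constraints(tampered, cs)
  expect_false(attr(ver, "all_match"))
  bad <- ver$predicate[!ver$match]
  expect_true(all(grepl("notch", bad)))
  # an empty constraint list is vacuously satisfied
  empty <- lbbb_constraints("e", n = 59, sex = cs$sex,
                            constraints = tibble::tibble(
                              predicate = character(), count = integer()))
  expect_true(attr(verify_constraints(cohort, empty), "all_match"))
})

test_that("unknown predicates are rejected up front", {
  expect_error(
    lbbb_constraints("x", n = 4, sex = c(M = 2, F = 2),
                     constraints = c(never_heard_of_it = 2)),
    "unknown predicate_id")
})
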