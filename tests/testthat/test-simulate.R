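test_that("simulation parameters are validated", {
  expect_error(sim_params(n = 0), "positive integer")
  expect_error(sim_params(n = 10, proximal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(n = 10, qrsd_sd = 0), "> 0")
  expect_error(sim_params(n = 10,
                          prevalence = c(rwpt_gt60_v5 = 0.9,
                                         rwpt_gt60_v6 = 0.2)),
               "nested")
  expect_error(default_sim_params("mars"), "arg")
})

test_that("population presets carry the published marginal rates", {
  avi <- default_sim_params("avi")
  expect_equal(avi$n, 59L)
  expect_equal(avi$prevalence[["notch_V5"]], 1)    # lateral notching 100%
  expect_equal(avi$qrsd_mean_M, 154)
  expect_equal(avi$qrsd_mean_F, 145)
  ctl <- default_sim_params("control")
  expect_equal(ctl$proximal_fraction, 0.85)        # lateral notching 85%
  expect_equal(ctl$n, 118L)
  crt <- default_sim_params("crt")
  expect_equal(crt$n, 33L)
  # implied all-four-lateral rate matches the printed 76%
  expect_equal(crt$prevalence[["notch_I"]] * crt$prevalence[["notch_aVL"]],
               25 / 33, tolerance = 1e-10)
})

test_that("degenerate prevalences are honored exactly", {
  co <- simulate_cohort(default_sim_params("avi", n = 200), seed = 1)
  expect_true(all(co$notch_V5))   # prevalence 1
  expect_true(all(co$notch_V6))
  expect_true(all(!co$q_V5 & !co$q_V6))  # prevalence 0
})

test_that("every simulated patient is valid and satisfies inclusion", {
  for (pop in c("avi", "control", "crt")) {
    co <- simulate_cohort(default_sim_params(pop, n = 300), seed = 2)
    expect_equal(nrow(validate_features(co)), 0, info = pop)
    expect_true(all(evaluate_inclusion(co)$overall), info = pop)
    expect_true(all(co$qrsd_ms >= 120), info = pop)
  }
})

test_that("simulation is reproducible under a seed", {
  a <- simulate_cohort(default_sim_params("control", n = 100), seed = 9)
  b <- simulate_cohort(default_sim_params("control", n = 100), seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("empirical prevalences sit inside central 99% binomial bounds", {
  n <- 2000
  sp <- default_sim_params("avi", n = n)
  co <- simulate_cohort(sp, seed = 31)
  pv <- sp$prevalence
  for (nm in setdiff(names(pv), "v1_qs")) {
    p <- pv[[nm]]
    if (p <= 0 || p >= 1) next
    k <- sum(co[[nm]])
    expect_gte(k, qbinom(0.005, n, p))
    expect_lte(k, qbinom(0.995, n, p))
  }
})

test_that("with full proximal fraction and AVI defaults ESC positivity is 100%", {
  co <- simulate_cohort(default_sim_params("avi", n = 500), seed = 4)
  s <- glance(classify_cohort(co, builtin_spec("esc2013")))
  expect_equal(s$percent, 100L)
})

test_that("latent-class structure separates lateral notching", {
  co <- simulate_cohort(default_sim_params("control", n = 2000), seed = 6)
  cls <- attr(co, "latent_class")
  lat_or <- eval_predicate(co, "notch_lateral_or")
  expect_true(mean(lat_or[cls == "proximal"]) > 0.99)
  expect_true(mean(lat_or[cls == "distal"]) < 0.05)
})

test_that("the QRSD sex effect is recoverable by OLS", {
  co <- simulate_cohort(default_sim_params("avi", n = 2000), seed = 8)
  fit <- recover_sex_effect(co)
  expect_true(fit$conf_low <= 9 && 9 <= fit$conf_high)
  expect_equal(nrow(tidy(fit)), 1)

  # equal means: interval covers zero
  sp0 <- sim_params(n = 1500, qrsd_mean_M = 150, qrsd_mean_F = 150)
  fit0 <- recover_sex_effect(simulate_cohort(sp0, seed = 10))
  expect_true(fit0$conf_low <= 0 && 0 <= fit0$conf_high)

  # constant QRSD: coefficient exactly zero
  cc <- simulate_cohort(sp0, seed = 11)
  cc$qrsd_ms <- 150
  expect_equal(recover_sex_effect(cc)$estimate, 0)

  single <- simulate_cohort(sp0, seed = 12)
  single$sex <- "F"
  expect_error(recover_sex_effect(single), "single sex")
})

test_that("sim params round-trip through YAML", {
  sp <- default_sim_params("control", n = 77, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_params_yaml(sp, f)
  sp2 <- read_sim_params_yaml(f)
  expect_equal(unclass(sp2), unclass(sp), tolerance = 1e-12)
})
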