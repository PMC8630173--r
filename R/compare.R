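# default feature rows of a two-cohort concordance report, in the row order
# of the published comparison table
COMPARISON_FEATURE_ROWS <- c(
  "qrsd_ge_120", "qrsd_ge_130", "sex_qrsd_cutoff", "v1_qs_rs",
  "no_q_v56", "no_q_v56_i", "no_q_v56_i_avl", "q_aVL",
  "rwpt_gt60_v56", "rwpt_gt60_v6_only",
  "notch_lateral_or", "notch_lateral_all", "notch_ge2_any6")

#' Two-cohort concordance comparison
#'
#' Builds a comparison-table report between two cohorts: one row per feature
#' predicate and per LBBB definition, with counts, percentages (integer,
#' rounded half away from zero, plus a 4-decimal form) and a two-group test.
#' The test per row is Fisher's exact test when any expected cell count is
#' below 5 and the (uncorrected) chi-square test otherwise; rows where the
#' predicate holds for every patient of both cohorts are marked `NP` (not
#' possible) and carry no p-value.
#'
#' @param cohort_a,cohort_b Cohort tibbles.
#' @param specs Definitions to include (default: all built-ins).
#' @param feature_rows Feature predicate ids to include.
#' @param labels Length-2 character vector naming the cohorts.
#' @return A tibble of class `lbbb_comparison` with columns `row_type`,
#'   `predicate`, counts/percentages per cohort, `test`, `statistic`,
#'   `p_value`.
#' @examples
#' a <- simulate_cohort(default_sim_params("avi", n = 50), seed = 1)
#' b <- simulate_cohort(default_sim_params("control", n = 100), seed = 2)
#' compare_cohorts(a, b)
#' @export
compare_cohorts <- function(cohort_a, cohort_b, specs = builtin_specs(),
                            feature_rows = COMPARISON_FEATURE_ROWS,
                            labels = c("A", "B")) {
  cohort_a <- assert_cohort(cohort_a, "cohort_a")
  cohort_b <- assert_cohort(cohort_b, "cohort_b")
  if (inherits(specs, "lbbb_definition")) specs <- list(specs)
  na <- nrow(cohort_a); nb <- nrow(cohort_b)
  rows <- c(setNames(as.list(feature_rows), feature_rows))
  row_type <- setNames(rep("feature", length(feature_rows)), feature_rows)
  for (s in specs) {
    rows[[s$name]] <- s$name
    row_type[s$name] <- "definition"
  }
  out <- bind_rows(lapply(names(rows), function(pid) {
    ka <- sum(eval_predicate(cohort_a, pid))
    kb <- sum(eval_predicate(cohort_b, pid))
    res <- row_test(ka, na, kb, nb)
    tibble(row_type = row_type[[pid]], predicate = pid,
           count_a = ka, percent_a = pct_int(ka, na),
           percent_exact_a = pct_exact(ka, na),
           count_b = kb, percent_b = pct_int(kb, nb),
           percent_exact_b = pct_exact(kb, nb),
           test = res$test, statistic = res$statistic, p_value = res$p)
  }))
  structure(out, labels = labels, n_a = na, n_b = nb,
            class = c("lbbb_comparison", class(out)))
}

# test-selection rule (the published analysis does not state per-row choice):
# Fisher when any expected cell < 5, chi-square otherwise; NP when the
# predicate is constant-true in both cohorts
row_test <- function(ka, na, kb, nb) {
  if (ka == na && kb == nb)
    return(list(test = "NP", statistic = NA_real_, p = NA_real_))
  t <- two_by_two(ka, na - ka, kb, nb - kb)
  n <- na + nb
  expected <- outer(c(na, nb), c(ka + kb, n - ka - kb)) / n
  if (any(expected < 5)) {
    f <- fisher_exact(t)
    list(test = "fisher", statistic = NA_real_, p = f$p_two_sided)
  } else {
    cs <- chi_square(t)
    list(test = "chi_square", statistic = cs$statistic, p = cs$p)
  }
}

#' @export
print.lbbb_comparison <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("<lbbb_comparison> ", lab[1], " (n = ", attr(x, "n_a"), ") vs ",
      lab[2], " (n = ", attr(x, "n_b"), ")\n", sep = "")
  print(as_tibble(x), n = Inf)
  invisible(x)
}

#' @rdname compare_cohorts
#' @param object An `lbbb_comparison`.
#' @param ... Unused.
#' @export
autoplot.lbbb_comparison <- function(object, ...) {
  lab <- attr(object, "labels")
  df <- as_tibble(object) %>%
    select("predicate", "row_type", "percent_exact_a", "percent_exact_b") %>%
    tidyr::pivot_longer(c("percent_exact_a", "percent_exact_b"),
                        names_to = "cohort", values_to = "percent") %>%
    mutate(cohort = ifelse(.data$cohort == "percent_exact_a",
                           lab[1], lab[2]))
  df$predicate <- factor(df$predicate, levels = rev(unique(object$predicate)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent, y = .data$predicate,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Patients fulfilling criterion (%)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write a comparison report to disk
#'
#' @param x An `lbbb_comparison`.
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"md"` (a Markdown table mirroring the
#'   published row order).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path, format = c("csv", "json", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "lbbb_comparison"))
  df <- as_tibble(x)
  if (format == "csv") {
    readr::write_csv(df, path)
  } else if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    lab <- attr(x, "labels")
    fmt_p <- function(p, test) ifelse(test == "NP", "NP",
                                      ifelse(p < 0.001, "<0.001",
                                             sprintf("%.3f", p)))
    lines <- c(
      paste0("| Criterion | ", lab[1], " (n=", attr(x, "n_a"), ") | ",
             lab[2], " (n=", attr(x, "n_b"), ") | test | p |"),
      "|---|---|---|---|---|",
      sprintf("| %s | %d (%d) | %d (%d) | %s | %s |",
              df$predicate, df$count_a, df$percent_a, df$count_b,
              df$percent_b, df$test, fmt_p(df$p_value, df$test)))
    writeLines(lines, path)
  }
  invisible(path)
}
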