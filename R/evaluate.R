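#' Evaluate the broad LBBB inclusion criteria
#'
#' The permissive screening definition used to assemble LBBB cohorts before
#' any strict definition is applied: QRS duration >= 120 ms, QS or rS
#' morphology in V1, and absence of Q waves in V5 and V6.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with `patient_id`, one logical column per criterion
#'   (`qrsd_ge_120`, `v1_qs_rs`, `no_q_v5`, `no_q_v6`) and `overall`, the
#'   conjunction of all criteria.
#' @export
evaluate_inclusion <- function(cohort) {
  cohort <- as_tibble(cohort)
  tibble(
    patient_id = cohort$patient_id,
    qrsd_ge_120 = cohort$qrsd_ms >= 120,
    v1_qs_rs = cohort$v1_morphology %in% c("QS", "rS"),
    no_q_v5 = !cohort$q_V5,
    no_q_v6 = !cohort$q_V6
  ) %>%
    mutate(overall = .data$qrsd_ge_120 & .data$v1_qs_rs & .data$no_q_v5 &
             .data$no_q_v6)
}

qrsd_criterion <- function(cohort, rule) {
  switch(rule,
         fixed_120 = cohort$qrsd_ms >= 120,
         fixed_130 = cohort$qrsd_ms >= 130,
         sex_specific_130F_140M = {
           if (anyNA(cohort$sex) || !all(cohort$sex %in% c("M", "F"))) {
             bad <- cohort$patient_id[is.na(cohort$sex) |
                                        !cohort$sex %in% c("M", "F")]
             abort(paste0("sex is required for a sex-specific QRSD rule; ",
                          "missing/invalid for patient(s): ",
                          paste(bad, collapse = ", ")))
           }
           cohort$qrsd_ms >= ifelse(cohort$sex == "F", 130, 140)
         },
         abort(paste0("unknown qrsd_rule: ", rule)))
}

#' Evaluate one LBBB definition on a cohort
#'
#' Scores every patient against a rule set and reports each criterion
#' separately. The verdict (`overall`) is the conjunction of all binding
#' criteria; when the definition carries an ancillary axis flag it is
#' reported in `ancillary_axis_leftward` (missing axis gives `NA`) and is
#' never part of `overall`.
#'
#' @param cohort A cohort tibble.
#' @param spec An [lbbb_definition()].
#' @return A tibble with `patient_id`, `definition`, one logical column per
#'   criterion (`qrsd`, `v1`, `q_waves`, `notch`, and `rwpt` when required),
#'   `overall`, and `ancillary_axis_leftward` when applicable.
#' @examples
#' cohort <- simulate_cohort(sim_params(n = 10, seed = 1))
#' evaluate_definition(cohort, builtin_spec("strauss"))
#' @export
evaluate_definition <- function(cohort, spec) {
  stopifnot(inherits(spec, "lbbb_definition"))
  cohort <- as_tibble(cohort)
  crit <- tibble(patient_id = cohort$patient_id, definition = spec$name)
  crit$qrsd <- qrsd_criterion(cohort, spec$qrsd_rule)
  crit$v1 <- cohort$v1_morphology %in% c("QS", "rS")
  qcols <- q_col(spec$q_forbidden_leads)
  crit$q_waves <- if (length(qcols) == 0) rep(TRUE, nrow(cohort)) else
    !Reduce(`|`, lapply(qcols, function(cc) cohort[[cc]]))
  notch_mat <- do.call(cbind, lapply(notch_col(spec$notch_lead_set),
                                     function(cc) cohort[[cc]]))
  n_notched <- rowSums(notch_mat)
  need <- if (identical(spec$notch_min_count, "all"))
    length(spec$notch_lead_set) else spec$notch_min_count
  crit$notch <- n_notched >= need
  if (spec$rwpt_required)
    crit$rwpt <- cohort$rwpt_gt60_v5 & cohort$rwpt_gt60_v6
  crit_cols <- setdiff(names(crit), c("patient_id", "definition"))
  crit$overall <- Reduce(`&`, crit[crit_cols])
  if (spec$axis_ancillary)
    crit$ancillary_axis_leftward <-
      cohort$frontal_axis_deg <= spec$axis_threshold_deg
  crit
}

#' Classify a cohort against a set of LBBB definitions
#'
#' Applies [evaluate_definition()] for each definition and tabulates the
#' positive count and percentage per definition. Percentages are rounded half
#' away from zero to integers (the convention of the published tables) with a
#' 4-decimal companion.
#'
#' @param cohort A cohort tibble.
#' @param specs A list of [lbbb_definition()] objects (default: all built-in
#'   definitions), or a single definition.
#' @return An object of class `lbbb_classification` with components
#'   `results` (long per-patient verdicts), `summary` (per-definition counts
#'   and percentages), and `details` (per-definition criterion tables).
#' @examples
#' cohort <- simulate_cohort(sim_params(n = 50, seed = 1))
#' cls <- classify_cohort(cohort)
#' glance(cls)
#' @export
classify_cohort <- function(cohort, specs = builtin_specs()) {
  cohort <- assert_cohort(cohort)
  if (inherits(specs, "lbbb_definition")) specs <- list(specs)
  if (length(specs) > 0 && is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  details <- lapply(specs, function(s) evaluate_definition(cohort, s))
  results <- if (length(details) == 0)
    tibble(definition = character(), patient_id = character(),
           overall = logical())
  else
    bind_rows(lapply(details, function(d)
      d[, c("definition", "patient_id", "overall")]))
  n <- nrow(cohort)
  summary <- if (length(details) == 0)
    tibble(definition = character(), n_positive = integer(), n = integer(),
           percent = integer(), percent_exact = double())
  else
    bind_rows(lapply(details, function(d)
      tibble(definition = d$definition[1],
             n_positive = sum(d$overall), n = n,
             percent = pct_int(sum(d$overall), n),
             percent_exact = pct_exact(sum(d$overall), n))))
  structure(list(results = results, summary = summary, details = details,
                 n = n),
            class = "lbbb_classification")
}

#' @export
print.lbbb_classification <- function(x, ...) {
  cat("<lbbb_classification> ", x$n, " patients, ",
      length(x$details), " definition(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname classify_cohort
#' @param x An `lbbb_classification`.
#' @param ... Unused.
#' @export
tidy.lbbb_classification <- function(x, ...) x$results

#' @rdname classify_cohort
#' @export
glance.lbbb_classification <- function(x, ...) x$summary

#' @rdname classify_cohort
#' @param object An `lbbb_classification`.
#' @export
autoplot.lbbb_classification <- function(object, ...) {
  df <- object$summary
  df$definition <- factor(df$definition, levels = df$definition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$definition,
                                   y = .data$percent_exact)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n_positive, " (",
                                                   .data$percent, "%)")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Definition positive (%)",
                  title = "Concordance with LBBB definitions") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
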