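#' Parameterized LBBB definitions
#'
#' An `lbbb_definition` is a small parameter object describing one
#' electrocardiographic LBBB rule set: the QRS-duration rule, the V1
#' morphology requirement, the leads in which Q waves are forbidden, the
#' notch/slur lead set with its minimum count, whether R-wave peak time
#' > 60 ms is required in both V5 and V6, and whether a leftward frontal-axis
#' flag is reported as an ancillary (non-binding) criterion.
#'
#' @param name Definition name (free text).
#' @param qrsd_rule One of `"fixed_120"` (QRSD >= 120 ms), `"fixed_130"`
#'   (>= 130 ms) or `"sex_specific_130F_140M"` (>= 130 ms in females,
#'   >= 140 ms in males).
#' @param q_forbidden_leads Leads in which any Q wave disqualifies; subset of
#'   I, aVL, V5, V6.
#' @param notch_lead_set Leads counted for the notch/slur criterion.
#' @param notch_min_count Minimum number of notched/slurred leads in
#'   `notch_lead_set`, or `"all"` to require every lead in the set.
#' @param rwpt_required Require R-wave peak time > 60 ms in both V5 and V6.
#' @param axis_ancillary Report a leftward-axis flag (axis <=
#'   `axis_threshold_deg`) alongside, but never inside, the verdict.
#' @param axis_threshold_deg Ancillary axis threshold in degrees (default +30,
#'   the package's reading of "leftward"; configurable because published
#'   guidance recommends against a hard cut-off).
#' @return An object of class `lbbb_definition`.
#' @seealso [builtin_spec()] for the shipped definitions.
#' @export
lbbb_definition <- function(name,
                            qrsd_rule = c("fixed_120", "fixed_130",
                                          "sex_specific_130F_140M"),
                            q_forbidden_leads = c("V5", "V6"),
                            notch_lead_set = LEADS_LATERAL,
                            notch_min_count = 1,
                            rwpt_required = FALSE,
                            axis_ancillary = FALSE,
                            axis_threshold_deg = 30) {
  qrsd_rule <- match.arg(qrsd_rule)
  stopifnot(is.character(name), length(name) == 1)
  q_forbidden_leads <- as.character(q_forbidden_leads)
  if (!all(q_forbidden_leads %in% Q_LEADS))
    abort(paste0("q_forbidden_leads must be a subset of ",
                 paste(Q_LEADS, collapse = ", ")))
  notch_lead_set <- as.character(notch_lead_set)
  if (length(notch_lead_set) == 0 || !all(notch_lead_set %in% NOTCH_LEADS))
    abort("notch_lead_set must be a non-empty subset of the coded notch leads")
  if (!identical(notch_min_count, "all")) {
    notch_min_count <- as.integer(notch_min_count)
    if (is.na(notch_min_count) || notch_min_count < 1 ||
        notch_min_count > length(notch_lead_set))
      abort("notch_min_count must be 'all' or an integer in [1, |notch_lead_set|]")
  }
  structure(
    list(name = name, qrsd_rule = qrsd_rule,
         v1_rule = "qs_or_rs_required",
         q_forbidden_leads = q_forbidden_leads,
         notch_lead_set = notch_lead_set,
         notch_min_count = notch_min_count,
         rwpt_required = isTRUE(rwpt_required),
         axis_ancillary = isTRUE(axis_ancillary),
         axis_threshold_deg = axis_threshold_deg),
    class = "lbbb_definition")
}

#' @export
print.lbbb_definition <- function(x, ...) {
  cat("<lbbb_definition> ", x$name, "\n", sep = "")
  cat("  QRSD rule:      ", x$qrsd_rule, "\n", sep = "")
  cat("  V1 morphology:  QS or rS required\n")
  cat("  Q forbidden in: ", paste(x$q_forbidden_leads, collapse = ", "), "\n",
      sep = "")
  nmc <- if (identical(x$notch_min_count, "all")) "all" else
    paste0(">= ", x$notch_min_count)
  cat("  Notch/slur:     ", nmc, " of {",
      paste(x$notch_lead_set, collapse = ", "), "}\n", sep = "")
  cat("  RWPT > 60 ms in V5 and V6 required: ", x$rwpt_required, "\n", sep = "")
  if (x$axis_ancillary)
    cat("  Ancillary axis flag: axis <= ", x$axis_threshold_deg, " deg\n",
        sep = "")
  invisible(x)
}

#' Built-in LBBB definitions
#'
#' Returns one of the shipped rule sets:
#' \describe{
#'   \item{`esc2013`}{QRSD >= 120 ms; QS or rS in V1; no Q wave in V5/V6;
#'     notch/slur in at least one lateral lead (I, aVL, V5, V6); no RWPT
#'     requirement.}
#'   \item{`strauss`}{Sex-specific QRSD (>= 130 ms female, >= 140 ms male);
#'     QS or rS in V1; no Q wave in V5/V6; notch/slur in at least 2 of I, aVL,
#'     V1, V2, V5, V6; no RWPT requirement. The original mid-QRS notch-timing
#'     qualifier is not evaluated because notch flags are coded without
#'     timing.}
#'   \item{`aha2009`}{QRSD >= 120 ms; QS or rS in V1; no Q wave in I, V5, V6;
#'     notch/slur in all four lateral leads; RWPT > 60 ms required in both V5
#'     and V6.}
#'   \item{`aha2009_variant`}{AHA 2009 with the Q-wave lead set and the RWPT
#'     requirement varied via `q_forbidden_leads` (one of
#'     `c("V5","V6","I")` or `c("V5","V6","I","aVL")`) and `rwpt_required`.}
#'   \item{`proposed`}{Proximal-LBBB definition: QRSD >= 120 ms; QS or rS in
#'     V1; no Q wave in V5/V6 only (small q permitted in I and aVL);
#'     notch/slur in at least 2 of the four lateral leads; no RWPT
#'     requirement; leftward frontal axis reported as an ancillary flag.}
#' }
#'
#' @param name One of `"esc2013"`, `"strauss"`, `"aha2009"`,
#'   `"aha2009_variant"`, `"proposed"`.
#' @param q_forbidden_leads,rwpt_required Variant parameters, used by
#'   `aha2009_variant` only.
#' @param axis_threshold_deg Ancillary axis threshold for `proposed`.
#' @return An [lbbb_definition()].
#' @examples
#' builtin_spec("strauss")
#' builtin_spec("aha2009_variant", q_forbidden_leads = c("V5", "V6", "I"),
#'              rwpt_required = FALSE)
#' @export
builtin_spec <- function(name, q_forbidden_leads = c("V5", "V6", "I"),
                         rwpt_required = TRUE, axis_threshold_deg = 30) {
  switch(
    name,
    esc2013 = lbbb_definition("esc2013", "fixed_120",
                              q_forbidden_leads = c("V5", "V6"),
                              notch_lead_set = LEADS_LATERAL,
                              notch_min_count = 1),
    strauss = lbbb_definition("strauss", "sex_specific_130F_140M",
                              q_forbidden_leads = c("V5", "V6"),
                              notch_lead_set = c("I", "aVL", "V1", "V2",
                                                 "V5", "V6"),
                              notch_min_count = 2),
    aha2009 = lbbb_definition("aha2009", "fixed_120",
                              q_forbidden_leads = c("V5", "V6", "I"),
                              notch_lead_set = LEADS_LATERAL,
                              notch_min_count = "all",
                              rwpt_required = TRUE),
    aha2009_variant = {
      qset <- as.character(q_forbidden_leads)
      if (!setequal(qset, c("V5", "V6", "I")) &&
          !setequal(qset, c("V5", "V6", "I", "aVL")))
        abort("aha2009_variant: q_forbidden_leads must be {V5,V6,I} or {V5,V6,I,aVL}")
      vname <- paste0("aha2009_",
                      if (setequal(qset, c("V5", "V6", "I"))) "qV56I"
                      else "qV56IaVL",
                      if (rwpt_required) "_rwpt" else "_norwpt")
      lbbb_definition(vname, "fixed_120",
                      q_forbidden_leads = q_forbidden_leads,
                      notch_lead_set = LEADS_LATERAL,
                      notch_min_count = "all",
                      rwpt_required = rwpt_required)
    },
    proposed = lbbb_definition("proposed", "fixed_120",
                               q_forbidden_leads = c("V5", "V6"),
                               notch_lead_set = LEADS_LATERAL,
                               notch_min_count = 2,
                               axis_ancillary = TRUE,
                               axis_threshold_deg = axis_threshold_deg),
    abort(paste0("unknown definition name: '", name, "'"))
  )
}

#' The four core definitions plus AHA variants, in published-table order
#'
#' Convenience list used throughout: ESC 2013, Strauss, AHA 2009, the four
#' AHA 2009 variants, and the proximal-LBBB proposal.
#'
#' @param include_variants Include the four AHA 2009 variants.
#' @param include_proposed Include the proximal-LBBB definition.
#' @return Named list of [lbbb_definition()] objects.
#' @export
builtin_specs <- function(include_variants = TRUE, include_proposed = TRUE) {
  specs <- list(builtin_spec("esc2013"), builtin_spec("strauss"),
                builtin_spec("aha2009"))
  if (include_variants) {
    specs <- c(specs, list(
      builtin_spec("aha2009_variant", c("V5", "V6", "I"), TRUE),
      builtin_spec("aha2009_variant", c("V5", "V6", "I", "aVL"), TRUE),
      builtin_spec("aha2009_variant", c("V5", "V6", "I"), FALSE),
      builtin_spec("aha2009_variant", c("V5", "V6", "I", "aVL"), FALSE)))
  }
  if (include_proposed) specs <- c(specs, list(builtin_spec("proposed")))
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' Read / write definition specs as YAML
#'
#' Definitions serialize to a flat YAML mapping so users can ship custom rule
#' sets; files for the built-in definitions are installed under
#' `system.file("extdata", "definitions", package = "lbbbr")`.
#'
#' @param spec An [lbbb_definition()].
#' @param path File path.
#' @return `write_definition_yaml` returns `path` invisibly;
#'   `read_definition_yaml` returns an [lbbb_definition()].
#' @export
write_definition_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "lbbb_definition"))
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_definition_yaml
#' @export
read_definition_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  lbbb_definition(name = x$name, qrsd_rule = x$qrsd_rule,
                  q_forbidden_leads = unlist(x$q_forbidden_leads),
                  notch_lead_set = unlist(x$notch_lead_set),
                  notch_min_count = x$notch_min_count,
                  rwpt_required = x$rwpt_required,
                  axis_ancillary = x$axis_ancillary,
                  axis_threshold_deg = x$axis_threshold_deg %||% 30)
}
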