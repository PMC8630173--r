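#' Named feature predicates
#'
#' Count constraints and comparison reports refer to boolean functions of a
#' patient's coded features by a stable `predicate_id`. The registry covers
#' single-lead flags (`notch_V5`, `q_aVL`, ...), the threshold and
#' combination rows of the published feature tables (`qrsd_ge_130`,
#' `sex_qrsd_cutoff`, `notch_lateral_or`, `rwpt_gt60_v56`, ...), the broad
#' `inclusion` rule, and every built-in definition name (`esc2013`,
#' `strauss`, `aha2009`, the AHA variants, `proposed`), which are evaluated
#' through the rule engines.
#'
#' @return `predicate_ids()` returns the registered identifiers;
#'   `eval_predicate()` a logical vector over the cohort's rows;
#'   `predicate_matrix()` a logical matrix with one column per predicate.
#' @param cohort A cohort tibble.
#' @param id,ids Predicate identifier(s).
#' @name predicates
NULL

notch_count <- function(cohort, leads)
  rowSums(do.call(cbind, lapply(notch_col(leads), function(cc) cohort[[cc]])))

definition_overall <- function(cohort, spec_name) {
  specs <- builtin_specs()
  if (!spec_name %in% names(specs)) abort(paste0("unknown spec ", spec_name))
  evaluate_definition(cohort, specs[[spec_name]])$overall
}

make_predicate_registry <- function() {
  reg <- list(
    sex_male = function(ch) ch$sex == "M",
    sex_female = function(ch) ch$sex == "F",
    qrsd_ge_120 = function(ch) ch$qrsd_ms >= 120,
    qrsd_ge_130 = function(ch) ch$qrsd_ms >= 130,
    qrsd_ge_140 = function(ch) ch$qrsd_ms >= 140,
    sex_qrsd_cutoff = function(ch)
      ch$qrsd_ms >= ifelse(ch$sex == "F", 130, 140),
    v1_qs_rs = function(ch) ch$v1_morphology %in% c("QS", "rS"),
    no_q_v56 = function(ch) !ch$q_V5 & !ch$q_V6,
    no_q_v56_i = function(ch) !ch$q_V5 & !ch$q_V6 & !ch$q_I,
    no_q_v56_i_avl = function(ch) !ch$q_V5 & !ch$q_V6 & !ch$q_I & !ch$q_aVL,
    rwpt_gt60_v56 = function(ch) ch$rwpt_gt60_v5 & ch$rwpt_gt60_v6,
    rwpt_gt60_v6_only = function(ch) ch$rwpt_gt60_v6 & !ch$rwpt_gt60_v5,
    notch_lateral_or = function(ch) notch_count(ch, LEADS_LATERAL) >= 1,
    notch_lateral_all = function(ch) notch_count(ch, LEADS_LATERAL) >= 4,
    notch_lateral_ge2 = function(ch) notch_count(ch, LEADS_LATERAL) >= 2,
    notch_ge2_any6 = function(ch)
      notch_count(ch, c("I", "aVL", "V1", "V2", "V5", "V6")) >= 2,
    notch_inferior_or = function(ch) notch_count(ch, LEADS_INFERIOR) >= 1,
    notch_septal_or = function(ch) notch_count(ch, LEADS_SEPTAL) >= 1,
    inclusion = function(ch) evaluate_inclusion(ch)$overall
  )
  for (lead in NOTCH_LEADS) {
    local({
      cc <- notch_col(lead)
      reg[[cc]] <<- function(ch) ch[[cc]]
    })
  }
  for (lead in Q_LEADS) {
    local({
      cc <- q_col(lead)
      reg[[cc]] <<- function(ch) ch[[cc]]
    })
  }
  reg$rwpt_gt60_v5 <- function(ch) ch$rwpt_gt60_v5
  reg$rwpt_gt60_v6 <- function(ch) ch$rwpt_gt60_v6
  for (nm in names(builtin_specs())) {
    local({
      spec_name <- nm
      reg[[spec_name]] <<- function(ch) definition_overall(ch, spec_name)
    })
  }
  reg
}

PREDICATES <- NULL  # populated at load time (.onLoad)

.onLoad <- function(libname, pkgname) {
  assign("PREDICATES", make_predicate_registry(),
         envir = parent.env(environment()))
}

#' @rdname predicates
#' @export
predicate_ids <- function() names(PREDICATES)

#' @rdname predicates
#' @export
eval_predicate <- function(cohort, id) {
  if (!id %in% names(PREDICATES))
    abort(paste0("unknown predicate_id: '", id, "'"))
  PREDICATES[[id]](as_tibble(cohort))
}

#' @rdname predicates
#' @export
predicate_matrix <- function(cohort, ids) {
  cohort <- as_tibble(cohort)
  m <- matrix(FALSE, nrow = nrow(cohort), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (id in ids) m[, id] <- eval_predicate(cohort, id)
  m
}
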