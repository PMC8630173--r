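#' Cohort count constraints
#'
#' A constraint set names a cohort, its size, its sex split, and a list of
#' `(predicate, count)` pairs: each predicate (see [predicates]) must hold
#' for exactly `count` of the cohort's patients. This is the machine-readable
#' form of a published "number (percentage)" table column, and the input to
#' [reconstruct_cohort()].
#'
#' @param label Cohort label.
#' @param n Cohort size.
#' @param sex Named integer vector `c(M = , F = )`; must sum to `n`.
#' @param constraints A data frame with columns `predicate` and `count`, or a
#'   named integer vector.
#' @return An object of class `lbbb_constraints`.
#' @examples
#' lbbb_constraints("toy", n = 4, sex = c(M = 2, F = 2),
#'                  constraints = c(notch_lateral_or = 4, qrsd_ge_130 = 3))
#' @export
lbbb_constraints <- function(label, n, sex, constraints) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("cohort size n must be a positive integer")
  sex <- setNames(as.integer(sex[c("M", "F")]), c("M", "F"))
  if (anyNA(sex) || any(sex < 0) || sum(sex) != n)
    abort("sex counts must be non-negative and sum to n")
  if (!is.data.frame(constraints))
    constraints <- tibble(predicate = names(constraints),
                          count = as.integer(constraints))
  constraints <- as_tibble(constraints)[, c("predicate", "count")]
  constraints$count <- as.integer(constraints$count)
  if (anyNA(constraints$count) || any(constraints$count < 0) ||
      any(constraints$count > n))
    abort("every constraint count must lie in [0, n]")
  if (anyDuplicated(constraints$predicate))
    abort("predicate ids must be unique within a constraint set")
  unknown <- setdiff(constraints$predicate, predicate_ids())
  if (length(unknown) > 0)
    abort(paste0("unknown predicate_id: ",
                 paste(unknown, collapse = ", ")))
  structure(list(label = label, n = n, sex = sex, constraints = constraints),
            class = "lbbb_constraints")
}

#' @export
print.lbbb_constraints <- function(x, ...) {
  cat("<lbbb_constraints> ", x$label, ": n = ", x$n, " (M ", x$sex[["M"]],
      ", F ", x$sex[["F"]], "), ", nrow(x$constraints), " constraint(s)\n",
      sep = "")
  print(x$constraints, n = Inf)
  invisible(x)
}

#' Read / write constraint sets (YAML or JSON)
#'
#' The YAML schema is `{label, n, sex: {M, F}, constraints: [{predicate,
#' count}, ...]}`. Fixtures transcribed from the published cohort tables are
#' installed under `system.file("extdata", package = "lbbbr")`:
#' `table2_avi.yaml` (n = 59), `table2_control.yaml` (n = 118) and
#' `table3_crt.yaml` (n = 33).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param cs An `lbbb_constraints` object.
#' @return `read_constraints` returns an [lbbb_constraints()] object.
#' @export
read_constraints <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  # a bare `n:` key is YAML-1.1 boolean shorthand; tolerate both spellings
  names(x)[names(x) == "FALSE"] <- "n"
  cons <- bind_rows(lapply(x$constraints, function(cc)
    tibble(predicate = cc$predicate, count = as.integer(cc$count))))
  lbbb_constraints(label = x$label, n = x$n,
                   sex = c(M = x$sex$M, F = x$sex$F), constraints = cons)
}

#' @rdname read_constraints
#' @export
write_constraints <- function(cs, path) {
  stopifnot(inherits(cs, "lbbb_constraints"))
  obj <- list(label = cs$label, n = cs$n,
              sex = list(M = unname(cs$sex[["M"]]), F = unname(cs$sex[["F"]])),
              constraints = lapply(seq_len(nrow(cs$constraints)), function(i)
                list(predicate = cs$constraints$predicate[i],
                     count = cs$constraints$count[i])))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Load a shipped constraint fixture
#'
#' @param name One of `"table2_avi"`, `"table2_control"`, `"table3_crt"`.
#' @param features_only Drop the definition-level rows (the `esc2013`,
#'   `strauss`, `aha2009*` constraints), keeping only feature-level counts.
#'   Used to show that definition concordances are forced by the feature
#'   marginals plus the rule logic rather than baked into the fixture.
#' @return An [lbbb_constraints()] object.
#' @export
cohort_constraints <- function(name = c("table2_avi", "table2_control",
                                        "table3_crt"),
                               features_only = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "lbbbr")
  cs <- read_constraints(path)
  if (features_only) {
    defs <- names(builtin_specs())
    cs$constraints <- cs$constraints[!cs$constraints$predicate %in% defs, ]
  }
  cs
}
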