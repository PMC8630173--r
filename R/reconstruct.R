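# ---- constraint-based cohort reconstruction -------------------------------
#
# A published cohort table gives marginal counts of feature predicates (and
# definition verdicts). reconstruct_cohort() materializes a patient-level
# feature matrix hitting every count exactly: patients are drawn from a
# deduplicated space of feature archetypes (distinct combinations of the base
# features any constrained predicate depends on) by a depth-first search with
# constraint propagation; logical relations between constrained predicates
# (implication, conjunction/Frechet bounds) are derived from the archetype
# truth table and used for pruning. The seed only permutes tie-breaking
# order among equally attractive archetypes, so reconstruction is
# deterministic for a given (constraint set, seed).

# every predicate is a conjunction of atomic factors; each factor carries the
# base features it depends on and an evaluator, so the reconstructor can
# (a) derive static dependencies and (b) detect factors that are forced true
# on the admissible archetype space and drop them from the dependency graph
PRED_FACTORS <- local({
  lat_n <- function(ch) rowSums(cbind(ch$notch_I, ch$notch_aVL, ch$notch_V5,
                                      ch$notch_V6))
  fac <- function(req, fn) list(req = req, fn = fn)
  lat <- paste0("notch_", c("I", "aVL", "V5", "V6"))
  six <- paste0("notch_", c("I", "aVL", "V1", "V2", "V5", "V6"))
  inf <- paste0("notch_", c("II", "III", "aVF"))
  f_male <- fac("sex", function(ch) ch$sex == "M")
  f_120 <- fac("qrsd", function(ch) ch$qrsd_ms >= 120)
  f_130 <- fac("qrsd", function(ch) ch$qrsd_ms >= 130)
  f_140 <- fac("qrsd", function(ch) ch$qrsd_ms >= 140)
  f_cut <- fac(c("sex", "qrsd"),
               function(ch) ch$qrsd_ms >= ifelse(ch$sex == "F", 130, 140))
  f_v1 <- fac("v1", function(ch) ch$v1_morphology %in% c("QS", "rS"))
  f_noq <- lapply(c("q_I", "q_aVL", "q_V5", "q_V6"), function(cc)
    fac(cc, function(ch) !ch[[cc]]))
  names(f_noq) <- c("q_I", "q_aVL", "q_V5", "q_V6")
  f_q <- lapply(c("q_I", "q_aVL", "q_V5", "q_V6"), function(cc)
    fac(cc, function(ch) ch[[cc]]))
  names(f_q) <- names(f_noq)
  f_rw5 <- fac("rwpt_v5", function(ch) ch$rwpt_gt60_v5)
  f_rw6 <- fac("rwpt_v6", function(ch) ch$rwpt_gt60_v6)
  f_norw5 <- fac("rwpt_v5", function(ch) !ch$rwpt_gt60_v5)
  f_lat_or <- fac(lat, function(ch) lat_n(ch) >= 1)
  f_lat_ge2 <- fac(lat, function(ch) lat_n(ch) >= 2)
  f_lat_all <- fac(lat, function(ch) lat_n(ch) >= 4)
  f_ge2any6 <- fac(six, function(ch)
    lat_n(ch) + ch$notch_V1 + ch$notch_V2 >= 2)
  f_inf <- fac(inf, function(ch)
    ch$notch_II | ch$notch_III | ch$notch_aVF)
  f_sep <- fac(c("notch_V1", "notch_V2"),
               function(ch) ch$notch_V1 | ch$notch_V2)
  incl <- list(f_120, f_v1, f_noq$q_V5, f_noq$q_V6)
  fl <- list(
    sex_male = list(f_male),
    sex_female = list(fac("sex", function(ch) ch$sex == "F")),
    qrsd_ge_120 = list(f_120), qrsd_ge_130 = list(f_130),
    qrsd_ge_140 = list(f_140),
    sex_qrsd_cutoff = list(f_cut),
    v1_qs_rs = list(f_v1),
    no_q_v56 = list(f_noq$q_V5, f_noq$q_V6),
    no_q_v56_i = list(f_noq$q_V5, f_noq$q_V6, f_noq$q_I),
    no_q_v56_i_avl = list(f_noq$q_V5, f_noq$q_V6, f_noq$q_I, f_noq$q_aVL),
    q_I = list(f_q$q_I), q_aVL = list(f_q$q_aVL),
    q_V5 = list(f_q$q_V5), q_V6 = list(f_q$q_V6),
    rwpt_gt60_v5 = list(f_rw5), rwpt_gt60_v6 = list(f_rw6),
    rwpt_gt60_v56 = list(f_rw5, f_rw6),
    rwpt_gt60_v6_only = list(f_rw6, f_norw5),
    notch_lateral_or = list(f_lat_or), notch_lateral_all = list(f_lat_all),
    notch_lateral_ge2 = list(f_lat_ge2),
    notch_ge2_any6 = list(f_ge2any6),
    notch_inferior_or = list(f_inf), notch_septal_or = list(f_sep),
    inclusion = incl,
    esc2013 = c(incl, list(f_lat_or)),
    strauss = list(f_cut, f_v1, f_noq$q_V5, f_noq$q_V6, f_ge2any6),
    aha2009 = c(incl, list(f_noq$q_I, f_lat_all, f_rw5, f_rw6)),
    aha2009_qV56I_rwpt = c(incl, list(f_noq$q_I, f_lat_all, f_rw5, f_rw6)),
    aha2009_qV56IaVL_rwpt = c(incl, list(f_noq$q_I, f_noq$q_aVL, f_lat_all,
                                         f_rw5, f_rw6)),
    aha2009_qV56I_norwpt = c(incl, list(f_noq$q_I, f_lat_all)),
    aha2009_qV56IaVL_norwpt = c(incl, list(f_noq$q_I, f_noq$q_aVL,
                                           f_lat_all)),
    proposed = c(incl, list(f_lat_ge2))
  )
  for (ld in c("I", "aVL", "V1", "V2", "V5", "V6", "II", "III", "aVF")) {
    cc <- paste0("notch_", ld)
    fl[[cc]] <- list(local({
      col <- cc
      fac(col, function(ch) ch[[col]])
    }))
  }
  fl
})

# static base-feature dependencies per predicate (union over factors)
PRED_REQUIRES <- lapply(PRED_FACTORS, function(fl)
  unique(unlist(lapply(fl, `[[`, "req"))))

# dependencies that still matter on a filtered archetype space: factors
# forced true for every admissible archetype do not couple anything
effective_requires <- function(pred_names, cand) {
  lapply(PRED_FACTORS[pred_names], function(fl) {
    unique(unlist(lapply(fl, function(fc)
      if (all(fc$fn(cand))) character(0) else fc$req)))
  })
}

# representative in-range durations per QRSD bin (determinism of fixtures)
QRSD_BIN_VALUES <- c(`110` = 110, `125` = 125, `135` = 135, `150` = 150)

matrixStats_colMax <- function(m) {
  if (nrow(m) == 0) rep(0L, ncol(m)) else apply(m, 2, max)
}

# enumerate the archetype space: all combinations of the base features the
# constrained predicates depend on; inactive features take fixed defaults
candidate_space <- function(cs) {
  preds <- c("sex_male", cs$constraints$predicate)
  active <- unique(unlist(PRED_REQUIRES[preds]))
  dims <- list()
  dims$sex <- c("M", "F")                       # sex always constrained
  dims$qrsd <- if ("qrsd" %in% active) c(110, 125, 135, 150) else 148
  dims$v1 <- if ("v1" %in% active) c("rS", "other") else "rS"
  for (f in c("q_I", "q_aVL", "q_V5", "q_V6", "rwpt_v5", "rwpt_v6",
              paste0("notch_", c("I", "aVL", "V1", "V2", "V5", "V6",
                                 "II", "III", "aVF"))))
    dims[[f]] <- if (f %in% active) c(FALSE, TRUE) else FALSE
  grid <- do.call(expand.grid,
                  c(dims, list(KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)))
  cand <- tibble(
    patient_id = paste0("c", seq_len(nrow(grid))),
    sex = grid$sex,
    qrsd_ms = grid$qrsd,
    frontal_axis_deg = NA_real_,
    pr_ms = NA_real_,
    v1_morphology = grid$v1,
    notch_I = grid$notch_I, notch_aVL = grid$notch_aVL,
    notch_V1 = grid$notch_V1, notch_V2 = grid$notch_V2,
    notch_V5 = grid$notch_V5, notch_V6 = grid$notch_V6,
    notch_II = grid$notch_II, notch_III = grid$notch_III,
    notch_aVF = grid$notch_aVF,
    q_I = grid$q_I, q_aVL = grid$q_aVL, q_V5 = grid$q_V5, q_V6 = grid$q_V6,
    rwpt_gt60_v5 = grid$rwpt_v5, rwpt_gt60_v6 = grid$rwpt_v6,
    rwpt_lead1_ms = NA_real_
  )
  S <- predicate_matrix(cand, preds)
  # collapse archetypes indistinguishable to every constrained predicate;
  # the first (lexicographically smallest, fewest-features) combo represents
  key <- apply(S, 1, paste, collapse = "")
  keep <- !duplicated(key)
  list(cand = cand[keep, ], S = S[keep, , drop = FALSE], preds = preds)
}

# logical relations among constrained predicates, derived from the archetype
# truth table: equalities, implications, and conjunction triples
predicate_relations <- function(S) {
  k <- ncol(S)
  key <- function(v) paste(as.integer(v), collapse = "")
  col_keys <- apply(S, 2, key)
  imp <- list(); conj <- list(); disj <- list(); cover <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && all(S[, i] <= S[, j]))
      imp[[length(imp) + 1]] <- c(i, j)
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    both <- S[, i] & S[, j]
    if (!any(both)) disj[[length(disj) + 1]] <- c(i, j)
    if (all(S[, i] | S[, j])) cover[[length(cover) + 1]] <- c(i, j)
  }
  if (k >= 3) {
    lookup <- setNames(seq_len(k), col_keys)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      m <- lookup[key(S[, i] & S[, j])]
      if (!is.na(m) && m != i && m != j)
        conj[[length(conj) + 1]] <- c(i, j, unname(m))
    }
  }
  list(imp = imp, conj = conj, disj = disj, cover = cover,
       col_keys = col_keys)
}

#' Frechet feasibility pre-check for a constraint set
#'
#' Runs the necessary-condition checks on a constraint set before any search:
#' counts within `[0, n]`, equal counts for logically equivalent predicates,
#' monotonicity for implied predicates (if A implies B then `|A| <= |B|`),
#' and the Frechet bounds `max(0, |A|+|B|-n) <= |A & B| <= min(|A|, |B|)`
#' for every constrained conjunction. Logical relations are derived
#' automatically from the predicate definitions (by enumerating the feature
#' archetype space), so definition-level constraints are checked against
#' their component feature counts. Passing is necessary, not sufficient, for
#' a satisfying cohort to exist.
#'
#' @param cs An [lbbb_constraints()] object.
#' @return A tibble of checks (`check`, `detail`, `pass`) with attribute
#'   `feasible` (`TRUE` if no check failed); class `lbbb_feasibility`.
#' @examples
#' cs <- lbbb_constraints("toy", n = 10, sex = c(M = 5, F = 5),
#'   constraints = c(rwpt_gt60_v5 = 8, rwpt_gt60_v6 = 7, rwpt_gt60_v56 = 4))
#' frechet_feasibility(cs)   # violates the lower Frechet bound (5)
#' @export
frechet_feasibility <- function(cs) {
  stopifnot(inherits(cs, "lbbb_constraints"))
  space <- candidate_space(cs)
  S <- space$S
  preds <- space$preds
  counts <- c(cs$sex[["M"]], cs$constraints$count)
  n <- cs$n
  rel <- predicate_relations(S)
  rows <- list()
  add <- function(check, detail, pass)
    rows[[length(rows) + 1]] <<- tibble(check = check, detail = detail,
                                        pass = pass)
  for (i in seq_along(preds))
    add("range", paste0(preds[i], " = ", counts[i], " in [0, ", n, "]"),
        counts[i] >= 0 && counts[i] <= n)
  dup <- split(seq_along(preds), rel$col_keys)
  for (grp in dup) {
    if (length(grp) > 1) {
      ok <- length(unique(counts[grp])) == 1
      add("equivalence",
          paste0(paste(preds[grp], collapse = " == "), ": counts ",
                 paste(counts[grp], collapse = ", ")), ok)
    }
  }
  for (p in rel$imp) {
    i <- p[1]; j <- p[2]
    if (counts[i] > counts[j])
      add("implication",
          paste0(preds[i], " (", counts[i], ") implies ", preds[j], " (",
                 counts[j], "): requires ", counts[i], " <= ", counts[j]),
          FALSE)
  }
  for (tr in rel$conj) {
    i <- tr[1]; j <- tr[2]; m <- tr[3]
    lo <- max(0, counts[i] + counts[j] - n)
    hi <- min(counts[i], counts[j])
    ok <- counts[m] >= lo && counts[m] <= hi
    add("frechet",
        paste0(preds[m], " = ", preds[i], " & ", preds[j], ": ", counts[m],
               " in [", lo, ", ", hi, "]"), ok)
  }
  out <- bind_rows(rows)
  structure(out, feasible = all(out$pass), class = c("lbbb_feasibility",
                                                     class(out)))
}

#' @export
print.lbbb_feasibility <- function(x, ...) {
  cat("<lbbb_feasibility> ",
      if (attr(x, "feasible")) "feasible-so-far" else "INFEASIBLE",
      " (", sum(!x$pass), " violated / ", nrow(x), " checks)\n", sep = "")
  bad <- x[!x$pass, ]
  if (nrow(bad) > 0) print(as_tibble(bad), n = Inf)
  invisible(x)
}

#' Reconstruct a patient-level cohort from count constraints
#'
#' Materializes a cohort of `cs$n` patients whose coded features satisfy
#' every count constraint exactly. Patients are assigned one at a time from
#' the deduplicated archetype space by a depth-first search: at each step the
#' archetype best matching the remaining per-constraint quotas is tried
#' first, infeasible branches are pruned via implication and Frechet bounds,
#' and ties are broken in a seed-determined order. Numeric features are
#' instantiated at fixed representative values per threshold bin (e.g. a
#' QRS duration of 135 ms for the `[130, 140)` bin), the frontal axis is
#' left unset unless constrained, and features no constrained predicate
#' depends on take fixed defaults (flags `FALSE`, morphology `rS`), so the
#' result is byte-stable across runs.
#'
#' @param cs An [lbbb_constraints()] object.
#' @param seed Integer; controls tie-breaking order only.
#' @param max_nodes Search-effort cap before reporting infeasibility.
#' @return A cohort tibble with `cs$n` rows; attribute `constraints` carries
#'   `cs`. Raises an error when the pre-check fails or the search exhausts.
#' @examples
#' cs <- cohort_constraints("table2_avi", features_only = TRUE)
#' cohort <- reconstruct_cohort(cs, seed = 1)
#' verify_constraints(cohort, cs)
#' @export
reconstruct_cohort <- function(cs, seed = 0, max_nodes = 500000) {
  stopifnot(inherits(cs, "lbbb_constraints"))
  feas <- frechet_feasibility(cs)
  if (!attr(feas, "feasible")) {
    bad <- feas[!feas$pass, ]
    abort(paste0("infeasible constraint set '", cs$label, "': ",
                 paste(paste0("[", bad$check, "] ", bad$detail),
                       collapse = "; ")))
  }
  space <- candidate_space(cs)
  S0 <- space$S
  preds <- space$preds
  counts <- c(cs$sex[["M"]], cs$constraints$count)
  # merge logically equivalent constraints (equal counts guaranteed above)
  rel0 <- predicate_relations(S0)
  keep_cols <- !duplicated(rel0$col_keys)
  S <- S0[, keep_cols, drop = FALSE]
  counts <- counts[keep_cols]
  # constraints at exactly n (or 0) are satisfied by every patient (or
  # none): archetypes disagreeing with them can never be used, so drop them
  # up front — this typically collapses the space by an order of magnitude
  usable <- rep(TRUE, nrow(S))
  for (j in seq_along(counts)) {
    if (counts[j] == cs$n) usable <- usable & S[, j]
    if (counts[j] == 0) usable <- usable & !S[, j]
  }
  if (!any(usable))
    abort(paste0("infeasible constraint set '", cs$label,
                 "': the always/never constraints admit no patient archetype"))
  S <- S[usable, , drop = FALSE]
  cand <- space$cand[usable, ]
  preds1 <- preds[keep_cols]

  # on the filtered space further constraints can coincide (e.g. a
  # definition reduces to its one non-forced component); merging them keeps
  # the constraint graph sparse and is a feasibility requirement in itself
  key2 <- apply(S, 2, paste, collapse = "")
  for (grp in split(seq_along(counts), key2)) {
    if (length(unique(counts[grp])) > 1)
      abort(paste0("infeasible constraint set '", cs$label, "': ",
                   paste(preds1[grp], collapse = ", "),
                   " are equivalent for every admissible patient but have ",
                   "unequal counts (", paste(counts[grp], collapse = ", "),
                   ")"))
  }
  keepc <- !duplicated(key2)
  S <- S[, keepc, drop = FALSE]
  counts <- counts[keepc]
  preds1 <- preds1[keepc]

  # constraints forced by the filtering (count n or 0) now hold for every
  # archetype; only the strictly interior ones still need placing
  interior <- counts > 0 & counts < cs$n
  S <- S[, interior, drop = FALSE]
  counts <- counts[interior]
  preds1 <- preds1[interior]

  finalize <- function(cohort) {
    cohort$patient_id <- sprintf("%s_%03d", cs$label, seq_len(cs$n))
    cohort <- as_tibble(cohort)
    attr(cohort, "constraints") <- cs
    cohort
  }

  # solve for a given grouping of the interior constraints: each component
  # is solved on its own (usually small) archetype-class space; patients
  # take each component's features from that component's solution and
  # defaults (the first admissible archetype) elsewhere, which is exact
  # when no constraint spans two components
  solve_grouped <- function(comp) {
    cohort <- cand[rep(1L, cs$n), ]
    for (ci in seq_along(comp)) {
      cols <- comp[[ci]]$idx
      key <- apply(S[, cols, drop = FALSE], 1, paste, collapse = "")
      class_rows <- which(!duplicated(key))      # representative archetypes
      Sc <- matrix(as.integer(S[class_rows, cols, drop = FALSE]),
                   length(class_rows), length(cols))
      blocks <- dfs_counts(Sc, counts[cols], cs$n, seed + 131 * ci,
                           max_nodes)
      if (is.null(blocks))
        abort(paste0("infeasible constraint set '", cs$label,
                     "': no patient-level assignment satisfies the joint ",
                     "counts (", paste0(preds1[cols], " = ", counts[cols],
                                        collapse = ", "), ")"))
      cls <- unlist(lapply(blocks, function(bm) rep(bm[1], bm[2])))
      rid <- class_rows[cls]                     # per-patient archetype row
      for (col in feature_columns(comp[[ci]]$features))
        cohort[[col]] <- cand[[col]][rid]
    }
    finalize(cohort)
  }

  if (length(counts) == 0) return(reconstruction_checked(finalize(cand[rep(1L, cs$n), ]), cs))
  cohort <- solve_grouped(constraint_components(preds1, cand))
  ver <- verify_constraints(cohort, cs)
  if (!attr(ver, "all_match")) {
    # rare: a forced (always/never) constraint straddles components through
    # a counting threshold; re-solve with all constraints as one component
    cohort <- solve_grouped(list(list(
      idx = seq_along(counts),
      features = unique(unlist(PRED_REQUIRES[preds1])))))
  }
  reconstruction_checked(cohort, cs)
}

# internal self-check: a returned reconstruction must satisfy its own
# constraint set exactly (guards the composition step)
reconstruction_checked <- function(cohort, cs) {
  ver <- verify_constraints(cohort, cs)
  if (!attr(ver, "all_match")) {
    bad <- ver[!ver$match, ]
    abort(paste0("internal error: reconstruction of '", cs$label,
                 "' misses constraint(s): ",
                 paste0(bad$predicate, " (", bad$observed, " != ",
                        bad$expected, ")", collapse = ", ")))
  }
  cohort
}

# group constraints into connected components over shared base features
# (effective dependencies when the admissible archetype table is supplied)
constraint_components <- function(pred_names, cand = NULL) {
  feats <- if (is.null(cand)) PRED_REQUIRES[pred_names] else
    effective_requires(pred_names, cand)
  comp_id <- seq_along(pred_names)
  repeat {
    changed <- FALSE
    for (i in seq_along(pred_names)) for (j in seq_along(pred_names)) {
      if (comp_id[i] != comp_id[j] &&
          length(intersect(feats[[i]], feats[[j]])) > 0) {
        comp_id[comp_id == max(comp_id[i], comp_id[j])] <-
          min(comp_id[i], comp_id[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp_id), function(id) {
    idx <- which(comp_id == id)
    list(idx = idx, features = unique(unlist(feats[idx])))
  })
}

# cohort columns holding a set of base features
feature_columns <- function(features) {
  map <- c(sex = "sex", qrsd = "qrsd_ms", v1 = "v1_morphology",
           rwpt_v5 = "rwpt_gt60_v5", rwpt_v6 = "rwpt_gt60_v6")
  vapply(features, function(f) if (f %in% names(map)) map[[f]] else f,
         character(1))
}

# depth-first search over archetype multiplicities for one component:
# find blocks (archetype, multiplicity) summing to n with column sums
# exactly `counts`; candidate order by proportional-quota score with
# seed-derived tie-breaking, largest feasible block first. The greedy
# descent is sensitive to tie order, so the search restarts with freshly
# drawn tie-break priorities (deterministic in the seed) whenever one
# ordering exhausts its node budget
dfs_counts <- function(Si, counts, n, seed, max_nodes, restarts = 40) {
  u <- nrow(Si); k <- ncol(Si)
  rel <- predicate_relations(matrix(as.logical(Si), u, k))
  budget <- max(20000, ceiling(max_nodes / restarts))
  for (attempt in seq_len(restarts)) {
    priority <- with_seed(seed + 7919 * (attempt - 1), runif(u))
    res <- dfs_counts_once(Si, counts, n, priority, budget, rel)
    if (!is.null(res$blocks)) return(res$blocks)
    if (!res$exhausted) return(NULL)  # complete search: truly infeasible
  }
  abort(paste0("reconstruction search exhausted (", restarts,
               " restarts x ", budget,
               " nodes); no satisfying assignment found within budget"))
}

# one search run: at each node the best-scoring usable archetype is chosen
# and its total multiplicity branched from the largest feasible block down
# to zero, after which that archetype is excluded from the subtree — each
# archetype is decided exactly once per branch, so no assignment is ever
# revisited as a reordered split
dfs_counts_once <- function(Si, counts, n, priority, max_nodes, rel) {
  u <- nrow(Si); k <- ncol(Si)
  nodes <- 0L
  exhausted <- FALSE
  state_ok <- function(t, r) {
    if (any(t < 0) || any(t > r)) return(FALSE)
    for (p in rel$imp) if (t[p[1]] > t[p[2]]) return(FALSE)
    for (p in rel$disj) if (t[p[1]] + t[p[2]] > r) return(FALSE)
    for (p in rel$cover) if (t[p[1]] + t[p[2]] < r) return(FALSE)
    for (tr in rel$conj)
      if (t[tr[1]] + t[tr[2]] - r > t[tr[3]]) return(FALSE)
    TRUE
  }
  pick <- function(t, r, avail) {
    idx <- which(avail & rowSums(Si > matrix(t, u, k, byrow = TRUE)) == 0)
    if (length(idx) == 0) return(0L)
    f <- t / r
    St <- Si[idx, , drop = FALSE]
    sc <- rowSums((St - matrix(f, length(idx), k, byrow = TRUE))^2)
    idx[order(sc, priority[idx])][1]
  }
  search <- function(t, r, avail) {
    if (r == 0) return(if (all(t == 0)) list() else NULL)
    # every outstanding need must still be coverable by available archetypes
    St <- Si[avail, , drop = FALSE]
    if (any(t > 0 & matrixStats_colMax(St) == 0)) return(NULL)
    v <- pick(t, r, avail)
    if (v == 0L) return(NULL)
    s <- Si[v, ]
    avail2 <- avail; avail2[v] <- FALSE
    m_hi <- min(r, if (any(s == 1)) min(t[s == 1]) else r,
                if (any(s == 0)) min(r - t[s == 0]) else r)
    for (m in m_hi:0) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes) {
        exhausted <<- TRUE
        stop(structure(list(message = "node budget", call = NULL),
                       class = c("lbbb_dfs_exhausted", "error",
                                 "condition")))
      }
      t2 <- t - m * s
      if (!state_ok(t2, r - m)) next
      res <- search(t2, r - m, avail2)
      if (!is.null(res))
        return(if (m > 0) c(list(c(v, m)), res) else res)
    }
    NULL
  }
  blocks <- tryCatch(search(counts, n, rep(TRUE, u)),
                     lbbb_dfs_exhausted = function(e) NULL)
  list(blocks = blocks, exhausted = exhausted)
}

#' Verify a cohort against a constraint set
#'
#' Recomputes every constrained count from the cohort (via the same predicate
#' registry the reconstructor used, but on the realized patient table) and
#' reports expected versus observed per constraint, plus the sex split.
#'
#' @param cohort A cohort tibble.
#' @param cs An [lbbb_constraints()] object.
#' @return A tibble (`predicate`, `expected`, `observed`, `match`) with
#'   attribute `all_match`; class `lbbb_verification`.
#' @export
verify_constraints <- function(cohort, cs) {
  stopifnot(inherits(cs, "lbbb_constraints"))
  cohort <- as_tibble(cohort)
  preds <- c("sex_male", cs$constraints$predicate)
  expected <- c(cs$sex[["M"]], cs$constraints$count)
  observed <- vapply(preds, function(p) sum(eval_predicate(cohort, p)),
                     integer(1))
  out <- tibble(predicate = preds, expected = as.integer(expected),
                observed = as.integer(observed),
                match = expected == observed)
  n_ok <- nrow(cohort) == cs$n
  structure(out, all_match = all(out$match) && n_ok, n_expected = cs$n,
            n_observed = nrow(cohort),
            class = c("lbbb_verification", class(out)))
}

#' @export
print.lbbb_verification <- function(x, ...) {
  cat("<lbbb_verification> ",
      if (attr(x, "all_match")) "all constraints match" else "MISMATCH",
      " (n ", attr(x, "n_observed"), "/", attr(x, "n_expected"), ")\n",
      sep = "")
  bad <- x[!x$match, ]
  if (nrow(bad) > 0) print(as_tibble(bad), n = Inf)
  invisible(x)
}
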