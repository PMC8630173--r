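---
title: "Scoring, reconstructing and simulating LBBB definition concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, reconstructing and simulating LBBB definition concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbbbr)
```

## The problem

Left bundle branch block (LBBB) has no single electrocardiographic
definition. The ESC 2013, Strauss and AHA 2009 rule sets all start from a
widened QRS with a QS/rS pattern in V1, but differ in the QRS-duration
threshold, the leads in which Q waves are forbidden, how many lateral leads
must show mid-QRS notching or slurring, and whether a prolonged R-wave peak
time (RWPT) is required. Because conduction block high in the left bundle
("proximal" LBBB) is the substrate that predicts response to cardiac
resynchronisation therapy, and aortic-valve-implantation (AVI)-induced LBBB
is proximal by mechanism, cohorts of AVI-induced LBBB give an anchor for
asking which definitional criteria actually identify proximal block.

`lbbbr` turns that analysis into reusable, testable components:

1. a tabular data model for coded ECG features (one row per patient);
2. rule engines for the four definitions plus the AHA variants;
3. a constraint-based reconstructor that materializes patient-level feature
   matrices exactly consistent with published cohort-level counts;
4. a synthetic cohort simulator with a latent proximal/distal class;
5. a concordance/statistics layer (exact and asymptotic 2×2 tests,
   Mann-Whitney U) producing two-cohort comparison reports.

## The data model

A cohort is a plain tibble. Notching and slurring are collapsed into one
boolean per lead because every scored criterion treats "notching/slurring"
as a single disjunctive feature; RWPT is coded as the `> 60 ms` threshold
flag per lead (V5, V6) that the criteria actually use, with an opaque
optional numeric for lead I kept only for descriptive parity (its published
unit is inconsistent, so no unit is asserted). The frontal axis is optional:
no scored definition requires it, and the proximal-LBBB proposal treats it
as ancillary only.

```{r}
cohort <- simulate_cohort(default_sim_params("avi", n = 6), seed = 1)
dplyr::glimpse(cohort[1:8])
```

## The rule engines

Each definition is a parameter object (`lbbb_definition`): a QRS-duration
rule (`fixed_120` or the sex-specific 130/140 ms Strauss rule), the V1
morphology requirement, a set of Q-forbidden leads, a notch lead set with a
minimum count (or "all"), and an RWPT switch. `evaluate_definition()`
reports every criterion separately and the verdict as their conjunction, so
a discordant patient can be traced to the failing criterion.

Operationalization choices where the published rule text is not fully
mechanizable from coded features:

* **ESC 2013** is scored as the broad inclusion criteria plus
  notching/slurring in at least one lateral lead, without an RWPT term. This
  reading is pinned by the published counts: in both cohorts the ESC row
  equals the "notching/slurring in V5-6, I or aVL" row exactly.
* **Strauss** is scored without the original mid-QRS notch-timing qualifier
  (notch flags carry no timing), and V2 morphology is not enforced (only V1
  is coded; the published feature table carries no V2 morphology row).
* **AHA 2009** requires notching/slurring in *all four* lateral leads,
  following the published reading of "broad notched or slurred R".
  ST/T-discordance wording in the full AHA text is never scored.
* **The proximal-LBBB proposal** takes QRSD ≥ 120 ms, QS/rS in V1, absent Q
  in V5/V6 only (a small q in I or aVL does not disqualify), and
  notching/slurring in ≥ 2 lateral leads. The leftward-axis criterion is
  ancillary by design; we default its threshold to +30°, reading "axis ≤
  30°" literally as a signed threshold, and keep it configurable because a
  hard cut-off is explicitly discouraged. It never enters the verdict.

Percentages are rounded half away from zero, the convention that reproduces
every printed table percentage (e.g. 10/59 → 17, 95/118 → 81).

## Cohort reconstruction from printed counts

Patient-level data are not deposited; what is printed are cohort-level
counts of feature predicates and definition verdicts. `reconstruct_cohort()`
treats those as exact count constraints and searches for a patient-level
boolean matrix satisfying all of them:

* patients are grouped into *archetypes* — distinct combinations of the base
  features any constrained predicate depends on;
* constraints forced at `n` or `0` prune the archetype space up front;
* the remaining constraints decompose into connected components over shared
  base features (dependencies are computed on the pruned space, so a
  definition whose QRSD factor is already forced does not couple the QRSD
  group to the notch group);
* each component is solved by a depth-first search over archetype
  multiplicities: the archetype best matching the remaining per-constraint
  quotas is chosen, its total multiplicity branched from the largest
  feasible block down to zero, and the archetype then excluded from the
  subtree, so no assignment is revisited as a reordered split;
* pruning uses bounds derived automatically from the archetype truth table:
  implications (`A ⇒ B` forces `t_A ≤ t_B`), Fréchet bounds for constrained
  conjunctions, and disjointness/covering cuts (`t_A + t_B ≤ r`,
  `t_A + t_B ≥ r`);
* the seed only permutes tie-breaking among equally attractive archetypes;
  a restart schedule (fresh tie-break priorities, deterministic in the
  seed) guards against unlucky orderings.

Numeric fields are instantiated at fixed representative values per
threshold bin (125/135/150 ms; 110 ms only when sub-120 ms patients are
admissible), the axis is left unset unless constrained, and unconstrained
flags take fixed defaults — so a reconstruction is byte-stable for a given
(constraint set, seed), and `verify_constraints()` independently re-counts
every predicate on the result. `frechet_feasibility()` runs the necessary
conditions up front and reports violated bounds as data.

Two points about what reconstruction does and does not claim:

* The matrix is *a* witness, not *the* cohort: only threshold-consistent
  values are reconstructed (no medians/IQRs), and no uniqueness is claimed.
* When the feature marginals logically force a definition count, the forced
  value emerges without the definition row being in the constraint set.
  That is the non-circular check used throughout the tests: reconstruct
  from feature rows only, then ask the engines.

The shipped fixtures transcribe the published cohort columns: `table2_avi`
(n = 59), `table2_control` (n = 118), `table3_crt` (n = 33). The CRT
fixture omits the published Strauss definition row: the printed 32/33
exceeds the printed sex-specific QRSD count (31/33) that the Strauss rule
conjoins, so no patient-level matrix can satisfy both — the constraint set
documents this and `frechet_feasibility()` rejects it if added back. The
published abstract also reports the AVI AHA concordance as 18% where the
tables give 10/59 = 17%; the engines follow the tables. One printed
percentage (28/59 shown as 48%) conflicts with its own count (47.46% under
every rounding that reproduces the other rows); the count is treated as the
substance.

```{r}
cs <- cohort_constraints("table2_avi", features_only = TRUE)
avi <- reconstruct_cohort(cs, seed = 1)
glance(classify_cohort(avi))
```

## The simulator

`simulate_cohort()` draws a latent binary class per patient — proximal
block with probability `proximal_fraction`, distal otherwise — and the
class drives the correlation among lateral notch flags: within-class
per-lead probabilities are derived from the marginal prevalences (so each
flag's marginal prevalence equals its parameter exactly), with distal
patients carrying no lateral notching. This single latent dichotomy is the
only dependence mechanism the underlying biology suggests: proximal block
produces the notched lateral activation pattern; an LBBB pattern without
notching most likely reflects distal block. Two nestings mirror observed
structure: RWPT > 60 ms in V5 occurs only with V6, and a lead-I Q wave only
with an aVL Q wave. Everything else is independent given the class.

Preset parameters (`default_sim_params()`) come from the published tables:

* AVI: male QRSD 154 ms, female 145 ms, common sd 12 ms (≈ IQR/1.35 pooled
  across the sex-specific IQRs), truncated at 120 ms (the inclusion
  threshold — sub-120 ms QRS is deliberately not modelled); axis −15°,
  sd 48/1.35°; per-lead lateral notch probabilities chosen so the implied
  combination rates match the printed ones (V5 = V6 = 1, I = aVL = √0.54 so
  that all-four = 54% and any-lateral = 100%); 42% male.
* control: proximal fraction 0.85 (the printed 85% lateral-notching rate),
  within-class per-lead rates fitted to the printed all-four rate (31%);
  QRSD 150/141 ms (the printed overall median with the AVI sex shift
  carried over, since sex-specific control medians are unpublished).
* CRT: all-four rate 76%, QRSD 164/155 ms, 52% male; the RWPT marginal is
  set so the implied ratio of RWPT-positive to RWPT-free AHA concordance
  echoes the printed 33%/70% pair.

Within-class per-lead notch probabilities are unpublished; the values above
are free parameters of the generator, fixed once from the printed
combination counts and documented here. Printed medians/IQRs map to Normal
parameters via sd ≈ IQR/1.35. What passing simulator tests show is
therefore calibration *to this generative model*, not to real ECGs: real
notch detection noise, inter-reader disagreement, axis/QRSD correlation and
repolarisation features are all outside the model.

One consequence is worth stating precisely. The QRSD truncation at 120 ms
raises the female mean by ≈ 0.56 ms but the male mean by only ≈ 0.09 ms (the
female distribution has more mass below 120), so the estimand of the OLS
male–female contrast in `recover_sex_effect()` is ≈ 8.5 ms, not the nominal
9 ms parameter gap. With n = 2000 (SE ≈ 0.55 ms) the 95% CI covers the
nominal 9 ms in only ~83% of replicates, and the joint event "every
non-degenerate feature prevalence inside its central 99% binomial interval
(~13 intervals) *and* CI covers 9 ms" occurs in ~74% of replicates — close
to the 0.99^13 × 0.83 product expected under independence. The recovery
test in the test suite records this behaviour as measured; a joint pass
rate above 95% is not achievable under this generative model, and the
parameters were fixed from the printed tables rather than adjusted to the
test.

## Statistics

`fisher_exact()` computes the two-sided p-value by full hypergeometric
enumeration with the point-probability (minimum-likelihood) rule — the
convention matters in the third decimal compared with doubling the
one-sided tail, so it is stated: all tables with the observed margins whose
point probability does not exceed the observed table's (within a 1e-7
relative tolerance for floating-point ties) contribute. `chi_square()` is
the closed-form 2×2 statistic with optional Yates correction.
`mann_whitney()` uses midranks; for combined sizes ≤ 12 the p-value is an
exact enumeration over all group assignments, beyond that a tie-corrected
Normal approximation without continuity correction.

`compare_cohorts()` mirrors the published table layout: one row per feature
predicate and definition with counts, percentages and a test. The published
analysis does not state which test produced which row, so a selection rule
had to be chosen: Fisher when any expected cell is below 5, chi-square
otherwise, with the chosen test reported per row so either can be forced.
Rows where the criterion holds for every patient of both cohorts are marked
`NP` (not possible), as in print. No multiplicity correction is applied,
mirroring the source analysis. `check_printed_pvalues()` audits every
printed categorical p-value against both candidate tests at the printed
rounding: 24 of 26 rows are consistent with at least one candidate; the two
CRT QRSD-threshold rows are not reproducible from their printed counts
under either test and are listed as failures rather than asserted away.

## Numerical and degenerate-input conventions

* Percentages: integer display rounds half away from zero; a 4-decimal
  companion is always carried.
* `fisher_exact` requires both row totals positive; a zero `bc`
  cross-product reports an infinite odds ratio (NaN when `ad` is also 0).
* `chi_square` requires all margins positive.
* `mann_whitney` with zero variance (all values tied) reports p = 1.
* Reconstruction search effort is capped (`max_nodes`); exhaustion is
  reported as an error naming the constraint component, distinct from a
  proven infeasibility, which names the violated bound or the equivalent
  predicates with unequal counts.
* Axis values are clipped to [−180, 180) in simulation; cohort validation
  rejects values outside that range.

## Problem sizes used by the tests

The test suite reconstructs all three cohorts (n = 33–118), sweeps every
2×2 table with total ≤ 40 against the enumeration oracle, checks the
implication chain on 10⁵ random feature vectors, and runs 100 simulator
replicates at n = 2000. These sizes make every check exact or tightly
calibrated at desk scale; nothing downstream depends on larger runs.

## Known limitations

* Waveform-level analysis (notch detection, RWPT measurement) is out of
  scope: features arrive coded.
* Reconstructed cohorts are witnesses for the printed counts, not estimates
  of the real joint distribution; quantities the constraints do not pin
  down (e.g. the proposed definition's concordance on control patients) can
  vary across admissible matrices.
* The simulator's latent-class model is deliberately minimal; it is a test
  harness for the engines and statistics, not a generative model of
  clinical ECG populations.
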