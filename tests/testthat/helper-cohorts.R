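# build a one-row patient tibble with sensible LBBB-ish defaults; override
# any field by name
make_patient <- function(patient_id = "P1", sex = "M", qrsd_ms = 148,
                         frontal_axis_deg = -15, pr_ms = 190,
                         v1_morphology = "rS",
                         notch = c("V5", "V6"), q = character(),
                         rwpt_gt60_v5 = FALSE, rwpt_gt60_v6 = FALSE,
                         rwpt_lead1_ms = NA_real_) {
  p <- tibble::tibble(
    patient_id = patient_id, sex = sex, qrsd_ms = qrsd_ms,
    frontal_axis_deg = frontal_axis_deg, pr_ms = pr_ms,
    v1_morphology = v1_morphology,
    notch_I = "I" %in% notch, notch_aVL = "aVL" %in% notch,
    notch_V1 = "V1" %in% notch, notch_V2 = "V2" %in% notch,
    notch_V5 = "V5" %in% notch, notch_V6 = "V6" %in% notch,
    notch_II = "II" %in% notch, notch_III = "III" %in% notch,
    notch_aVF = "aVF" %in% notch,
    q_I = "I" %in% q, q_aVL = "aVL" %in% q,
    q_V5 = "V5" %in% q, q_V6 = "V6" %in% q,
    rwpt_gt60_v5 = rwpt_gt60_v5, rwpt_gt60_v6 = rwpt_gt60_v6,
    rwpt_lead1_ms = rwpt_lead1_ms
  )
  p
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$patient_id <- make.unique(out$patient_id)
  out
}

# a random valid feature vector (one-row cohort); used by property tests
random_patient <- function(id) {
  make_patient(
    patient_id = id,
    sex = sample(c("M", "F"), 1),
    qrsd_ms = sample(c(118, 125, 132, 138, 145, 160), 1),
    v1_morphology = sample(c("QS", "rS", "other"), 1),
    notch = sample(c("I", "aVL", "V1", "V2", "V5", "V6", "II", "III", "aVF"),
                   sample(0:9, 1)),
    q = sample(c("I", "aVL", "V5", "V6"), sample(0:4, 1)),
    rwpt_gt60_v5 = runif(1) < 0.4, rwpt_gt60_v6 = runif(1) < 0.6
  )
}

random_cohort <- function(n, seed = 1) {
  withr::with_seed(seed,
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      random_patient(paste0("R", i)))))
}
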