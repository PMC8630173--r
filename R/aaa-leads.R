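#' Standard 12-lead identifiers and anatomical lead sets
#'
#' The twelve conventional surface ECG leads, plus the anatomical groupings the
#' LBBB definitions refer to: lateral (I, aVL, V5, V6), inferior (II, III,
#' aVF) and septal (V1, V2).
#'
#' @format Character vectors of lead identifiers.
#' @name lead_sets
NULL

#' @rdname lead_sets
#' @export
LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname lead_sets
#' @export
LEADS_LATERAL <- c("I", "aVL", "V5", "V6")

#' @rdname lead_sets
#' @export
LEADS_INFERIOR <- c("II", "III", "aVF")

#' @rdname lead_sets
#' @export
LEADS_SEPTAL <- c("V1", "V2")

# leads whose notch/slur status a cohort table must carry
NOTCH_LEADS <- c("I", "aVL", "V1", "V2", "V5", "V6", "II", "III", "aVF")

# leads whose Q-wave status a cohort table must carry
Q_LEADS <- c("I", "aVL", "V5", "V6")

notch_col <- function(lead) paste0("notch_", lead)
q_col <- function(lead) paste0("q_", lead)
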