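#' Per-feature clinical counts for the ARID2-related-disorder cohorts
#'
#' Affected / responder counts per feature for the 27-individual new
#' series and the 26 previously published individuals. These counts are
#' the contract the packaged per-individual fixture reproduces; responders
#' below the cohort size reflect features with missing clinical data.
#'
#' @return Data frame `feature`, `aff_this`, `resp_this`, `aff_lit`,
#'   `resp_lit`.
#' @export
arid2_table1_counts <- function() {
  counts <- rbind(
    c("male_sex",                 13, 27, 17, 26),
    c("hypotonia",                18, 27, 14, 20),
    c("psychomotor_delay",        24, 24, 24, 25),
    c("speech_disorder",          22, 25, 13, 15),
    c("intellectual_disability",  14, 20, 22, 23),
    c("epilepsy",                  2, 26,  2, 24),
    c("brain_mri_anomalies",      11, 18,  8, 13),
    c("behavioral_problems",      16, 25, 15, 23),
    c("autism_spectrum_disorder",  0, 25,  2, 23),
    c("adhd",                     10, 25,  7, 23),
    c("low_frustration_tolerance", 5, 25,  3, 23),
    c("aggressive_behavior",       3, 25,  3, 23),
    c("anxiety_disorder",          3, 25,  4, 23),
    c("feeding_difficulties",     12, 19,  8, 26),
    c("facial_features",          27, 27, 25, 26),
    c("coarse_face",              12, 19, 15, 21),
    c("ptosis",                    2, 23,  3, 23),
    c("myopia",                    4, 23,  6, 18),
    c("hyperopia",                 6, 23,  3, 17),
    c("strabismus",                5, 23,  7, 18),
    c("astigmatism",               2, 23,  1, 17),
    c("deafness",                  2, 20,  3, 12),
    c("dental_anomalies",         19, 26,  6, 25),
    c("hair_anomalies",           12, 24, 10, 20),
    c("nail_anomalies",           16, 26,  8, 21),
    c("bone_anomalies",            3, 16,  6, 19),
    c("hand_feet_anomalies",      11, 25, 15, 26),
    c("short_stature",             4, 27, 15, 25),
    c("cardiologic_features",      3, 15,  4, 15),
    c("de_novo_variant",          21, 27, NA, NA))
  out <- data.frame(feature = counts[, 1L],
                    aff_this = as.integer(counts[, 2L]),
                    resp_this = as.integer(counts[, 3L]),
                    aff_lit = as.integer(counts[, 4L]),
                    resp_lit = as.integer(counts[, 5L]),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$aff_this <= out$resp_this, na.rm = TRUE),
            all(out$aff_lit <= out$resp_lit, na.rm = TRUE))
  out
}

.assign_states <- function(n_ind, aff, resp) {
  if (is.na(aff)) return(rep("unknown", n_ind))
  c(rep("present", aff), rep("absent", resp - aff),
    rep("unknown", n_ind - resp))
}

#' Packaged per-individual phenotype fixture
#'
#' Builds a per-individual phenotype table whose series-level counts match
#' [arid2_table1_counts()] exactly. Within each series, states are
#' assigned deterministically in individual order (present first, then
#' absent, then unknown): the joint phenotype of any single synthetic
#' individual is not meaningful -- the per-feature counts are the
#' contract.
#'
#' @return Validated phenotype table: 27 `this_series` + 26 `literature`
#'   individuals.
#' @export
arid2_phenotype_fixture <- function() {
  counts <- arid2_table1_counts()
  n_this <- 27L; n_lit <- 26L
  this <- data.frame(individual_id = sprintf("P%02d", seq_len(n_this)),
                     series = "this_series", stringsAsFactors = FALSE)
  lit <- data.frame(individual_id = sprintf("L%02d", seq_len(n_lit)),
                    series = "literature", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(counts))) {
    f <- counts$feature[i]
    this[[f]] <- .assign_states(n_this, counts$aff_this[i],
                                counts$resp_this[i])
    lit[[f]] <- .assign_states(n_lit, counts$aff_lit[i], counts$resp_lit[i])
  }
  merge_series(this, lit)
}
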