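# Shared fixtures, all built in code.

base_params <- tdm_parameters()
std_lt <- synthetic_dutch_life_table()

flat_lt <- function(q, ages = 0:110) life_table(ages, rep(q, length(ages)))
immortal_lt <- flat_lt(0)

# parameters describing a single 28-day cycle with effectively no mortality
# or recurrence (survivor curves ~ 1 throughout)
one_cycle_params <- function(...) {
  tdm_parameters(
    horizon_age = 53 + 28 / 365.25,
    dfs_low_intercept = 20, bcmort_intercept = 20,
    ...
  )
}

# a deterministic serum cohort mirroring the published validation counts:
# 813 tested, 277 below threshold, 113 escalated of whom 75 reach target
published_validation_cohort <- function(threshold = 5.97) {
  occ1 <- tibble::tibble(
    patient_id = 1:813, occasion = 1L, dose_mg = 20,
    concentration_ng_ml = c(rep(threshold / 2, 277), rep(threshold * 2, 536))
  )
  occ2 <- tibble::tibble(
    patient_id = 1:113, occasion = 2L, dose_mg = 40,
    concentration_ng_ml = c(rep(threshold * 1.5, 75), rep(threshold / 2, 38))
  )
  dplyr::bind_rows(occ1, occ2)
}
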