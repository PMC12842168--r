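#' Reference clinical cohort summary
#'
#' Published summary counts of the clinical cohort the simulator scenarios
#' are calibrated to: recording counts per access type and dysfunction
#' group, and the male/total sex counts per group. These are the inputs
#' for the demographic balance checks ([compare_categorical()] on the sex
#' distribution) and for cohort bookkeeping.
#'
#' @return A list with `groups` (data frame: access type, group, n
#'   recordings, n male) and scalars `n_patients`, `n_recordings`.
#' @examples
#' ref <- reference_cohort()
#' sum(ref$groups$n[ref$groups$access_type == "AVF"])
#' @export
reference_cohort <- function() {
  groups <- data.frame(
    access_type = c("AVF", "AVF", "AVF", "AVG", "AVG"),
    group = c("normal", "arterial_dysfunction", "venous_dysfunction",
              "normal", "graft_dysfunction"),
    n = c(47L, 72L, 65L, 16L, 36L),
    n_male = c(25L, 46L, 40L, 9L, 17L),
    age_mean = c(66, 68, 66, 69, 71),
    age_sd = c(11, 12, 11, 8, 12),
    stenosis_mean = c(NA, 61, 68, NA, 65),
    stenosis_sd = c(NA, 12, 12, NA, 11),
    stringsAsFactors = FALSE
  )
  list(groups = groups, n_patients = 157L, n_recordings = 236L)
}
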