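ACCESS_TYPES <- c("AVF", "AVG")
SITES <- c("arterial_puncture", "venous_puncture", "anastomosis")
GROUPS <- c("normal", "arterial_dysfunction", "venous_dysfunction",
            "graft_dysfunction")
PHASES <- c("pre_PTA", "post_PTA", "none")
SEXES <- c("male", "female")

#' Recording metadata
#'
#' Acquisition metadata attached to each bruit recording: who, which access,
#' where on the access, the dysfunction group, and (for angioplasty
#' patients) the pre/post phase.
#'
#' Two structural rules are enforced: the anastomosis site only exists for
#' arteriovenous fistulas (grafts have no surgical artery-vein anastomosis
#' accessible to auscultation), and the arterial/venous dysfunction groups
#' apply to fistulas while graft dysfunction applies to grafts.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param access_type `"AVF"` or `"AVG"`.
#' @param site One of `"arterial_puncture"`, `"venous_puncture"`,
#'   `"anastomosis"`.
#' @param group One of `"normal"`, `"arterial_dysfunction"`,
#'   `"venous_dysfunction"`, `"graft_dysfunction"`.
#' @param phase One of `"pre_PTA"`, `"post_PTA"`, `"none"`.
#' @param stenosis_pct Angiographic stenosis percentage, or `NA`.
#' @param age Age in years, or `NA`.
#' @param sex `"male"`, `"female"`, or `NA`.
#' @return An object of class `recording_metadata`.
#' @examples
#' recording_metadata("P01", "AVF", "arterial_puncture", "normal")
#' @export
recording_metadata <- function(patient_id, access_type, site, group,
                               phase = "none", stenosis_pct = NA_real_,
                               age = NA_real_, sex = NA_character_) {
  md <- list(
    patient_id = as.character(patient_id),
    access_type = match.arg(access_type, ACCESS_TYPES),
    site = match.arg(site, SITES),
    group = match.arg(group, GROUPS),
    phase = match.arg(phase, PHASES),
    stenosis_pct = as.numeric(stenosis_pct),
    age = as.numeric(age),
    sex = if (is.na(sex)) NA_character_ else match.arg(sex, SEXES)
  )
  class(md) <- "recording_metadata"
  validate_recording_metadata(md)
}

validate_recording_metadata <- function(md) {
  if (md$site == "anastomosis" && md$access_type != "AVF") {
    stop("metadata_invalid: anastomosis site is only defined for AVF access",
         call. = FALSE)
  }
  if (md$group %in% c("arterial_dysfunction", "venous_dysfunction") &&
      md$access_type != "AVF") {
    stop("metadata_invalid: arterial/venous dysfunction groups apply to AVF only",
         call. = FALSE)
  }
  if (md$group == "graft_dysfunction" && md$access_type != "AVG") {
    stop("metadata_invalid: graft_dysfunction applies to AVG only",
         call. = FALSE)
  }
  if (!is.na(md$stenosis_pct) &&
      (md$stenosis_pct < 0 || md$stenosis_pct > 100)) {
    stop("metadata_invalid: stenosis_pct must be in [0, 100]", call. = FALSE)
  }
  md
}

#' @export
print.recording_metadata <- function(x, ...) {
  cat(sprintf("<recording_metadata> %s | %s %s | %s | %s\n",
              x$patient_id, x$access_type, x$site, x$group, x$phase))
  invisible(x)
}

metadata_as_row <- function(md) {
  data.frame(
    patient_id = md$patient_id, access_type = md$access_type,
    site = md$site, group = md$group, phase = md$phase,
    stenosis_pct = md$stenosis_pct, age = md$age,
    sex = if (is.na(md$sex)) NA_character_ else md$sex,
    stringsAsFactors = FALSE
  )
}

metadata_from_row <- function(row) {
  recording_metadata(
    patient_id = row$patient_id, access_type = row$access_type,
    site = row$site, group = row$group,
    phase = if (is.null(row$phase) || is.na(row$phase)) "none" else row$phase,
    stenosis_pct = if (is.null(row$stenosis_pct)) NA_real_ else row$stenosis_pct,
    age = if (is.null(row$age)) NA_real_ else row$age,
    sex = if (is.null(row$sex)) NA_character_ else row$sex
  )
}
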