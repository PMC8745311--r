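#' Lesion inventory for one eye
#'
#' Aggregated lesion evidence feeding the ICDR staging rules: counts per
#' lesion type, the number of quadrants containing hemorrhages, the
#' annotation flags for signs the pixel pipeline does not detect (venous
#' beading, IRMA, neovascularization), and the distance from the fovea to
#' the nearest bright lesion (in disc-diameter units) used for the macular
#' edema call.
#'
#' @param ma,hem,ex,cws non-negative lesion counts.
#' @param hemorrhage_quadrants,venous_beading_quadrants,irma_quadrants
#'   quadrant counts, 0–4.
#' @param neovascularization logical annotation flag.
#' @param bright_lesion_min_distance_to_fovea dd units, or `NA` if no bright
#'   lesion is present.
#' @return object of class `lesion_inventory`.
#' @export
lesion_inventory <- function(ma = 0L, hem = 0L, ex = 0L, cws = 0L,
                             hemorrhage_quadrants = 0L,
                             venous_beading_quadrants = 0L,
                             irma_quadrants = 0L,
                             neovascularization = FALSE,
                             bright_lesion_min_distance_to_fovea = NA_real_) {
  counts <- c(ma = ma, hem = hem, ex = ex, cws = cws)
  if (any(counts < 0)) stop("lesion counts must be non-negative")
  quads <- c(hemorrhage_quadrants, venous_beading_quadrants, irma_quadrants)
  if (any(quads < 0 | quads > 4)) stop("quadrant counts must lie in 0..4")
  if (!is.na(bright_lesion_min_distance_to_fovea) &&
      bright_lesion_min_distance_to_fovea < 0)
    stop("distances must be non-negative")
  structure(list(ma = as.integer(ma), hem = as.integer(hem),
                 ex = as.integer(ex), cws = as.integer(cws),
                 hemorrhage_quadrants = as.integer(hemorrhage_quadrants),
                 venous_beading_quadrants = as.integer(venous_beading_quadrants),
                 irma_quadrants = as.integer(irma_quadrants),
                 neovascularization = isTRUE(neovascularization),
                 bright_lesion_min_distance_to_fovea =
                   bright_lesion_min_distance_to_fovea),
            class = "lesion_inventory")
}

#' Image-level diagnosis
#'
#' A single capture is `DR` whenever lesions were found, regardless of image
#' quality; otherwise `UNG` if the quality gate failed, otherwise `NODR`.
#'
#' @param analysis an [analyze_image()] result.
#' @return `"DR"`, `"NODR"` or `"UNG"`.
#' @export
grade_image <- function(analysis) {
  stopifnot(inherits(analysis, "image_analysis"))
  if (length(analysis$lesions) > 0) "DR"
  else if (!isTRUE(analysis$quality$gradable)) "UNG"
  else "NODR"
}

#' ICDR severity stage from a lesion inventory
#'
#' Implements the International Clinical Diabetic Retinopathy severity
#' scale: proliferative (`PROL`) if neovascularization; severe
#' non-proliferative (`SEV`) under the 4-2-1 rule (hemorrhages in all four
#' quadrants, venous beading in two or more, or IRMA in one or more); mild
#' (`MILD`) if microaneurysms are the only finding; moderate (`MOD`) for any
#' other lesion evidence; `NODR` otherwise.
#'
#' @param inv a [lesion_inventory()].
#' @return stage string.
#' @export
stage_eye <- function(inv) {
  stopifnot(inherits(inv, "lesion_inventory"))
  if (inv$neovascularization) return("PROL")
  if (inv$hemorrhage_quadrants == 4L || inv$venous_beading_quadrants >= 2L ||
      inv$irma_quadrants >= 1L) return("SEV")
  others <- inv$hem + inv$ex + inv$cws + inv$venous_beading_quadrants
  if (inv$ma > 0L && others == 0L) return("MILD")
  if (inv$ma + others > 0L) return("MOD")
  "NODR"
}

#' Macular edema call
#'
#' Operationalised as a bright lesion (exudate or cotton-wool spot) within
#' one disc-diameter of the fovea.
#'
#' @param inv a [lesion_inventory()].
#' @param dme_dd distance threshold in disc-diameter units.
#' @return logical flag.
#' @export
detect_dme <- function(inv, dme_dd = default_params()$grading$dme_dd) {
  stopifnot(inherits(inv, "lesion_inventory"))
  d <- inv$bright_lesion_min_distance_to_fovea
  !is.na(d) && d <= dme_dd
}

# Merge per-capture lesion candidates for one eye: union of candidates,
# deduplicated by centroid distance in frame (dd) coordinates.
merge_captures <- function(analyses, dedup_dd = default_params()$merge$dedup_dd) {
  merged <- list()
  for (an in analyses) {
    for (cand in an$lesions) {
      dup <- FALSE
      for (m in merged) {
        d <- sqrt((cand$frame_x - m$frame_x)^2 + (cand$frame_y - m$frame_y)^2)
        if (d < dedup_dd) { dup <- TRUE; break }
      }
      if (!dup) merged[[length(merged) + 1]] <- cand
    }
  }
  merged
}

# Build a lesion inventory from merged lesion candidates.
candidates_inventory <- function(cands, venous_beading_quadrants = 0L,
                                 irma_quadrants = 0L,
                                 neovascularization = FALSE) {
  types <- vapply(cands, `[[`, "", "type")
  hem_q <- unique(vapply(cands[types == "HEM"], `[[`, 0L, "quadrant"))
  bright_r <- vapply(cands[types %in% c("EX", "CWS")], `[[`, 0, "polar_r")
  lesion_inventory(
    ma = sum(types == "MA"), hem = sum(types == "HEM"),
    ex = sum(types == "EX"), cws = sum(types == "CWS"),
    hemorrhage_quadrants = length(hem_q),
    venous_beading_quadrants = venous_beading_quadrants,
    irma_quadrants = irma_quadrants,
    neovascularization = neovascularization,
    bright_lesion_min_distance_to_fovea =
      if (length(bright_r)) min(bright_r) else NA_real_)
}

#' Eye-level grade from the captures of one eye
#'
#' Merges the lesion candidates of 1–3 captures (union, deduplicated by
#' centroid distance in disc-diameter coordinates), calls the eye gradable
#' if at least one capture passed the quality gate, and applies the
#' image-level rule at eye level: lesions give `DR` regardless of quality.
#'
#' @param analyses list of [analyze_image()] results for one eye.
#' @param eye `"OD"` or `"OS"`.
#' @param venous_beading_quadrants,irma_quadrants,neovascularization
#'   annotation flags merged into the eye's inventory.
#' @return object of class `eye_grade` with fields `eye`, `status`, `stage`,
#'   `dme`, `inventory`.
#' @export
grade_eye <- function(analyses, eye = "OD",
                      venous_beading_quadrants = 0L, irma_quadrants = 0L,
                      neovascularization = FALSE) {
  if (length(analyses) == 0) stop("grade_eye needs at least one analysis")
  merged <- merge_captures(analyses)
  inv <- candidates_inventory(merged, venous_beading_quadrants,
                              irma_quadrants, neovascularization)
  gradable <- any(vapply(analyses, function(a)
    isTRUE(a$quality$gradable), TRUE))
  stage <- stage_eye(inv)
  status <- if (stage != "NODR") "DR" else if (!gradable) "UNG" else "NODR"
  dme <- if (status == "UNG") FALSE else detect_dme(inv)
  structure(list(eye = eye, status = status,
                 stage = if (status == "UNG") "NODR" else stage,
                 dme = dme, gradable = gradable, inventory = inv),
            class = "eye_grade")
}

#' Build an eye grade directly from known facts
#'
#' Convenience constructor used when grading ground truth or external
#' annotations rather than pixel analyses.
#'
#' @param status `"DR"`, `"NODR"` or `"UNG"`.
#' @param stage ICDR stage (ignored, forced to `"NODR"`, when `status = "UNG"`).
#' @param dme macular edema flag.
#' @param eye `"OD"` or `"OS"`.
#' @return an `eye_grade`.
#' @export
eye_grade <- function(status, stage = "NODR", dme = FALSE, eye = "OD") {
  status <- match.arg(status, diag_levels())
  stage <- match.arg(stage, stage_levels())
  if (status == "DR" && stage == "NODR")
    stop("a DR eye needs a stage above NODR")
  if (status != "DR") stage <- "NODR"
  if (status == "UNG") dme <- FALSE
  structure(list(eye = eye, status = status, stage = stage, dme = isTRUE(dme),
                 gradable = status != "UNG", inventory = NULL),
            class = "eye_grade")
}

#' Patient-level diagnosis from two eye grades
#'
#' Applies the screening aggregation rules: any eye with lesions makes the
#' patient `DR` (lesions count regardless of quality, so `DR` takes
#' precedence over `UNG` by default — switchable); otherwise any ungradable
#' eye makes the patient `UNG`; otherwise `NODR`. The patient stage is the
#' worst (highest) stage over eyes, macular edema is present if either eye
#' has it, and sight-threatening DR (STDR) means macular edema or a stage of
#' severe or worse.
#'
#' @param od,os [eye_grade()]s (either may be `NULL` for single-eye patients).
#' @param ung_precedence `"dr_over_ung"` (default) or `"ung_over_dr"`.
#' @return object of class `patient_diagnosis` with `status`, `stage`,
#'   `dme`, `stdr`.
#' @export
aggregate_patient <- function(od, os = NULL,
                              ung_precedence = default_params()$grading$ung_precedence) {
  ung_precedence <- match.arg(ung_precedence, c("dr_over_ung", "ung_over_dr"))
  eyes <- Filter(Negate(is.null), list(od, os))
  if (length(eyes) == 0) stop("at least one eye grade is required")
  statuses <- vapply(eyes, `[[`, "", "status")
  any_dr <- any(statuses == "DR")
  any_ung <- any(statuses == "UNG")
  status <- if (ung_precedence == "dr_over_ung") {
    if (any_dr) "DR" else if (any_ung) "UNG" else "NODR"
  } else {
    if (any_ung) "UNG" else if (any_dr) "DR" else "NODR"
  }
  stage <- "NODR"; dme <- FALSE
  if (status == "DR") {
    dr_eyes <- eyes[statuses == "DR"]
    stage <- stage_levels()[max(vapply(dr_eyes, function(e)
      stage_rank(e$stage), 0L))]
    dme <- any(vapply(eyes, `[[`, TRUE, "dme"))
  }
  structure(list(status = status, stage = stage, dme = dme,
                 stdr = dme || stage %in% c("SEV", "PROL"),
                 single_eye = length(eyes) == 1L),
            class = "patient_diagnosis")
}

#' @export
print.patient_diagnosis <- function(x, ...) {
  cat(sprintf("<patient_diagnosis> %s stage=%s dme=%s stdr=%s\n",
              x$status, x$stage, x$dme, x$stdr))
  invisible(x)
}

#' @export
print.eye_grade <- function(x, ...) {
  cat(sprintf("<eye_grade> %s %s stage=%s dme=%s\n",
              x$eye, x$status, x$stage, x$dme))
  invisible(x)
}
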