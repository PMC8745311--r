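#' Analyze one fundus capture
#'
#' Runs the full per-image pipeline: quality gate, vessel segmentation,
#' landmark localization, dark and bright lesion detection. Lesion detection
#' is attempted even on ungradable images (a lesion finding overrides
#' quality at grading time); stage failures are recorded as reasons rather
#' than thrown, so the function never errors on a decodable image.
#'
#' @param image a [fundus_image()].
#' @param params parameter list from [default_params()].
#' @return object of class `image_analysis` with fields `quality`, `frame`
#'   (or `NULL`), `vessels` (or `NULL`), `lesions` (possibly empty list) and
#'   `reasons` (character log of stage failures).
#' @export
analyze_image <- function(image, params = default_params()) {
  stopifnot(inherits(image, "fundus_image"))
  quality <- assess_quality(image, params)
  frame <- NULL; vessels <- NULL; lesions <- list()
  reasons <- character()
  if (is.null(quality$field)) {
    reasons <- c(reasons, "field not detected")
  } else {
    green <- image$pixels[, , 2]
    fmask <- quality$field$mask
    vessels <- tryCatch(segment_vessels(green, fmask, params),
                        error = function(e) {
                          reasons <<- c(reasons, conditionMessage(e)); NULL
                        })
    frame <- tryCatch(locate_landmarks(green, quality$field, vessels, params),
                      error = function(e) {
                        reasons <<- c(reasons, conditionMessage(e)); NULL
                      })
    if (!is.null(frame) && !is.null(vessels)) {
      lesions <- c(
        detect_dark_lesions(green, vessels, frame, quality$field, params),
        detect_bright_lesions(green, frame, quality$field, params))
    }
  }
  structure(list(quality = quality, frame = frame, vessels = vessels,
                 lesions = lesions, reasons = reasons,
                 patient_id = image$patient_id, eye = image$eye,
                 capture = image$capture),
            class = "image_analysis")
}

#' @export
print.image_analysis <- function(x, ...) {
  types <- vapply(x$lesions, `[[`, "", "type")
  cat(sprintf("<image_analysis> %s %s#%d gradable=%s lesions=%d (%s)%s\n",
              x$patient_id, x$eye, x$capture, x$quality$gradable,
              length(types),
              if (length(types)) paste(names(table(types)),
                                       table(types), collapse = " ") else "-",
              if (length(x$reasons)) paste0(" reasons: ",
                                            paste(x$reasons, collapse = "; "))
              else ""))
  invisible(x)
}

# JSON-serializable summary of an analysis (documented schema).
analysis_to_list <- function(an) {
  list(
    patient_id = an$patient_id, eye = an$eye, capture = an$capture,
    quality = list(gradable = an$quality$gradable,
                   sharpness = an$quality$sharpness,
                   illuminated_fraction = an$quality$illuminated_fraction,
                   saturation_fraction = an$quality$saturation_fraction,
                   reasons = as.list(an$quality$reasons)),
    frame = if (is.null(an$frame)) NULL else list(
      disc_center = an$frame$disc_center, disc_radius = an$frame$disc_radius,
      fovea_center = an$frame$fovea_center, axis_angle = an$frame$axis_angle,
      dd = an$frame$dd),
    lesions = lapply(an$lesions, function(l) list(
      type = l$type, centroid = l$centroid, area = l$area,
      circularity = l$circularity, contrast = l$contrast,
      polar_r = l$polar_r, theta = l$theta, quadrant = l$quadrant)),
    reasons = as.list(an$reasons))
}
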