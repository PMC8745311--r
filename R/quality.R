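#' Image quality gate
#'
#' Decides whether a capture is gradable. Metrics are computed only inside
#' the detected circular field: `sharpness` is the high-frequency energy of
#' the green plane (mean squared residual against a 2 px Gaussian smooth)
#' normalised by its squared mean intensity (so a global exposure change
#' does not move it), `illuminated_fraction` is the fraction
#' of field pixels whose luminance clears the exposure floor, and
#' `saturation_fraction` the fraction at the sensor maximum. The image is
#' gradable iff sharpness and illumination clear their minima and saturation
#' stays below its maximum.
#'
#' @param image a [fundus_image()].
#' @param params parameter list, see [default_params()]; uses the `$quality`
#'   block.
#' @return object of class `quality_report` with fields `gradable`,
#'   `sharpness`, `illuminated_fraction`, `saturation_fraction`, `reasons`,
#'   and the detected `field` (center, radius, mask).
#' @export
assess_quality <- function(image, params = default_params()) {
  stopifnot(inherits(image, "fundus_image"))
  q <- params$quality
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (min(h, w) < q$min_size)
    stop(sprintf("image too small for analysis (%d x %d, need >= %d)",
                 h, w, q$min_size))
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  cand <- lum > q$field_floor
  if (mean(cand) < q$min_field_fraction) {
    return(structure(list(gradable = FALSE, sharpness = 0,
                          illuminated_fraction = 0, saturation_fraction = 0,
                          reasons = "underexposed", field = NULL),
                     class = "quality_report"))
  }
  # keep the largest connected candidate region and close its holes, so the
  # field fit is insensitive to isolated bright noise outside the field
  lab <- as_mat(EBImage::bwlabel(cand * 1))
  sizes <- tabulate(as.vector(lab))
  cand <- as_mat(EBImage::fillHull((lab == which.max(sizes)) * 1)) > 0
  g <- coord_grid(h, w)
  cx <- mean(g$x[cand]); cy <- mean(g$y[cand])
  radius <- sqrt(sum(cand) / pi)
  field <- disc_mask(h, w, c(cx, cy), 0.97 * radius)

  green <- px[, , 2]
  hf <- green - as_mat(EBImage::gblur(green, 2))
  mu <- mean(green[field])
  sharpness <- mean(hf[field]^2) / (mu^2 + 1e-12)
  illuminated <- mean(lum[field] >= q$illum_floor)
  saturated <- mean(pmax(px[, , 1], px[, , 2], px[, , 3])[field] >= 254 / 255)

  reasons <- character()
  if (sharpness < q$sharpness_min) reasons <- c(reasons, "blur")
  if (illuminated < q$illuminated_min) reasons <- c(reasons, "underexposed")
  if (saturated > q$saturation_max) reasons <- c(reasons, "saturated")
  structure(list(gradable = length(reasons) == 0L,
                 sharpness = sharpness,
                 illuminated_fraction = illuminated,
                 saturation_fraction = saturated,
                 reasons = reasons,
                 field = list(center = c(cx, cy), radius = radius,
                              mask = field)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> gradable=%s sharpness=%.4g illum=%.2f sat=%.3f%s\n",
              x$gradable, x$sharpness, x$illuminated_fraction,
              x$saturation_fraction,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ","), "]")
              else ""))
  invisible(x)
}
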