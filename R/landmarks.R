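#' Locate the optic disc and macula; build the retinal coordinate frame
#'
#' The optic disc is found on the green plane as the brightest circular
#' region: vessels are filled by a grayscale closing, the plane is smoothed,
#' and a binary mask of the top-percentile pixels inside the field is
#' labelled; the largest component of plausible disc area (ties broken
#' toward the brighter) gives the disc centre. The disc radius is then
#' refined as the half-maximum crossing of the radial intensity profile
#' about that centre, which is insensitive to the percentile chosen. The
#' fovea is the darkest windowed region within an annulus 2–3
#' disc-diameters from the disc, within a configurable half-angle of the
#' disc horizontal (searched on both sides, since laterality is not
#' assumed).
#'
#' The returned frame measures lesion positions in polar coordinates about
#' the fovea: `r` in disc-diameter (dd) units and `theta` in degrees from
#' the fovea-to-disc axis, positive toward the superior retina (up in the
#' image).
#'
#' @param green green plane matrix.
#' @param field list with `center`, `radius` (from [assess_quality()]), or
#'   `NULL` to refit from the plane.
#' @param vessels optional [segment_vessels()] result; vessel pixels are
#'   additionally suppressed before thresholding when supplied.
#' @param params parameter list; uses the `$landmarks` block.
#' @return object of class `retinal_frame`: `disc_center`, `disc_radius`,
#'   `fovea_center`, `axis_angle` (degrees), `dd`.
#' @export
locate_landmarks <- function(green, field = NULL, vessels = NULL,
                             params = default_params()) {
  p <- params$landmarks
  h <- nrow(green); w <- ncol(green)
  if (is.null(field)) {
    cand <- green > 0.05
    if (!any(cand)) stop("disc not found: empty image")
    g0 <- coord_grid(h, w)
    field <- list(center = c(mean(g0$x[cand]), mean(g0$y[cand])),
                  radius = sqrt(sum(cand) / pi))
  }
  fmask <- disc_mask(h, w, field$center, 0.95 * field$radius)

  filled <- green
  if (!is.null(vessels) && any(vessels$mask)) {
    closed <- as_mat(EBImage::closing(green, EBImage::makeBrush(13, "disc")))
    filled[vessels$mask] <- closed[vessels$mask]
  } else {
    filled <- as_mat(EBImage::closing(green, EBImage::makeBrush(13, "disc")))
  }
  sm <- as_mat(EBImage::gblur(filled, p$smooth_sigma))

  thr <- quantile(sm[fmask], p$disc_quantile, names = FALSE)
  bright <- fmask & sm >= thr
  lab <- as_mat(EBImage::bwlabel(bright * 1))
  sizes <- tabulate(as.vector(lab))
  field_area <- pi * field$radius^2
  plausible <- which(sizes >= p$disc_min_area_frac * field_area &
                     sizes <= p$disc_max_area_frac * field_area)
  if (length(plausible) == 0) stop("disc not found")
  best <- plausible[order(-sizes[plausible],
                          -vapply(plausible, function(i)
                            mean(sm[lab == i]), 0))][1]
  sel <- lab == best
  g <- coord_grid(h, w)
  disc_center <- c(mean(g$x[sel]), mean(g$y[sel]))

  # refine the radius: area of the half-maximum component about the centre
  dxc <- g$x - disc_center[1]; dyc <- g$y - disc_center[2]
  rr <- sqrt(dxc^2 + dyc^2)
  peak <- mean(sm[rr < 4])
  bg <- median(sm[fmask])
  if (peak - bg < p$disc_min_contrast) stop("disc not found: no bright peak")
  half <- bg + 0.5 * (peak - bg)
  labh <- as_mat(EBImage::bwlabel((sm >= half & fmask) * 1))
  centre_lab <- labh[round(disc_center[2]), round(disc_center[1])]
  if (centre_lab == 0) stop("disc not found: no half-maximum support")
  area_half <- sum(labh == centre_lab)
  disc_radius <- min(sqrt(area_half / pi), 0.3 * field$radius)
  dd <- 2 * disc_radius

  # fovea: darkest window in a 2-3 dd annulus near the disc horizontal
  win <- max(3, round(p$fovea_window_frac * disc_radius))
  avg <- as_mat(EBImage::gblur(filled, win / 2))
  dx <- g$x - disc_center[1]; dy <- g$y - disc_center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- abs(atan2(dy, dx)) * 180 / pi          # angle from +x axis
  ang <- pmin(ang, 180 - ang)                   # from horizontal, both sides
  annulus <- r >= p$fovea_annulus_dd[1] * dd & r <= p$fovea_annulus_dd[2] * dd &
    ang <= p$fovea_half_angle &
    disc_mask(h, w, field$center, field$radius - win - 2)
  if (!any(annulus)) stop("macula not found: search region empty")
  idx <- which(annulus)
  best_px <- idx[which.min(avg[idx])]
  fovea_center <- c(g$x[best_px], g$y[best_px])
  axis <- disc_center - fovea_center
  structure(list(disc_center = disc_center, disc_radius = disc_radius,
                 fovea_center = fovea_center,
                 axis_angle = signed_angle(c(1, 0), axis),
                 dd = dd),
            class = "retinal_frame")
}

# Polar coordinates of a pixel point in a retinal frame.
frame_polar <- function(frame, pt) {
  v <- pt - frame$fovea_center
  r <- sqrt(sum(v^2)) / frame$dd
  theta <- signed_angle(frame$disc_center - frame$fovea_center, v)
  quadrant <- if (theta >= 0 && theta < 90) 1L else if (theta >= 90) 2L
    else if (theta < -90) 3L else 4L
  list(r = r, theta = theta, quadrant = quadrant)
}

#' @export
print.retinal_frame <- function(x, ...) {
  cat(sprintf("<retinal_frame> disc (%.0f, %.0f) r=%.1f; fovea (%.0f, %.0f); dd=%.1f px\n",
              x$disc_center[1], x$disc_center[2], x$disc_radius,
              x$fovea_center[1], x$fovea_center[2], x$dd))
  invisible(x)
}
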