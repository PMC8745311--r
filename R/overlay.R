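# Pixel coordinates of a circle outline (radius r, thickness ~th px).
circle_px <- function(center, r, h, w, th = 2) {
  pts <- lapply(seq(r - (th - 1) / 2, r + (th - 1) / 2, by = 0.5), function(rr) {
    t <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * rr * 2)))
    cbind(round(center[2] + rr * sin(t)), round(center[1] + rr * cos(t)))
  })
  pts <- unique(do.call(rbind, pts))
  pts[pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w, ,
      drop = FALSE]
}

# Pixel coordinates of a straight segment from a to b (x, y points).
segment_px <- function(a, b, h, w) {
  n <- max(2, ceiling(pt_dist(a, b)))
  xs <- round(seq(a[1], b[1], length.out = n))
  ys <- round(seq(a[2], b[2], length.out = n))
  pts <- unique(cbind(ys, xs))
  pts[pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w, ,
      drop = FALSE]
}

paint_px <- function(px, pts, col) {
  if (nrow(pts) == 0) return(px)
  for (k in 1:3) px[cbind(pts, rep(k, nrow(pts)))] <- col[k]
  px
}

# Grid pixel coordinates for a frame (rings at 1 and 2 dd + quadrant spokes).
overlay_grid_px <- function(frame, h, w) {
  pts <- rbind(circle_px(frame$fovea_center, frame$dd, h, w, th = 1),
               circle_px(frame$fovea_center, 2 * frame$dd, h, w, th = 1))
  axis <- (frame$disc_center - frame$fovea_center) /
    pt_dist(frame$disc_center, frame$fovea_center)
  perp <- c(axis[2], -axis[1])
  for (dir in list(axis, -axis, perp, -perp))
    pts <- rbind(pts, segment_px(frame$fovea_center,
                                 frame$fovea_center + 2 * frame$dd * dir,
                                 h, w))
  unique(pts)
}

#' Render the diagnostic overlay
#'
#' Draws the analysis on top of the photograph: red ring markers at dark
#' lesions (microaneurysms, hemorrhages), blue ring markers at bright
#' lesions (exudates, cotton-wool spots), and the fovea-centred polar grid
#' with rings at 1 and 2 disc-diameters plus the quadrant spokes, in white.
#'
#' @param image a [fundus_image()].
#' @param analysis an [analyze_image()] result; must contain a frame.
#' @param marker_radius marker ring radius in pixels.
#' @return `H x W x 3` numeric raster in `[0, 1]`.
#' @export
render_overlay <- function(image, analysis, marker_radius = 9) {
  stopifnot(inherits(image, "fundus_image"),
            inherits(analysis, "image_analysis"))
  if (is.null(analysis$frame)) stop("analysis has no coordinate frame")
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  px <- paint_px(px, overlay_grid_px(analysis$frame, h, w), c(1, 1, 1))
  for (l in analysis$lesions) {
    col <- if (l$type %in% c("MA", "HEM")) c(1, 0, 0) else c(0, 0, 1)
    px <- paint_px(px, circle_px(l$centroid, marker_radius, h, w), col)
  }
  px
}
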