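# Label a thresholded response map and package components as candidates.
# Filtering (area, exclusion zones, vessel overlap) is done by the callers.
extract_candidates <- function(resp, frame) {
  lab <- as_mat(EBImage::bwlabel((resp > 0) * 1))
  n <- max(lab)
  if (n == 0) return(list())
  shp <- EBImage::computeFeatures.shape(lab)
  g <- coord_grid(nrow(resp), ncol(resp))
  lapply(seq_len(n), function(i) {
    sel <- which(lab == i)
    area <- shp[i, "s.area"]
    per <- max(shp[i, "s.perimeter"], 1)
    centroid <- c(mean(g$x[sel]), mean(g$y[sel]))
    pol <- frame_polar(frame, centroid)
    list(centroid = centroid, area = area,
         circularity = min(4 * pi * area / per^2, 1.15),
         contrast = mean(resp[sel]),
         polar_r = pol$r, theta = pol$theta, quadrant = pol$quadrant,
         frame_x = pol$r * cos(pol$theta * pi / 180),
         frame_y = pol$r * sin(pol$theta * pi / 180),
         mask_idx = sel)
  })
}

#' Detect dark lesions (microaneurysms and hemorrhages)
#'
#' Dark residual objects are the dark blobs remaining once the vessel tree
#' is accounted for: the residual of a grayscale closing of the green plane
#' is thresholded at the minimum contrast and labelled. The connected vessel
#' tree forms one residual component far above the lesion area range and is
#' discarded by the structural area filter; any candidate with most of its
#' pixels on the (dilated) vessel mask, or lying in the disc or fovea
#' exclusion zones, is likewise dropped. A surviving candidate is a
#' microaneurysm if small and nearly circular (area at most `a_ma`,
#' circularity at least `circ_ma`), a hemorrhage otherwise.
#'
#' @param green green plane matrix.
#' @param vessels a [segment_vessels()] result.
#' @param frame a [locate_landmarks()] frame.
#' @param field list with `center`, `radius` of the fundus field.
#' @param params parameter list; uses the `$dark_lesions` block.
#' @return list of lesion candidates (type `MA` or `HEM`) with centroid,
#'   area, circularity, contrast and fovea-centred polar coordinates.
#' @export
detect_dark_lesions <- function(green, vessels, frame, field,
                                params = default_params()) {
  p <- params$dark_lesions
  bg <- as_mat(EBImage::closing(green, EBImage::makeBrush(p$close_size, "disc")))
  resid <- pmax(bg - green, 0)
  resid[resid < p$c_min] <- 0
  vdil <- as_mat(EBImage::dilate(vessels$suppress * 1,
                                 EBImage::makeBrush(2 * p$vessel_dilate + 1,
                                                    "disc"))) > 0
  resid[vdil] <- 0
  cands <- extract_candidates(resid, frame)
  out <- list()
  for (cd in cands) {
    if (cd$area < p$a_min || cd$area > p$a_max) next
    if (pt_dist(cd$centroid, frame$disc_center) <
        p$disc_exclude_dd * frame$dd) next
    if (cd$polar_r < p$fovea_exclude_dd) next    # the fovea itself is dark
    # rim ring beyond the vessel detector's reach holds undetected vessel tips
    if (pt_dist(cd$centroid, field$center) > field$radius - p$rim_exclude) next
    cd$type <- if (cd$area <= p$a_ma && cd$circularity >= p$circ_ma)
      "MA" else "HEM"
    cd$mask_idx <- NULL
    out[[length(out) + 1]] <- cd
  }
  out
}

#' Detect bright lesions (exudates and cotton-wool spots)
#'
#' Bright blobs are extracted with a grayscale white-top-hat after all dark
#' structure (vessels, dark lesions) has been removed by a wide grayscale
#' closing — otherwise dark objects shed bright halos in the top-hat. The
#' response is thresholded at the minimum contrast and cleared in a guard
#' band along the field rim (where the top-hat reacts to the field
#' boundary); components touching the slightly dilated optic disc circle
#' are excluded so the disc is never reported as a lesion. Candidates with
#' a sharp boundary (mean gradient magnitude on the component boundary at
#' least `g_min`) are classified as exudates, soft-edged ones as
#' cotton-wool spots.
#'
#' @inheritParams detect_dark_lesions
#' @param params parameter list; uses the `$bright_lesions` block.
#' @return list of lesion candidates (type `EX` or `CWS`).
#' @export
detect_bright_lesions <- function(green, frame, field,
                                  params = default_params()) {
  p <- params$bright_lesions
  h <- nrow(green); w <- ncol(green)
  work <- as_mat(EBImage::closing(green, EBImage::makeBrush(p$fill_size, "disc")))
  resp <- white_tophat(work, EBImage::makeBrush(p$tophat_size, "disc"))
  resp[resp < p$b_min] <- 0
  guard <- field$radius - (p$tophat_size + 5) / 2
  resp[!disc_mask(h, w, field$center, guard)] <- 0
  cands <- extract_candidates(resp, frame)
  disc_excl_r <- frame$disc_radius + p$disc_dilate_dd * frame$dd
  g <- coord_grid(h, w)
  dist_disc <- sqrt((g$x - frame$disc_center[1])^2 +
                    (g$y - frame$disc_center[2])^2)
  gm <- grad_mag(work)
  out <- list()
  for (cd in cands) {
    if (cd$area < p$a_min || cd$area > p$a_max) next
    if (min(dist_disc[cd$mask_idx]) <= disc_excl_r) next  # overlaps the disc
    comp <- matrix(FALSE, h, w); comp[cd$mask_idx] <- TRUE
    inner <- as_mat(EBImage::erode(comp * 1, EBImage::makeBrush(3, "box"))) > 0
    boundary <- comp & !inner
    cd$edge_sharpness <- mean(gm[boundary])
    cd$type <- if (cd$edge_sharpness >= p$g_min) "EX" else "CWS"
    cd$mask_idx <- NULL
    out[[length(out) + 1]] <- cd
  }
  out
}
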