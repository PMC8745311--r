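#' Vessel segmentation on the green plane
#'
#' Detects the retinal vessel tree as dark elongated structures: the maximum
#' black-top-hat response over line structuring elements at several
#' orientations, thresholded at a fixed contrast floor, restricted to the
#' (rim-eroded) field. Components are then classified by shape using the
#' distance transform: a component is vessel-like when its area is large
#' relative to its inscribed-disc area (elongated), and blob-like dark
#' objects (lesion candidates) are excluded. The returned `mask` keeps
#' vessel-like components above the minimum size; `suppress` additionally
#' keeps small vessel-like fragments (used to silence vessel residue during
#' dark-lesion detection). A morphological skeleton (Lantuejoul) of the mask
#' is returned alongside and is a subset of the mask by construction.
#'
#' @param green single-channel intensity matrix (the green plane).
#' @param field_mask logical matrix of in-field pixels.
#' @param params parameter list; uses the `$vessels` block.
#' @return object of class `vessel_map` with logical `mask`, `skeleton` and
#'   `suppress`.
#' @export
segment_vessels <- function(green, field_mask, params = default_params()) {
  v <- params$vessels
  if (!any(field_mask)) stop("empty field mask")
  angles <- seq(0, 180, length.out = v$n_angles + 1)[seq_len(v$n_angles)]
  resp <- matrix(0, nrow(green), ncol(green))
  for (a in angles) {
    resp <- pmax(resp, black_tophat(green, line_brush(v$line_length, a)))
  }
  inner <- as_mat(EBImage::erode(
    field_mask * 1, EBImage::makeBrush(2 * v$field_erode + 1, "disc"))) > 0
  raw <- resp >= v$threshold & inner
  raw <- fill_vessel_holes(raw, v$hole_max)
  lab <- as_mat(EBImage::bwlabel(raw * 1))
  n <- max(lab)
  if (n == 0) {
    empty <- matrix(FALSE, nrow(green), ncol(green))
    return(structure(list(mask = empty, skeleton = empty, suppress = empty),
                     class = "vessel_map"))
  }
  dm <- as_mat(EBImage::distmap(raw * 1))
  labv <- as.vector(lab); labv_pos <- labv > 0
  sizes <- tabulate(labv, n)
  maxd <- rep(0, n)
  agg <- tapply(as.vector(dm)[labv_pos], labv[labv_pos], max)
  maxd[as.integer(names(agg))] <- agg
  # elongated if area clearly exceeds the inscribed-disc area, and dark
  # relative to the field background (the dark-vessel assumption: corridors
  # of bright structures must not pass)
  med <- median(green[inner])
  dark <- rep(FALSE, n)
  gagg <- tapply(as.vector(green)[labv_pos], labv[labv_pos], median)
  dark[as.integer(names(gagg))] <- gagg < med - v$threshold
  vessel_like <- sizes > 3 * pi * maxd^2 & dark
  mask <- matrix(labv_pos & vessel_like[pmax(labv, 1)] &
                   sizes[pmax(labv, 1)] >= v$min_size,
                 nrow(green), ncol(green))
  suppress <- matrix(labv_pos & vessel_like[pmax(labv, 1)],
                     nrow(green), ncol(green))
  structure(list(mask = mask, skeleton = morph_skeleton(mask),
                 suppress = suppress),
            class = "vessel_map")
}

# Fill small enclosed holes of a binary response mask: a component's own
# interior (the ring response of a wide dark blob, or a vessel crossing)
# is filled, and so is a hole bordered only by elongated components; a hole
# that touches a blob-like component (a lesion candidate sitting inside a
# vessel loop) is left open so the candidate is never absorbed.
fill_vessel_holes <- function(raw, hole_max) {
  h <- nrow(raw)
  lab0 <- as_mat(EBImage::bwlabel(raw * 1))
  n0 <- max(lab0)
  if (n0 == 0) return(raw)
  dm0 <- as_mat(EBImage::distmap(raw * 1))
  sizes0 <- tabulate(as.vector(lab0), n0)
  maxd0 <- rep(0, n0)
  pos <- as.vector(lab0) > 0
  agg <- tapply(as.vector(dm0)[pos], as.vector(lab0)[pos], max)
  maxd0[as.integer(names(agg))] <- agg
  blob0 <- sizes0 <= 3 * pi * maxd0^2
  holes <- as_mat(EBImage::bwlabel(
    ((as_mat(EBImage::fillHull(raw * 1)) > 0) & !raw) * 1))
  nh <- max(holes)
  if (nh == 0) return(raw)
  hsize <- tabulate(as.vector(holes), nh)
  for (i in which(hsize <= hole_max)) {
    idx <- which(holes == i)
    nb <- unique(lab0[c(idx - 1L, idx + 1L, idx - h, idx + h)])
    nb <- nb[nb > 0]
    if (length(nb) == 1L || !any(blob0[nb])) raw[idx] <- TRUE
  }
  raw
}

# Line structuring element at any angle (obtuse angles are the mirror of
# their supplement, which is all the underlying brush generator supports).
line_brush <- function(len, angle) {
  a <- angle %% 180
  if (a <= 90) EBImage::makeBrush(len, "line", angle = a)
  else {
    k <- EBImage::makeBrush(len, "line", angle = 180 - a)
    k[, rev(seq_len(ncol(k))), drop = FALSE]
  }
}

# Lantuejoul morphological skeleton: union over n of erode^n(M) minus its
# opening. Always a subset of the input mask.
morph_skeleton <- function(mask) {
  kern <- EBImage::makeBrush(3, "box")
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  cur <- mask * 1
  while (any(cur > 0)) {
    opened <- as_mat(EBImage::opening(cur, kern))
    skel <- skel | (cur > 0 & opened == 0)
    cur <- as_mat(EBImage::erode(cur, kern))
  }
  skel
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %d vessel px, %d skeleton px\n",
              sum(x$mask), sum(x$skeleton)))
  invisible(x)
}
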