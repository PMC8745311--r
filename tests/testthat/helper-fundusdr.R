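# Shared helpers for the test suite.

# Match detected candidates to ground-truth lesions by nearest centroid
# within one (true) lesion radius; returns hits, type agreements, truth n.
match_lesions <- function(truth, cands) {
  hits <- 0L; type_ok <- 0L
  for (tl in truth) {
    if (length(cands) == 0) next
    ds <- vapply(cands, function(cd) sqrt(sum((cd$centroid - tl$center)^2)), 0)
    if (min(ds) <= max(tl$radius, 4)) {
      hits <- hits + 1L
      if (cands[[which.min(ds)]]$type == tl$type) type_ok <- type_ok + 1L
    }
  }
  c(hits = hits, type_ok = type_ok, n = length(truth))
}

# A faster, smaller geometry for tests that do not measure pixel metrics.
small_config <- function(...) synth_image_config(width = 400, height = 400, ...)

# Minimal hand-built image_analysis for grading-rule tests.
fake_analysis <- function(gradable = TRUE, lesions = list()) {
  structure(list(
    quality = structure(list(gradable = gradable, sharpness = NA_real_,
                             illuminated_fraction = NA_real_,
                             saturation_fraction = NA_real_,
                             reasons = character(), field = NULL),
                        class = "quality_report"),
    frame = NULL, vessels = NULL, lesions = lesions, reasons = character()),
    class = "image_analysis")
}

# Minimal lesion candidate as produced by the detectors.
fake_candidate <- function(type, frame_x = runif(1, -2, 2),
                           frame_y = runif(1, -2, 2), polar_r = NULL,
                           quadrant = NULL) {
  r <- sqrt(frame_x^2 + frame_y^2)
  th <- atan2(frame_y, frame_x) * 180 / pi
  q <- if (th >= 0 && th < 90) 1L else if (th >= 90) 2L
    else if (th < -90) 3L else 4L
  list(type = type, centroid = c(NA_real_, NA_real_), area = 20,
       circularity = 0.9, contrast = 0.2,
       polar_r = polar_r %||% r, theta = th,
       quadrant = quadrant %||% q,
       frame_x = frame_x, frame_y = frame_y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided 95% binomial acceptance band for an observed count.
binom_band <- function(n, p) stats::qbinom(c(0.025, 0.975), n, p)
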