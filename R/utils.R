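# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1013904223) %% 2147483647L)
}

# Pixel-centre coordinate grids for an H x W raster (x = column, y = row).
coord_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

# Logical mask of the circular fundus field.
disc_mask <- function(h, w, center, radius) {
  g <- coord_grid(h, w)
  (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
}

# Stamp filled discs of radius r at integer centres (x, y) into a logical mask.
stamp_discs <- function(mask, xs, ys, rs) {
  h <- nrow(mask); w <- ncol(mask)
  for (r in unique(rs)) {
    sel <- rs == r
    ir <- max(0L, as.integer(ceiling(r)))
    off <- expand.grid(dx = -ir:ir, dy = -ir:ir)
    off <- off[off$dx^2 + off$dy^2 <= r^2, , drop = FALSE]
    px <- as.vector(outer(off$dx, round(xs[sel]), "+"))
    py <- as.vector(outer(off$dy, round(ys[sel]), "+"))
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    mask[cbind(py[ok], px[ok])] <- TRUE
  }
  mask
}

# Euclidean distance between two (x, y) points.
pt_dist <- function(a, b) sqrt(sum((a - b)^2))

# Clamp to [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Quantize a [0,1] raster to 8-bit levels (ensures byte-identical round trips).
quantize8 <- function(x) round(clamp(x) * 255) / 255

# Gradient magnitude (central differences) of a matrix.
grad_mag <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

# EBImage results back to plain matrices.
as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

# Grayscale morphology wrappers (EBImage).
black_tophat <- function(m, kern) as_mat(EBImage::blackTopHat(m, kern))
white_tophat <- function(m, kern) as_mat(EBImage::whiteTopHat(m, kern))

# Signed angle (degrees, in (-180, 180]) from vector u to vector v, measured
# with y increasing upward on screen (pixel y runs downward, hence the sign
# flip), so that a horizontal mirror of the image flips the sign.
signed_angle <- function(u, v) {
  cross <- -(u[1] * v[2] - u[2] * v[1])  # y-down pixel coords -> flip sign
  dot <- sum(u * v)
  ang <- atan2(cross, dot) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_levels <- function() c("NODR", "MILD", "MOD", "SEV", "PROL")
diag_levels <- function() c("DR", "NODR", "UNG")

stage_rank <- function(stage) match(stage, stage_levels())
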