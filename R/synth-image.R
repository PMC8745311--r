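#' Configuration for one synthetic fundus capture
#'
#' Describes the geometry, vasculature, lesion load and degradation of a
#' synthetic non-mydriatic fundus photograph: a circular field on a dark
#' surround, a bright optic disc with a dark branching vessel tree rooted in
#' it, a dark fovea 2.5 disc-diameters temporal to the disc, and
#' parameterised lesions. Defaults emulate a 45-degree macula-centred field:
#' disc radius about a tenth of the image width, disc placed nasally (to the
#' right of the image for a right eye, mirrored for the left).
#'
#' @param width,height raster size in pixels.
#' @param eye `"OD"` or `"OS"`; controls the temporal direction.
#' @param field_radius radius of the fundus field circle.
#' @param disc_center,disc_radius optic disc geometry; defaults place the
#'   disc just inside the nasal field edge.
#' @param fovea_offset_dd fovea distance from the disc centre along the
#'   temporal axis, in disc-diameter units.
#' @param vessel_branches number of main vessel trunks leaving the disc.
#' @param vessel_width_range `c(min, max)` vessel widths in pixels.
#' @param vessel_contrast vessel darkening as a fraction of the local
#'   background green intensity.
#' @param lesions list of lesion descriptors from [lesion_spec()].
#' @param venous_beading_quadrants,irma_quadrants,neovascularization
#'   annotation flags recorded in the ground truth (not rendered as pixels).
#' @param blur_sigma,vignette_strength,exposure_scale degradation: Gaussian
#'   blur sigma (px), radial vignetting in `[0, 1]`, global exposure scale in
#'   `(0, 1]`.
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param seed integer seed; the whole render is a pure function of the
#'   configuration, including this seed.
#' @param noise_seed optional separate seed for the pixel noise only, so
#'   repeat captures of one eye can share geometry, vessels and lesions
#'   while differing in noise; defaults to `seed`.
#' @return object of class `synth_image_config`.
#' @export
synth_image_config <- function(width = 600, height = 600, eye = "OD",
                               field_radius = round(0.4667 * min(width, height)),
                               disc_radius = round(0.10 * width),
                               disc_center = NULL,
                               fovea_offset_dd = 2.5,
                               vessel_branches = 6,
                               vessel_width_range = c(3, 8),
                               vessel_contrast = 0.45,
                               lesions = list(),
                               venous_beading_quadrants = 0L,
                               irma_quadrants = 0L,
                               neovascularization = FALSE,
                               blur_sigma = 0, vignette_strength = 0,
                               exposure_scale = 1, noise_sd = 0.008,
                               seed = 1L, noise_seed = NULL) {
  eye <- match.arg(eye, c("OD", "OS"))
  center <- c(width / 2, height / 2)
  nasal <- if (eye == "OD") 1 else -1   # disc sits nasally
  if (is.null(disc_center))
    disc_center <- c(center[1] + nasal * (field_radius - disc_radius - 5),
                     center[2])
  dd <- 2 * disc_radius
  fovea_center <- disc_center - c(nasal * fovea_offset_dd * dd, 0)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              eye = eye, field_center = center, field_radius = field_radius,
              disc_center = disc_center, disc_radius = disc_radius,
              dd = dd, fovea_center = fovea_center,
              fovea_offset_dd = fovea_offset_dd,
              vessel_branches = vessel_branches,
              vessel_width_range = vessel_width_range,
              vessel_contrast = vessel_contrast,
              lesions = lesions,
              venous_beading_quadrants = as.integer(venous_beading_quadrants),
              irma_quadrants = as.integer(irma_quadrants),
              neovascularization = isTRUE(neovascularization),
              blur_sigma = blur_sigma,
              vignette_strength = vignette_strength,
              exposure_scale = exposure_scale,
              noise_sd = noise_sd, seed = as.integer(seed),
              noise_seed = if (is.null(noise_seed)) NULL else as.integer(noise_seed))
  class(cfg) <- "synth_image_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  inside_field <- function(p, margin = 0)
    pt_dist(p, cfg$field_center) + margin <= cfg$field_radius
  if (cfg$vignette_strength < 0 || cfg$vignette_strength > 1)
    stop("vignette_strength must lie in [0, 1]")
  if (cfg$exposure_scale <= 0 || cfg$exposure_scale > 1)
    stop("exposure_scale must lie in (0, 1]")
  if (!inside_field(cfg$disc_center, cfg$disc_radius))
    stop("optic disc extends outside the field circle")
  if (!inside_field(cfg$fovea_center, 0.35 * cfg$dd))
    stop("fovea lies outside the field circle")
  if (pt_dist(cfg$disc_center, cfg$fovea_center) <
      cfg$disc_radius + 0.35 * cfg$dd)
    stop("disc and fovea overlap")
  for (l in cfg$lesions) {
    if (l$radius <= 0) stop("lesion radii must be positive")
    if (!inside_field(l$center, l$radius))
      stop("lesion placed outside the field circle")
  }
  invisible(cfg)
}

#' Describe one synthetic lesion
#'
#' @param type `"MA"` (microaneurysm), `"HEM"` (hemorrhage), `"EX"`
#'   (hard exudate) or `"CWS"` (cotton-wool spot).
#' @param center `(x, y)` pixel position.
#' @param radius lesion radius in pixels.
#' @return a lesion descriptor list.
#' @export
lesion_spec <- function(type, center, radius) {
  type <- match.arg(type, c("MA", "HEM", "EX", "CWS"))
  list(type = type, center = as.numeric(center), radius = as.numeric(radius))
}

# Grow the vessel tree as stamped discs; returns logical mask.
# Pure function of cfg (uses the RNG; callers wrap in with_seed).
grow_vessel_tree <- function(cfg) {
  h <- cfg$height; w <- cfg$width
  mask <- matrix(FALSE, h, w)
  wmin <- cfg$vessel_width_range[1]; wmax <- cfg$vessel_width_range[2]
  n <- cfg$vessel_branches
  base_angles <- seq(0, 360, length.out = n + 1)[-(n + 1)] +
    runif(n, -20, 20)
  xs <- c(); ys <- c(); rs <- c()
  stack <- lapply(base_angles, function(a)
    list(pos = cfg$disc_center, ang = a * pi / 180,
         width = runif(1, 0.85 * wmax, wmax), depth = 0L))
  max_seg <- 420L
  while (length(stack) > 0) {
    br <- stack[[1]]; stack <- stack[-1]
    pos <- br$pos; ang <- br$ang; wd <- br$width
    for (i in seq_len(max_seg)) {
      pos <- pos + 2.2 * c(cos(ang), sin(ang))
      ang <- ang + rnorm(1, 0, 0.16)
      wd <- wd * 0.9975
      if (wd < wmin) break
      if (pt_dist(pos, cfg$field_center) > cfg$field_radius - 3) break
      # keep vessels out of the foveal avascular zone
      if (pt_dist(pos, cfg$fovea_center) < 0.35 * cfg$dd) break
      xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); rs <- c(rs, wd / 2)
      if (br$depth < 3 && runif(1) < 0.035) {
        side <- sample(c(-1, 1), 1)
        stack <- c(stack, list(list(
          pos = pos, ang = ang + side * runif(1, 0.35, 0.9),
          width = wd * 0.72, depth = br$depth + 1L)))
      }
    }
  }
  if (length(xs)) mask <- stamp_discs(mask, xs, ys, round(rs * 2) / 2)
  mask
}

lesion_quadrant <- function(center, fovea, disc) {
  theta <- signed_angle(disc - fovea, center - fovea)
  if (theta >= 0 && theta < 90) 1L
  else if (theta >= 90) 2L
  else if (theta < -90) 3L
  else 4L
}

# Build the ground-truth lesion inventory implied by a config.
config_inventory <- function(cfg) {
  types <- vapply(cfg$lesions, `[[`, "", "type")
  hem_q <- unique(vapply(cfg$lesions[types == "HEM"], function(l)
    lesion_quadrant(l$center, cfg$fovea_center, cfg$disc_center), 0L))
  bright <- cfg$lesions[types %in% c("EX", "CWS")]
  bdist <- if (length(bright))
    min(vapply(bright, function(l)
      pt_dist(l$center, cfg$fovea_center), 0)) / cfg$dd else NA_real_
  lesion_inventory(
    ma = sum(types == "MA"), hem = sum(types == "HEM"),
    ex = sum(types == "EX"), cws = sum(types == "CWS"),
    hemorrhage_quadrants = length(hem_q),
    venous_beading_quadrants = cfg$venous_beading_quadrants,
    irma_quadrants = cfg$irma_quadrants,
    neovascularization = cfg$neovascularization,
    bright_lesion_min_distance_to_fovea = bdist)
}

# Paint a soft-edged blend toward `col` with weight raster `wt` inside a
# bounding box; `ch` is a list of three channel matrices (modified in place).
blend_box <- function(ch, rows, cols, wt, col, strength = c(1, 1, 1)) {
  for (k in 1:3) {
    sub <- ch[[k]][rows, cols]
    ch[[k]][rows, cols] <- sub * (1 - wt * strength[k]) +
      col[k] * wt * strength[k]
  }
  ch
}

lesion_bbox <- function(cfg, center, r, pad = 6) {
  rows <- max(1, floor(center[2] - r - pad)):min(cfg$height, ceiling(center[2] + r + pad))
  cols <- max(1, floor(center[1] - r - pad)):min(cfg$width, ceiling(center[1] + r + pad))
  list(rows = rows, cols = cols,
       dx = outer(rep(1, length(rows)), cols) - center[1],
       dy = outer(rows, rep(1, length(cols))) - center[2])
}

#' Render a synthetic fundus capture with ground truth
#'
#' Deterministically renders the configured eye: shaded circular field,
#' bright optic disc, recursive dark vessel tree, dark fovea, lesions
#' (microaneurysms as small dark circular blobs, hemorrhages as larger
#' irregular dark blobs, exudates as sharp-edged bright blobs, cotton-wool
#' spots as soft-edged bright blobs), then degradation (blur, vignetting,
#' underexposure) last. The returned ground truth records every placement,
#' the rendered vessel mask, the intended ICDR stage implied by the lesion
#' list and annotation flags, and the intended gradability (degradation
#' within the documented generator thresholds, see [default_params()]
#' `$generator`).
#'
#' @param config a [synth_image_config()].
#' @param patient_id,capture identity stamped on the returned image.
#' @return list with elements `image` (a [fundus_image()]) and `truth`
#'   (class `ground_truth`).
#' @export
generate_eye_image <- function(config, patient_id = "synthetic", capture = 1L) {
  cfg <- validate_synth_config(config)
  gen <- default_params()$generator
  h <- cfg$height; w <- cfg$width
  out <- with_seed(cfg$seed, {
    g <- coord_grid(h, w)
    rfield <- sqrt((g$x - cfg$field_center[1])^2 + (g$y - cfg$field_center[2])^2)
    infield <- rfield <= cfg$field_radius
    profile <- 1 - 0.15 * (rfield / cfg$field_radius)^2
    base <- c(0.72, 0.48, 0.22)
    noise <- with_seed(cfg$noise_seed %||% cfg$seed,
                       lapply(1:3, function(k)
                         matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)))
    ch <- lapply(1:3, function(k) {
      m <- matrix(0.015, h, w)
      m[infield] <- base[k] * profile[infield]
      m + noise[[k]]
    })

    # optic disc (rendered before the vessels, which overlay it)
    ddisc <- sqrt((g$x - cfg$disc_center[1])^2 + (g$y - cfg$disc_center[2])^2)
    wdisc <- 1 / (1 + exp((ddisc - cfg$disc_radius) / (0.05 * cfg$disc_radius)))
    disc_col <- c(0.97, 0.93, 0.72)
    for (k in 1:3) ch[[k]] <- ch[[k]] * (1 - wdisc) + disc_col[k] * wdisc

    vmask <- grow_vessel_tree(cfg)
    vsoft <- as_mat(EBImage::gblur(vmask * 1, 0.7))
    vstr <- cfg$vessel_contrast * c(0.55, 1, 0.35)
    for (k in 1:3) ch[[k]] <- ch[[k]] * (1 - vstr[k] * vsoft)

    # fovea: smooth dark depression
    dfov2 <- (g$x - cfg$fovea_center[1])^2 + (g$y - cfg$fovea_center[2])^2
    wfov <- 0.30 * exp(-dfov2 / (2 * (0.35 * cfg$dd)^2))
    fstr <- c(0.7, 1, 0.5)
    for (k in 1:3) ch[[k]] <- ch[[k]] * (1 - fstr[k] * wfov)

    for (l in cfg$lesions) ch <- render_lesion(ch, cfg, l)

    # degradation, applied last
    if (cfg$blur_sigma > 0)
      ch <- lapply(ch, function(m) as_mat(EBImage::gblur(m, cfg$blur_sigma)))
    if (cfg$vignette_strength > 0) {
      vig <- 1 - cfg$vignette_strength * (rfield / cfg$field_radius)^2
      ch <- lapply(ch, function(m) m * clamp(vig))
    }
    if (cfg$exposure_scale < 1)
      ch <- lapply(ch, function(m) m * cfg$exposure_scale)

    px <- array(0, c(h, w, 3))
    for (k in 1:3) px[, , k] <- ch[[k]]
    list(px = quantize8(px), vmask = vmask)
  })

  gradable <- cfg$blur_sigma < gen$blur_fail &&
    cfg$exposure_scale >= gen$exposure_fail &&
    cfg$vignette_strength < gen$vignette_fail
  inv <- config_inventory(cfg)
  truth <- structure(list(
    disc_center = cfg$disc_center, disc_radius = cfg$disc_radius,
    fovea_center = cfg$fovea_center, dd = cfg$dd,
    lesions = cfg$lesions, inventory = inv,
    stage = stage_eye(inv), dme = detect_dme(inv),
    gradable = gradable, vessel_mask = out$vmask,
    eye = cfg$eye, seed = cfg$seed), class = "ground_truth")
  img <- fundus_image(out$px, patient_id = patient_id, eye = cfg$eye,
                      capture = capture)
  list(image = img, truth = truth)
}

render_lesion <- function(ch, cfg, l) {
  b <- lesion_bbox(cfg, l$center, l$radius * (if (l$type == "CWS") 2.2 else 1.6))
  d <- sqrt(b$dx^2 + b$dy^2)
  r <- l$radius
  switch(l$type,
    MA = {  # small dark circular blob, thin soft rim
      wt <- clamp((r + 0.8 - d) / 1.6)
      for (k in 1:3) {
        str <- c(0.35, 0.5, 0.25)[k]
        ch[[k]][b$rows, b$cols] <- ch[[k]][b$rows, b$cols] * (1 - str * wt)
      }
      ch
    },
    HEM = {  # larger irregular dark blob: union of jittered sub-discs
      wt <- matrix(0, nrow(d), ncol(d))
      for (i in 1:4) {
        off <- runif(2, -0.45 * r, 0.45 * r)
        rr <- runif(1, 0.55 * r, 0.85 * r)
        di <- sqrt((b$dx - off[1])^2 + (b$dy - off[2])^2)
        wt <- pmax(wt, clamp((rr + 1 - di) / 2))
      }
      for (k in 1:3) {
        str <- c(0.40, 0.55, 0.30)[k]
        ch[[k]][b$rows, b$cols] <- ch[[k]][b$rows, b$cols] * (1 - str * wt)
      }
      ch
    },
    EX = {  # sharp-edged bright blob
      wt <- 0.9 * (d <= r)
      blend_box(ch, b$rows, b$cols, wt, c(0.98, 0.95, 0.60))
    },
    CWS = {  # soft-edged bright blob
      wt <- 0.75 * exp(-d^2 / (2 * (r / 1.6)^2))
      blend_box(ch, b$rows, b$cols, wt, c(0.92, 0.92, 0.82))
    })
}

#' Sample a lesion layout consistent with an intended ICDR stage
#'
#' Draws lesion positions inside the field, away from the optic disc, the
#' vessel tree of the same configuration/seed, and each other. Stage
#' conventions: MILD places microaneurysms only; MOD adds hemorrhages and
#' possibly bright lesions; SEV additionally places hemorrhages in all four
#' quadrants (the hemorrhage arm of the 4-2-1 rule); PROL is SEV plus the
#' neovascularization annotation flag. With `dme = TRUE` one exudate is
#' placed within 1 disc-diameter of the fovea, otherwise bright lesions stay
#' beyond 1.2 dd.
#'
#' @param config a [synth_image_config()]; its seed drives the sampling.
#' @param stage intended stage, one of `"NODR"`, `"MILD"`, `"MOD"`, `"SEV"`,
#'   `"PROL"`.
#' @param dme whether to force a macular (DME-defining) exudate.
#' @return a new `synth_image_config` with `lesions` (and flags) filled in.
#' @export
sample_lesions <- function(config, stage = "MILD", dme = FALSE) {
  stage <- match.arg(stage, stage_levels())
  cfg <- config
  if (stage == "NODR") {
    cfg$lesions <- list()
    return(validate_synth_config(cfg))
  }
  # the renderer grows its tree at the start of the cfg$seed stream; replay
  # it identically so placements avoid the vessels that will be drawn
  vmask <- with_seed(cfg$seed, grow_vessel_tree(cfg))
  with_seed(child_seed(cfg$seed, 7L), {
    # distance from each pixel to the nearest vessel pixel
    vdist <- as_mat(EBImage::distmap((1 - vmask) * 1))
    placed <- list()
    ok_spot <- function(p, r, min_fov = 0.45, max_fov = Inf) {
      # stay clear of the rim guard band of the bright-lesion detector
      if (pt_dist(p, cfg$field_center) + r > cfg$field_radius - 26) return(FALSE)
      if (pt_dist(p, cfg$disc_center) < cfg$disc_radius + 0.6 * cfg$dd) return(FALSE)
      rf <- pt_dist(p, cfg$fovea_center) / cfg$dd
      if (rf < min_fov || rf > max_fov) return(FALSE)
      if (vdist[round(p[2]), round(p[1])] < r + 0.1 * cfg$dd) return(FALSE)
      for (q in placed)
        if (pt_dist(p, q$center) < (r + q$radius + 0.1 * cfg$dd)) return(FALSE)
      TRUE
    }
    draw_spot <- function(r, min_fov = 0.45, max_fov = Inf, quadrant = NULL) {
      for (i in 1:1500) {
        p <- cfg$field_center +
          runif(1, 0, cfg$field_radius - r - 26) *
          c(cos(a <- runif(1, 0, 2 * pi)), sin(a))
        if (!is.null(quadrant) &&
            !(lesion_quadrant(p, cfg$fovea_center, cfg$disc_center) %in% quadrant))
          next
        if (ok_spot(p, r, min_fov, max_fov)) return(p)
      }
      NULL
    }
    # lesion radii scale with the disc diameter so layouts remain feasible
    # at any raster size (at the default geometry dd = 120 px)
    add <- function(type, n, rmin_dd, rmax_dd, min_fov = 0.45, max_fov = Inf,
                    quadrant = NULL) {
      for (i in seq_len(n)) {
        r <- runif(1, rmin_dd, rmax_dd) * cfg$dd
        p <- draw_spot(r, min_fov, max_fov, quadrant)
        if (!is.null(p)) placed[[length(placed) + 1]] <<-
            lesion_spec(type, p, r)
      }
    }
    if (stage == "MILD") {
      add("MA", sample(2:6, 1), 0.0183, 0.0333)
    } else {
      add("MA", sample(3:8, 1), 0.0183, 0.0333)
      if (stage %in% c("SEV", "PROL")) {
        for (q in 1:4) add("HEM", 1, 0.0667, 0.1167, quadrant = q)
        add("HEM", sample(2:4, 1), 0.0583, 0.1167)
      } else {
        # moderate eyes keep hemorrhages out of one quadrant so the
        # 4-quadrant severe criterion is never met by accident
        add("HEM", sample(2:5, 1), 0.0583, 0.1167, quadrant = sample(1:4, 3))
      }
      if (dme) add("EX", 1, 0.0417, 0.075, min_fov = 0.45, max_fov = 0.85)
      add("EX", sample(1:3, 1), 0.0417, 0.0833, min_fov = 1.3)
      add("CWS", sample(0:2, 1), 0.075, 0.1083, min_fov = 1.3)
    }
    cfg$lesions <- placed
    if (stage == "PROL") cfg$neovascularization <- TRUE
  })
  validate_synth_config(cfg)
  cfg
}
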