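test_that("placed lesions are recovered with correct types", {
  tot <- c(hits = 0, type_ok = 0, n = 0)
  for (s in 1:5) {
    cfg <- sample_lesions(synth_image_config(seed = s), "MOD",
                          dme = s %% 2 == 0)
    res <- generate_eye_image(cfg)
    an <- analyze_image(res$image)
    tot <- tot + match_lesions(res$truth$lesions, an$lesions)
  }
  expect_gte(tot["hits"] / tot["n"], 0.8)
  expect_gte(tot["type_ok"] / tot["hits"], 0.8)
})

test_that("lesion-free images stay within the false-positive budget", {
  for (s in 101:105) {
    res <- generate_eye_image(synth_image_config(seed = s))
    an <- analyze_image(res$image)
    expect_lte(length(an$lesions), 2)
  }
})

test_that("a dark blob fused with the vessel tree is not reported", {
  res <- generate_eye_image(synth_image_config(seed = 6))
  tm <- res$truth$vessel_mask
  # deepest interior vessel pixel, away from disc and fovea
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(tm * 1)))
  g <- fundusdr:::coord_grid(600, 600)
  ddisc <- sqrt((g$x - res$truth$disc_center[1])^2 +
                (g$y - res$truth$disc_center[2])^2)
  cand <- which(dm >= 3 & ddisc > 1.2 * res$truth$dd)
  px <- cand[which.max(dm[cand])]
  ctr <- c(g$x[px], g$y[px])
  pix <- res$image$pixels
  blob <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 <= 9
  for (k in 1:3) { m <- pix[, , k]; m[blob] <- m[blob] * 0.5; pix[, , k] <- m }
  an <- analyze_image(fundus_image(pix))
  near <- vapply(an$lesions, function(l)
    sqrt(sum((l$centroid - ctr)^2)) < 8, TRUE)
  expect_false(any(near))
})

test_that("the optic disc is never reported as a bright lesion", {
  cfg <- sample_lesions(synth_image_config(seed = 7), "MOD", dme = TRUE)
  res <- generate_eye_image(cfg)
  an <- analyze_image(res$image)
  bright <- Filter(function(l) l$type %in% c("EX", "CWS"), an$lesions)
  expect_gt(length(bright), 0)
  for (l in bright)
    expect_gt(sqrt(sum((l$centroid - res$truth$disc_center)^2)),
              res$truth$disc_radius)
})

test_that("lesions are still detected on ungradable images", {
  cfg <- sample_lesions(synth_image_config(seed = 8), "MOD")
  cfg$blur_sigma <- 4   # the generator failure level; lesions remain visible
  res <- generate_eye_image(cfg)
  an <- analyze_image(res$image)
  expect_false(an$quality$gradable)
  expect_gt(length(an$lesions), 0)
})

test_that("adding an unsaturating constant does not change lesion counts", {
  cfg <- sample_lesions(synth_image_config(seed = 9), "MOD")
  res <- generate_eye_image(cfg)
  an0 <- analyze_image(res$image)
  shifted <- fundus_image(pmax(res$image$pixels - 0.04, 0))
  an1 <- analyze_image(shifted)
  expect_equal(length(an1$lesions), length(an0$lesions))
})
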