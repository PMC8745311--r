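test_that("crisp renders pass and degraded renders fail the quality gate", {
  for (s in 1:3) {
    crisp <- generate_eye_image(synth_image_config(seed = s))
    expect_true(assess_quality(crisp$image)$gradable)
  }
  for (sigma in c(4, 5, 8)) {
    blurred <- generate_eye_image(synth_image_config(seed = 1,
                                                     blur_sigma = sigma))
    q <- assess_quality(blurred$image)
    expect_false(q$gradable)
    expect_true("blur" %in% q$reasons)
  }
  for (sigma in c(0, 2, 3.5)) {
    ok <- generate_eye_image(synth_image_config(seed = 1, blur_sigma = sigma))
    expect_true(assess_quality(ok$image)$gradable)
  }
})

test_that("a black image is flagged underexposed", {
  img <- fundus_image(array(0, c(300, 300, 3)))
  q <- assess_quality(img)
  expect_false(q$gradable)
  expect_identical(q$reasons, "underexposed")
})

test_that("underexposure and vignetting fail on their own metrics", {
  dim1 <- generate_eye_image(synth_image_config(seed = 2, exposure_scale = 0.3))
  q1 <- assess_quality(dim1$image)
  expect_false(q1$gradable)
  expect_true("underexposed" %in% q1$reasons)
  expect_false(dim1$truth$gradable)

  vig <- generate_eye_image(synth_image_config(seed = 2,
                                               vignette_strength = 0.9))
  expect_false(assess_quality(vig$image)$gradable)
  expect_false(vig$truth$gradable)
})

test_that("a saturated field is flagged", {
  px <- array(0.02, c(300, 300, 3))
  fieldpx <- outer(1:300, 1:300,
                   function(y, x) (x - 150)^2 + (y - 150)^2 <= 120^2)
  for (k in 1:3) { m <- px[, , k]; m[fieldpx] <- 1; px[, , k] <- m }
  q <- assess_quality(fundus_image(px))
  expect_true("saturated" %in% q$reasons)
  expect_false(q$gradable)
})

test_that("tiny rasters are refused", {
  expect_error(assess_quality(fundus_image(array(0.5, c(32, 32, 3)))),
               "too small")
})
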