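test_that("rendering is byte-identical for a fixed seed", {
  cfg <- small_config(seed = 1)
  a <- generate_eye_image(cfg)
  b <- generate_eye_image(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
})

test_that("a lesion-free, undegraded render has clean ground truth", {
  res <- generate_eye_image(small_config(seed = 2))
  expect_length(res$truth$lesions, 0)
  expect_true(res$truth$gradable)
  expect_identical(res$truth$stage, "NODR")
  expect_false(res$truth$dme)
})

test_that("heavy degradation is marked ungradable and fails the sharpness gate", {
  res <- generate_eye_image(synth_image_config(seed = 3, blur_sigma = 8,
                                               exposure_scale = 0.3))
  expect_false(res$truth$gradable)
  q <- assess_quality(res$image)
  expect_lt(q$sharpness, default_params()$quality$sharpness_min)
  expect_false(q$gradable)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_image_config(vignette_strength = 1.5), "vignette")
  expect_error(synth_image_config(
    lesions = list(lesion_spec("MA", c(5, 5), 3))), "outside the field")
  expect_error(synth_image_config(
    lesions = list(lesion_spec("EX", c(300, 300), 0))), "positive")
  expect_error(synth_image_config(fovea_offset_dd = 0.3), "overlap")
  expect_error(lesion_spec("XYZ", c(1, 1), 2))
})

test_that("sampled lesion layouts reproduce the intended stage and DME state", {
  for (seed in 1:3) {
    for (stage in c("NODR", "MILD", "MOD", "SEV", "PROL")) {
      cfg <- sample_lesions(small_config(seed = seed), stage,
                            dme = stage %in% c("MOD", "SEV"))
      res <- generate_eye_image(cfg)
      expect_identical(res$truth$stage, stage)
      expect_identical(stage_eye(res$truth$inventory), stage)
      expect_identical(res$truth$dme, stage %in% c("MOD", "SEV"))
    }
  }
})

test_that("repeat captures share geometry but differ in noise", {
  cfg <- small_config(seed = 4)
  a <- generate_eye_image(cfg)
  cfg$noise_seed <- 999L
  b <- generate_eye_image(cfg)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  expect_false(identical(a$image$pixels, b$image$pixels))
})

test_that("left-eye geometry mirrors the right eye", {
  od <- synth_image_config(seed = 1, eye = "OD")
  os <- synth_image_config(seed = 1, eye = "OS")
  expect_gt(od$disc_center[1], od$fovea_center[1])
  expect_lt(os$disc_center[1], os$fovea_center[1])
  expect_equal(od$disc_center[1] - od$width / 2,
               od$width / 2 - os$disc_center[1])
})
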