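test_that("image-level status follows the lesion-overrides-quality rule", {
  expect_identical(grade_image(fake_analysis(TRUE)), "NODR")
  expect_identical(grade_image(fake_analysis(FALSE)), "UNG")
  expect_identical(
    grade_image(fake_analysis(FALSE, list(fake_candidate("HEM")))), "DR")
  expect_identical(
    grade_image(fake_analysis(TRUE, list(fake_candidate("MA")))), "DR")
})

test_that("staging matches an independent rule-table oracle on all boundary inventories", {
  # independent formulation: maximum severity over the triggered criteria
  oracle <- function(inv) {
    lvl <- 1L
    if (inv$ma > 0) lvl <- max(lvl, 2L)
    if (inv$hem + inv$ex + inv$cws + inv$venous_beading_quadrants > 0)
      lvl <- max(lvl, 3L)
    if (inv$hemorrhage_quadrants == 4 || inv$venous_beading_quadrants >= 2 ||
        inv$irma_quadrants >= 1) lvl <- max(lvl, 4L)
    if (inv$neovascularization) lvl <- max(lvl, 5L)
    c("NODR", "MILD", "MOD", "SEV", "PROL")[lvl]
  }
  grid <- expand.grid(ma = c(0, 1, 5), hem = c(0, 1, 12), ex = 0:1,
                      cws = 0:1, hq = c(0, 3, 4), vb = 0:2, irma = 0:1,
                      nv = c(FALSE, TRUE))
  grid <- grid[!(grid$hq > 0 & grid$hem == 0), ]
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    inv <- lesion_inventory(ma = gi$ma, hem = gi$hem, ex = gi$ex,
                            cws = gi$cws, hemorrhage_quadrants = gi$hq,
                            venous_beading_quadrants = gi$vb,
                            irma_quadrants = gi$irma,
                            neovascularization = gi$nv)
    expect_identical(stage_eye(inv), oracle(inv))
  }
})

test_that("specific staging examples", {
  expect_identical(stage_eye(lesion_inventory(ma = 3)), "MILD")
  expect_identical(stage_eye(lesion_inventory()), "NODR")
  expect_identical(stage_eye(lesion_inventory(ma = 5, hem = 12,
                                              hemorrhage_quadrants = 4)),
                   "SEV")
})

test_that("adding lesions never lowers the stage", {
  ranks <- function(st) match(st, c("NODR", "MILD", "MOD", "SEV", "PROL"))
  set.seed(42)
  for (i in 1:200) {
    base <- list(ma = rpois(1, 2), hem = rpois(1, 1), ex = rpois(1, 1),
                 cws = rpois(1, 0.5), hq = sample(0:4, 1),
                 vb = sample(0:4, 1), irma = sample(0:4, 1),
                 nv = runif(1) < 0.2)
    if (base$hq > 0 && base$hem == 0) base$hem <- 1
    mk <- function(b) lesion_inventory(b$ma, b$hem, b$ex, b$cws, b$hq, b$vb,
                                       b$irma, b$nv)
    more <- base
    fld <- sample(c("ma", "hem", "ex", "cws"), 1)
    more[[fld]] <- more[[fld]] + sample(1:3, 1)
    expect_gte(ranks(stage_eye(mk(more))), ranks(stage_eye(mk(base))))
  }
})

test_that("macular edema requires a bright lesion within one disc-diameter", {
  expect_true(detect_dme(lesion_inventory(ex = 1,
    bright_lesion_min_distance_to_fovea = 0.5)))
  expect_false(detect_dme(lesion_inventory(ex = 1,
    bright_lesion_min_distance_to_fovea = 3.0)))
  expect_false(detect_dme(lesion_inventory(ma = 4)))
})

test_that("eye grading merges captures and applies the quality override", {
  nodr <- fake_analysis(TRUE)
  ung <- fake_analysis(FALSE)
  mild <- fake_analysis(FALSE, list(fake_candidate("MA", 1.2, 0.3)))

  expect_identical(grade_eye(list(nodr, nodr, nodr))$status, "NODR")
  g <- grade_eye(list(ung, ung, mild))
  expect_identical(g$status, "DR")
  expect_identical(g$stage, "MILD")
  expect_identical(grade_eye(list(ung, ung, ung))$status, "UNG")
  expect_error(grade_eye(list()), "at least one")
})

test_that("duplicate candidates across captures are merged once", {
  a <- fake_analysis(TRUE, list(fake_candidate("MA", 1.00, 0.50)))
  b <- fake_analysis(TRUE, list(fake_candidate("MA", 1.05, 0.52),
                                fake_candidate("HEM", -1, -1)))
  g <- grade_eye(list(a, b))
  expect_equal(g$inventory$ma, 1L)
  expect_equal(g$inventory$hem, 1L)
})

test_that("patient aggregation follows worst-eye and precedence rules", {
  nodr <- eye_grade("NODR")
  ung <- eye_grade("UNG")
  mild <- eye_grade("DR", "MILD")
  mod_dme <- eye_grade("DR", "MOD", dme = TRUE)

  p <- aggregate_patient(nodr, mod_dme)
  expect_identical(p$status, "DR")
  expect_identical(p$stage, "MOD")
  expect_true(p$dme); expect_true(p$stdr)

  expect_identical(aggregate_patient(ung, nodr)$status, "UNG")
  expect_identical(aggregate_patient(mild, eye_grade("DR", "MOD"))$stage, "MOD")
  p0 <- aggregate_patient(nodr, nodr)
  expect_identical(p0$status, "NODR"); expect_false(p0$stdr)

  # precedence between a DR eye and an UNG eye is switchable
  expect_identical(aggregate_patient(ung, mild)$status, "DR")
  expect_identical(aggregate_patient(ung, mild,
                                     ung_precedence = "ung_over_dr")$status,
                   "UNG")
})

test_that("aggregation is symmetric and total over all status pairs", {
  eyes <- list(UNG = eye_grade("UNG"), NODR = eye_grade("NODR"),
               DR = eye_grade("DR", "MILD"))
  expected <- matrix(c("DR", "DR", "DR",
                       "DR", "NODR", "UNG",
                       "DR", "UNG", "UNG"), 3, 3, byrow = TRUE,
                     dimnames = list(c("DR", "NODR", "UNG"),
                                     c("DR", "NODR", "UNG")))
  for (a in names(eyes)) for (b in names(eyes)) {
    ab <- aggregate_patient(eyes[[a]], eyes[[b]])
    ba <- aggregate_patient(eyes[[b]], eyes[[a]])
    expect_identical(ab$status, expected[a, b])
    expect_identical(ab$status, ba$status)
    expect_identical(ab$stage, ba$stage)
  }
  # severe or proliferative stages imply sight-threatening disease
  expect_true(aggregate_patient(eye_grade("DR", "SEV"), nodr <- eye_grade("NODR"))$stdr)
  expect_true(aggregate_patient(eye_grade("DR", "PROL"), nodr)$stdr)
})
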