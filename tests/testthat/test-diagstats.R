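# Rebuild aligned diagnosis vectors from a 3x3 counts matrix.
expand_table <- function(m) {
  lv <- c("DR", "NODR", "UNG")
  test <- character(); ref <- character()
  for (i in 1:3) for (j in 1:3) {
    test <- c(test, rep(lv[i], m[i, j]))
    ref <- c(ref, rep(lv[j], m[i, j]))
  }
  list(test = test, ref = ref)
}

test_that("cross-tabulation reproduces the bundled study tables exactly", {
  tabs <- screening_tables()
  for (nm in c("alg_oph", "pcp_oph")) {
    v <- expand_table(tabs[[nm]])
    rebuilt <- crosstab_raters(v$test, v$ref)
    expect_equal(unclass(rebuilt)[, ], unclass(tabs[[nm]])[, ])
  }
  expect_equal(tabs$alg_oph["DR", "DR"], 455L)
  expect_equal(tabs$pcp_oph["NODR", "DR"], 214L)
})

test_that("identical raters give a diagonal cross-tab; bad input errors", {
  x <- c("DR", "NODR", "UNG", "DR")
  tab <- crosstab_raters(x, x)
  expect_equal(sum(tab) - sum(diag(unclass(tab))), 0L)
  expect_error(crosstab_raters(c("DR"), c("DR", "NODR")), "length")
  expect_error(crosstab_raters(c("MAYBE"), c("DR")), "unknown")
})

test_that("gradability collapse preserves totals and matches derived sums", {
  tabs <- screening_tables()
  g4 <- collapse_gradability(tabs$alg_oph)
  expect_equal(as.vector(t(g4)), c(2496, 97, 617, 310))
  g5 <- collapse_gradability(tabs$pcp_oph)
  expect_equal(as.vector(t(g5)), c(2825, 234, 288, 173))
  expect_equal(sum(g4), sum(tabs$alg_oph))
  all_grad <- crosstab_raters(c("DR", "NODR"), c("NODR", "DR"))
  gg <- collapse_gradability(all_grad)
  expect_equal(sum(gg["UNG", ]) + sum(gg[, "UNG"]), 0)
})

test_that("pairwise-gradable 2x2 reduction matches the study counts", {
  tabs <- screening_tables()
  t4 <- to_2x2(tabs$alg_oph)
  expect_equal(unlist(t4[c("tp", "fp", "fn", "tn")]),
               c(tp = 455L, fp = 379L, fn = 80L, tn = 1582L))
  t5 <- to_2x2(tabs$pcp_oph)
  expect_equal(unlist(t5[c("tp", "fp", "fn", "tn")]),
               c(tp = 373L, fp = 233L, fn = 214L, tn = 2005L))
  diag_only <- crosstab_raters(c("DR", "NODR"), c("DR", "NODR"))
  td <- to_2x2(diag_only)
  expect_equal(td$fp + td$fn, 0L)
  ung_only <- crosstab_raters(c("UNG", "UNG"), c("UNG", "DR"))
  expect_error(to_2x2(ung_only), "no patients")
})

test_that("perfect and degenerate accuracy tables behave", {
  acc <- diagnostic_accuracy(contingency_2x2(7, 0, 0, 13))
  expect_equal(acc$sensitivity$est, 1)
  expect_equal(acc$specificity$est, 1)
  expect_equal(acc$ppv$est, 1)
  expect_equal(acc$npv$est, 1)
  no_pos <- diagnostic_accuracy(contingency_2x2(0, 5, 0, 15))
  expect_true(is.na(no_pos$sensitivity$est))
  expect_false(is.na(no_pos$specificity$est))
})

test_that("Bayes and likelihood-ratio identities hold on random tables", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rmultinom(1, 400, runif(4, 0.05, 1))
    t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    acc <- diagnostic_accuracy(t)
    se <- acc$sensitivity$est; sp <- acc$specificity$est
    prev <- acc$prevalence$est
    ppv_bayes <- se * prev / (se * prev + (1 - sp) * (1 - prev))
    npv_bayes <- sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev)
    expect_equal(acc$ppv$est, ppv_bayes, tolerance = 1e-12)
    expect_equal(acc$npv$est, npv_bayes, tolerance = 1e-12)
    expect_equal(acc$lr_pos$est * (1 - sp), se, tolerance = 1e-12)
    expect_equal(acc$lr_neg$est * sp, 1 - se, tolerance = 1e-12)
    # the Fagan update at the table's own prevalence equals the PPV
    expect_equal(fagan_posttest(prev, acc$lr_pos$est)$posttest, acc$ppv$est,
                 tolerance = 1e-12)
  }
})

test_that("kappa matches a first-principles oracle on all small 2x2 tables", {
  oracle_kappa <- function(a, b) {
    po <- mean(a == b)
    pe <- sum(vapply(unique(c(a, b)), function(k)
      mean(a == k) * mean(b == k), 0))
    (po - pe) / (1 - pe)
  }
  for (tp in 0:4) for (fp in 0:4) for (fn in 0:4) for (tn in 0:4) {
    n <- tp + fp + fn + tn
    if (n == 0) next
    a <- c(rep("P", tp + fp), rep("N", fn + tn))
    b <- c(rep("P", tp), rep("N", fp), rep("P", fn), rep("N", tn))
    pe_check <- sum(vapply(c("P", "N"), function(k)
      mean(a == k) * mean(b == k), 0))
    if (1 - pe_check < 1e-12) {
      expect_error(cohen_kappa(matrix(c(tp, fn, fp, tn), 2, 2)), "degenerate")
    } else {
      k <- cohen_kappa(matrix(c(tp, fn, fp, tn), 2, 2))
      expect_equal(k$kappa, oracle_kappa(a, b), tolerance = 1e-12)
      expect_lte(k$kappa, k$p_o + 1e-12)
    }
  }
})

test_that("kappa special values and invariances", {
  perf <- matrix(c(30, 0, 0, 70), 2, 2)
  expect_equal(cohen_kappa(perf)$kappa, 1)
  indep <- outer(c(20, 80), c(30, 70)) / 100  # counts = marginal products
  expect_equal(cohen_kappa(indep)$kappa, 0)
  m <- matrix(c(40, 10, 5, 45), 2, 2)
  perm <- m[2:1, 2:1]
  expect_equal(cohen_kappa(m)$kappa, cohen_kappa(perm)$kappa)
})

test_that("kappa homogeneity is zero for identical inputs and errors on zero variance", {
  k1 <- cohen_kappa(matrix(c(40, 10, 5, 45), 2, 2))
  h <- kappa_homogeneity(k1, k1)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  expect_equal(h$df, 1L)
  k0 <- k1; k0$se <- 0
  expect_error(kappa_homogeneity(k0, k1), "zero")
})

test_that("single-point AUC and its degenerate values", {
  expect_equal(single_point_auc(1, 1)$auc, 1)
  expect_equal(single_point_auc(0.3, 0.7)$auc, 0.5)  # se = 1 - sp
  a <- single_point_auc(0.9, 0.8, 100, 300)
  b <- single_point_auc(0.7, 0.8, 120, 280)
  cmp <- compare_auc(a, b)
  expect_gt(cmp$z, 0)
  expect_lt(cmp$p, 1)
  expect_equal(cmp$p, 2 * pnorm(-abs(cmp$z)), tolerance = 1e-12)
  expect_error(compare_auc(single_point_auc(0.9, 0.8), b), "variances")
})

test_that("Fagan post-test probability follows the odds identity", {
  expect_equal(fagan_posttest(0.37, 1)$posttest, 0.37)
  p <- fagan_posttest(0.2, 5)
  expect_equal(p$posttest, 5 * 0.25 / (1 + 5 * 0.25), tolerance = 1e-12)
  expect_error(fagan_posttest(0, 2), "pretest")
  expect_error(fagan_posttest(0.5, -1), "positive")
})

test_that("two-proportion z-test matches the pooled formula and edge cases", {
  x1 <- 50; n1 <- 400; x2 <- 70; n2 <- 450
  r <- two_proportion_test(x1, n1, x2, n2)
  pp <- (x1 + x2) / (n1 + n2)
  z_manual <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(r$z, z_manual, tolerance = 1e-10)
  expect_equal(r$p, 2 * pnorm(-abs(z_manual)), tolerance = 1e-10)
  eq <- two_proportion_test(30, 100, 30, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(two_proportion_test(5, 0, 1, 10), "positive")
})

test_that("two-proportion test holds its nominal size under the null", {
  set.seed(31)
  nrep <- 2000
  x <- rbinom(nrep, 300, 0.15); y <- rbinom(nrep, 300, 0.15)
  p <- vapply(seq_len(nrep), function(i)
    two_proportion_test(x[i], 300, y[i], 300)$p, 0)
  band <- binom_band(nrep, 0.05)
  expect_gte(sum(p < 0.05), band[1])
  expect_lte(sum(p < 0.05), band[2])
})

test_that("the validation report of a rater against itself is perfect", {
  calls <- c(rep("DR", 30), rep("NODR", 60), rep("UNG", 10))
  rep <- validation_report(calls, calls)
  expect_equal(rep$accuracy$sensitivity$est, 1)
  expect_equal(rep$accuracy$specificity$est, 1)
  expect_equal(rep$kappa_dr$kappa, 1)
  expect_equal(rep$kappa_gradability$kappa, 1)
})

test_that("the report end-to-end reproduces the study's headline numbers", {
  tabs <- screening_tables()
  v <- expand_table(tabs$alg_oph)
  rep <- validation_report(v$test, v$ref, c(test = "ALG", reference = "OPH"))
  expect_equal(unclass(rep$table)["DR", "DR"], 455L)
  expect_equal(round(100 * rep$accuracy$sensitivity$est, 2), 85.05)
  expect_equal(round(rep$kappa_dr$kappa, 4), 0.5462)
  expect_equal(round(rep$kappa_gradability$kappa, 4), 0.3623)
  expect_equal(round(rep$auc$auc, 4), 0.8286)
  expect_equal(round(100 * rep$fagan_positive$posttest), 55)
})
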