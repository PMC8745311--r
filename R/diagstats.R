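#' Cross-tabulate two raters' diagnoses
#'
#' Builds the 3x3 table of patient counts with rows the test rater and
#' columns the reference rater, in the fixed label order `DR, NODR, UNG`.
#'
#' @param test,reference equal-length character vectors of diagnoses.
#' @param labels `c(test =, reference =)` rater names.
#' @return object of class `rater_table` (a labelled 3x3 integer matrix).
#' @export
crosstab_raters <- function(test, reference,
                            labels = c(test = "test", reference = "reference")) {
  if (length(test) != length(reference))
    stop("diagnosis lists differ in length")
  bad <- setdiff(unique(c(test, reference)), diag_levels())
  if (length(bad)) stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(test, diag_levels()), factor(reference, diag_levels()))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(test = diag_levels(), reference = diag_levels()))
  structure(m, class = c("rater_table", "matrix"), labels = labels)
}

#' Construct a rater table from counts
#'
#' @param counts 3x3 matrix of non-negative counts, rows = test rater,
#'   columns = reference rater, both ordered `DR, NODR, UNG`.
#' @inheritParams crosstab_raters
#' @return a `rater_table`.
#' @export
rater_table <- function(counts, labels = c(test = "test", reference = "reference")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) || sum(counts) == 0)
    stop("counts must be a non-negative 3x3 matrix with positive total")
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(test = diag_levels(), reference = diag_levels()))
  structure(m, class = c("rater_table", "matrix"), labels = labels)
}

#' Collapse a rater table to gradable vs ungradable
#'
#' `GRAD` pools the `DR` and `NODR` calls of each rater; the four cells sum
#' to the original total.
#'
#' @param t a [rater_table()].
#' @return 2x2 integer matrix with dimnames `GRAD, UNG`.
#' @export
collapse_gradability <- function(t) {
  stopifnot(inherits(t, "rater_table"))
  m <- matrix(c(sum(t[1:2, 1:2]), sum(t[1:2, 3]),
                sum(t[3, 1:2]), t[3, 3]),
              2, 2, byrow = TRUE,
              dimnames = list(test = c("GRAD", "UNG"),
                              reference = c("GRAD", "UNG")))
  m
}

#' Reduce a rater table to the 2x2 DR/NODR contingency table
#'
#' Drops every patient called `UNG` by either rater (the pairwise gradable
#' restriction) and counts the remaining pairs with the reference `DR`
#' column as the positive class.
#'
#' @param t a [rater_table()].
#' @return a [contingency_2x2()].
#' @export
to_2x2 <- function(t) {
  stopifnot(inherits(t, "rater_table"))
  if (sum(t[1:2, 1:2]) == 0) stop("no patients remain after UNG exclusion")
  contingency_2x2(tp = t["DR", "DR"], fp = t["DR", "NODR"],
                  fn = t["NODR", "DR"], tn = t["NODR", "NODR"])
}

#' 2x2 diagnostic contingency table
#'
#' @param tp,fp,fn,tn non-negative counts (true/false positive/negative,
#'   with the reference standard defining positivity).
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with positive total")
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "contingency_2x2")
}

# Wald proportion CI with continuity correction: p +/- (z*SE + 1/(2n)).
prop_ci_wald_cc <- function(x, n, alpha = 0.05) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  z <- qnorm(1 - alpha / 2)
  half <- z * sqrt(p * (1 - p) / n) + 1 / (2 * n)
  c(max(0, p - half), min(1, p + half))
}

# Log-method (Simel) CI for a likelihood ratio.
lr_ci_log <- function(lr, a, m, b, k, alpha = 0.05) {
  # lr = (a/m) / (b/k); var(log lr) = 1/a - 1/m + 1/b - 1/k
  if (any(c(a, b) == 0) || !is.finite(lr) || lr <= 0)
    return(c(NA_real_, NA_real_))
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(1 / a - 1 / m + 1 / b - 1 / k)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic accuracy indexes with confidence intervals
#'
#' Sensitivity, specificity, predictive values, prevalence (Wald intervals
#' with continuity correction) and likelihood ratios (log-method intervals)
#' from a 2x2 table. Indexes with a zero denominator are reported as `NA`
#' rather than thrown.
#'
#' @param t a [contingency_2x2()].
#' @param alpha significance level for the `1 - alpha` intervals.
#' @return object of class `diagnostic_accuracy`; each index is a list with
#'   `est` and `ci`.
#' @export
diagnostic_accuracy <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "contingency_2x2"))
  tp <- t$tp; fp <- t$fp; fn <- t$fn; tn <- t$tn
  n <- tp + fp + fn + tn
  npos <- tp + fn; nneg <- fp + tn
  idx <- function(x, d) if (d > 0) x / d else NA_real_
  se <- idx(tp, npos); sp <- idx(tn, nneg)
  ppv <- idx(tp, tp + fp); npv <- idx(tn, fn + tn)
  prev <- idx(npos, n)
  lr_pos <- if (!is.na(se) && !is.na(sp) && sp < 1) se / (1 - sp) else NA_real_
  lr_neg <- if (!is.na(se) && !is.na(sp) && sp > 0) (1 - se) / sp else NA_real_
  wrap <- function(est, x, d) list(est = est, ci = if (d > 0)
    prop_ci_wald_cc(x, d, alpha) else c(NA_real_, NA_real_))
  structure(list(
    table = t, n = n, alpha = alpha,
    prevalence = wrap(prev, npos, n),
    sensitivity = wrap(se, tp, npos),
    specificity = wrap(sp, tn, nneg),
    ppv = wrap(ppv, tp, tp + fp),
    npv = wrap(npv, tn, fn + tn),
    lr_pos = list(est = lr_pos, ci = lr_ci_log(lr_pos, tp, npos, fp, nneg, alpha)),
    lr_neg = list(est = lr_neg, ci = lr_ci_log(lr_neg, fn, npos, tn, nneg, alpha))),
    class = "diagnostic_accuracy")
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  fmt_pct <- function(v) sprintf("%.2f%% (%.2f-%.2f)", 100 * v$est,
                                 100 * v$ci[1], 100 * v$ci[2])
  fmt_lr <- function(v) sprintf("%.2f (%.2f-%.2f)", v$est, v$ci[1], v$ci[2])
  t <- x$table
  cat(sprintf("Diagnostic validity (n = %d)\n", x$n))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", t$tp, t$fp, t$fn, t$tn))
  cat("  Prevalence                ", fmt_pct(x$prevalence), "\n")
  cat("  Sensitivity               ", fmt_pct(x$sensitivity), "\n")
  cat("  Specificity               ", fmt_pct(x$specificity), "\n")
  cat("  Positive Predictive Value ", fmt_pct(x$ppv), "\n")
  cat("  Negative Predictive Value ", fmt_pct(x$npv), "\n")
  cat("  Likelihood Ratio +        ", fmt_lr(x$lr_pos), "\n")
  cat("  Likelihood Ratio -        ", fmt_lr(x$lr_neg), "\n")
  invisible(x)
}

#' Cohen's kappa with large-sample standard error
#'
#' Unweighted kappa for a square agreement table: observed agreement `p_o`
#' (diagonal share), chance agreement `p_e` (product of marginals), kappa
#' `(p_o - p_e) / (1 - p_e)`, with the Fleiss-Cohen-Everitt large-sample
#' variance and a normal-approximation interval.
#'
#' @param table square matrix of counts (e.g. a [rater_table()] or a
#'   [collapse_gradability()] result).
#' @param alpha significance level.
#' @return object of class `agreement_result` with `kappa`, `p_o`, `p_e`,
#'   `se`, `ci`, `n`.
#' @export
cohen_kappa <- function(table, alpha = 0.05) {
  m <- unclass(as.matrix(table))
  if (nrow(m) != ncol(m)) stop("agreement table must be square")
  n <- sum(m)
  if (n == 0) stop("empty table")
  p <- m / n
  po <- sum(diag(p))
  prow <- rowSums(p); pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (1 - pe < 1e-12) stop("degenerate marginals: kappa undefined (p_e = 1)")
  k <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  t1 <- sum(diag(p) * (1 - (prow + pcol) * (1 - k))^2)
  t2 <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (i != j) t2 <- t2 + p[i, j] * (pcol[i] + prow[j])^2
  t2 <- t2 * (1 - k)^2
  t3 <- (k - pe * (1 - k))^2
  var_k <- (t1 + t2 - t3) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- qnorm(1 - alpha / 2)
  structure(list(kappa = k, p_o = po, p_e = pe, se = se,
                 ci = c(k - z * se, min(1, k + z * se)), n = n, alpha = alpha),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%.4f-%.4f), p_o = %.4f, p_e = %.4f, n = %d\n",
              x$kappa, x$ci[1], x$ci[2], x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Kappa homogeneity test
#'
#' Tests whether several independent kappas share a common value: with
#' inverse-variance weights, `chi2 = sum w_i (k_i - k_bar)^2` against a
#' chi-square with one degree of freedom fewer than the number of kappas.
#'
#' @param ... two or more [cohen_kappa()] results (or one list of them).
#' @return list with `chi2`, `df`, `p`, `kappa_common`.
#' @export
kappa_homogeneity <- function(...) {
  ks <- list(...)
  if (length(ks) == 1 && !inherits(ks[[1]], "agreement_result")) ks <- ks[[1]]
  if (length(ks) < 2) stop("need at least two kappas")
  k <- vapply(ks, `[[`, 0, "kappa")
  v <- vapply(ks, `[[`, 0, "se")^2
  if (any(v <= 0)) stop("zero kappa variance: homogeneity test undefined")
  w <- 1 / v
  kbar <- sum(w * k) / sum(w)
  chi2 <- sum(w * (k - kbar)^2)
  df <- length(k) - 1L
  structure(list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
                 kappa_common = kbar),
            class = "kappa_homogeneity")
}

#' @export
print.kappa_homogeneity <- function(x, ...) {
  cat(sprintf("Kappa homogeneity: chi2 = %.4f, df = %d, p = %.4f (common k = %.4f)\n",
              x$chi2, x$df, x$p, x$kappa_common))
  invisible(x)
}

#' Single-operating-point ROC area
#'
#' The area under the two-segment ROC polygon through the single operating
#' point `(1 - sp, se)`, i.e. `(se + sp) / 2`. When the positive and
#' negative sample sizes are supplied, a confidence interval is propagated
#' from the binomial variances of sensitivity and specificity.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param n_pos,n_neg diseased / non-diseased counts behind `se` and `sp`.
#' @param alpha significance level.
#' @return object of class `auc_result` with `auc`, `var`, `ci`.
#' @export
single_point_auc <- function(se, sp, n_pos = NULL, n_neg = NULL, alpha = 0.05) {
  if (is.na(se) || is.na(sp))
    return(structure(list(auc = NA_real_, se_input = se, sp_input = sp,
                          var = NA_real_, ci = c(NA_real_, NA_real_)),
                     class = "auc_result"))
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  auc <- (se + sp) / 2
  v <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (!is.null(n_pos) && !is.null(n_neg) && n_pos > 0 && n_neg > 0) {
    v <- (se * (1 - se) / n_pos + sp * (1 - sp) / n_neg) / 4
    z <- qnorm(1 - alpha / 2)
    ci <- c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
  }
  structure(list(auc = auc, se_input = se, sp_input = sp, var = v, ci = ci),
            class = "auc_result")
}

#' Compare two single-point AUCs
#'
#' Two-sided z-test on the AUC difference using the sum of the propagated
#' variances (independent samples).
#'
#' @param a,b [single_point_auc()] results carrying variances.
#' @return list with `z`, `p`, `diff`.
#' @export
compare_auc <- function(a, b) {
  stopifnot(inherits(a, "auc_result"), inherits(b, "auc_result"))
  if (is.na(a$var) || is.na(b$var))
    stop("both AUCs need variances (supply n_pos/n_neg)")
  z <- (a$auc - b$auc) / sqrt(a$var + b$var)
  list(z = z, p = 2 * pnorm(-abs(z)), diff = a$auc - b$auc)
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f", x$auc))
  if (!is.na(x$var)) cat(sprintf(" (%.4f-%.4f)", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Fagan post-test probability
#'
#' Bayes update on the odds scale: the post-test probability given a
#' pre-test probability and a likelihood ratio.
#'
#' @param pretest pre-test probability, strictly between 0 and 1.
#' @param lr positive likelihood ratio to apply (LR+ for a positive test,
#'   LR- for a negative one).
#' @return list with `pretest`, `lr`, `posttest`.
#' @export
fagan_posttest <- function(pretest, lr) {
  if (pretest <= 0 || pretest >= 1) stop("pretest probability must lie in (0, 1)")
  if (lr <= 0) stop("likelihood ratio must be positive")
  odds <- lr * pretest / (1 - pretest)
  structure(list(pretest = pretest, lr = lr, posttest = odds / (1 + odds)),
            class = "posttest_result")
}

#' @export
print.posttest_result <- function(x, ...) {
  cat(sprintf("Fagan: pretest %.1f%%, LR %.2f -> posttest %.1f%%\n",
              100 * x$pretest, x$lr, 100 * x$posttest))
  invisible(x)
}

#' Two-proportion z-test
#'
#' Pooled-variance z-test for the difference of two independent proportions,
#' two-sided. With `correct = TRUE` the continuity-corrected chi-square
#' (Yates) is used. The p-value is obtained through [stats::prop.test()];
#' the signed z statistic is returned alongside.
#'
#' @param x1,n1,x2,n2 successes and totals of the two samples.
#' @param correct continuity correction flag.
#' @return list with `z`, `p`, `estimate` (the two proportions).
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n")
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = correct))
  z <- sign(x1 / n1 - x2 / n2) * sqrt(unname(ht$statistic))
  list(z = z, p = ht$p.value, estimate = c(p1 = x1 / n1, p2 = x2 / n2))
}
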