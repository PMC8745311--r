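#' Full validation report for one test rater against a reference
#'
#' Reproduces the complete validation battery from aligned per-patient
#' diagnosis lists: the 3x3 rater cross-tabulation, the gradable/ungradable
#' collapse with its kappa, the pairwise-gradable 2x2 accuracy block
#' (sensitivity, specificity, predictive values, likelihood ratios with
#' intervals), the DR/NODR kappa, the single-point ROC AUC, and the Fagan
#' post-test probabilities at the sample's own prevalence.
#'
#' @param test,reference equal-length diagnosis vectors in `DR, NODR, UNG`,
#'   aligned by patient.
#' @param labels `c(test =, reference =)` rater names.
#' @param alpha significance level.
#' @return object of class `validation_report`.
#' @export
validation_report <- function(test, reference,
                              labels = c(test = "test", reference = "reference"),
                              alpha = 0.05) {
  tab <- crosstab_raters(test, reference, labels)
  report_from_table(tab, alpha)
}

#' Validation report from an existing rater table
#'
#' @param tab a [rater_table()].
#' @param alpha significance level.
#' @return a `validation_report`.
#' @export
report_from_table <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "rater_table"))
  grad <- collapse_gradability(tab)
  # one-sided tables (e.g. no UNG call at all) leave kappa undefined; the
  # report carries NA for that block instead of failing
  safe_kappa <- function(m) tryCatch(cohen_kappa(m, alpha), error = function(e)
    structure(list(kappa = NA_real_, p_o = sum(diag(m)) / sum(m),
                   p_e = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                   n = sum(m), alpha = alpha), class = "agreement_result"))
  kappa_grad <- safe_kappa(grad)
  t2 <- to_2x2(tab)
  acc <- diagnostic_accuracy(t2, alpha)
  kappa_dr <- safe_kappa(matrix(c(t2$tp, t2$fn, t2$fp, t2$tn), 2, 2))
  auc <- single_point_auc(acc$sensitivity$est, acc$specificity$est,
                          n_pos = t2$tp + t2$fn, n_neg = t2$fp + t2$tn,
                          alpha = alpha)
  prev <- acc$prevalence$est
  safe_fagan <- function(lr) {
    if (is.finite(lr) && lr > 0 && prev > 0 && prev < 1)
      fagan_posttest(prev, lr)
    else structure(list(pretest = prev, lr = lr, posttest = NA_real_),
                   class = "posttest_result")
  }
  structure(list(
    labels = attr(tab, "labels"), table = tab, gradability = grad,
    kappa_gradability = kappa_grad, accuracy = acc, kappa_dr = kappa_dr,
    auc = auc,
    fagan_positive = safe_fagan(acc$lr_pos$est),
    fagan_negative = safe_fagan(acc$lr_neg$est)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  lb <- x$labels
  cat(sprintf("== Validation: %s vs %s (reference) ==\n", lb["test"], lb["reference"]))
  cat("\nDiagnosis cross-tabulation (rows = test, cols = reference):\n")
  print(unclass(x$table))
  cat("\nGradable/ungradable collapse:\n")
  print(x$gradability)
  cat("  "); print(x$kappa_gradability)
  cat("\nDR/NODR block (pairwise gradable):\n")
  print(x$accuracy)
  cat("  "); print(x$kappa_dr)
  cat("  "); print(x$auc)
  cat("  "); print(x$fagan_positive)
  cat("  "); print(x$fagan_negative)
  invisible(x)
}

# JSON-ready list form of a validation report.
report_to_list <- function(x) {
  acc_block <- function(v) list(est = v$est, ci = v$ci)
  list(
    labels = as.list(x$labels),
    table = list(counts = unclass(x$table)[,], rows = rownames(x$table),
                 cols = colnames(x$table)),
    gradability = list(counts = x$gradability[,],
                       kappa = x$kappa_gradability$kappa,
                       kappa_se = x$kappa_gradability$se,
                       kappa_ci = x$kappa_gradability$ci),
    accuracy = list(
      tp = x$accuracy$table$tp, fp = x$accuracy$table$fp,
      fn = x$accuracy$table$fn, tn = x$accuracy$table$tn,
      n = x$accuracy$n,
      prevalence = acc_block(x$accuracy$prevalence),
      sensitivity = acc_block(x$accuracy$sensitivity),
      specificity = acc_block(x$accuracy$specificity),
      ppv = acc_block(x$accuracy$ppv), npv = acc_block(x$accuracy$npv),
      lr_pos = acc_block(x$accuracy$lr_pos),
      lr_neg = acc_block(x$accuracy$lr_neg)),
    kappa_dr = list(kappa = x$kappa_dr$kappa, se = x$kappa_dr$se,
                    ci = x$kappa_dr$ci),
    auc = list(auc = x$auc$auc, ci = x$auc$ci),
    fagan = list(positive = x$fagan_positive$posttest,
                 negative = x$fagan_negative$posttest))
}

#' Write a validation report to JSON
#'
#' @param x a [validation_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(report_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
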