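#' Screening cohort specification
#'
#' Describes a synthetic screening population: every patient contributes two
#' eyes with three captures each. Stages are drawn from `stage_distribution`
#' (the patient's worst eye carries the drawn stage, the fellow eye a
#' uniformly drawn stage no worse), macular edema occurs with
#' `dme_rate_given_mod_or_worse` among patients staged moderate or worse,
#' and a patient is ungradable (both eyes degraded beyond the quality gate)
#' as an independent event with probability `ung_rate`. Defaults emulate a
#' large primary-care screening population: about 21% DR prevalence among
#' gradable patients, about 21% macular edema among moderate-or-worse, and
#' an 11.6% ungradable rate.
#'
#' @param n_patients number of patients.
#' @param stage_distribution named probabilities over
#'   `NODR, MILD, MOD, SEV, PROL`; must sum to 1.
#' @param dme_rate_given_mod_or_worse probability in `[0, 1]`.
#' @param ung_rate per-patient ungradability probability.
#' @param rater_models named list of rater error models, each
#'   `list(se =, sp =, p_ung =)`: the rater emits `UNG` with `p_ung`
#'   independently of truth, otherwise `DR` with probability `se` for truly
#'   DR patients and `1 - sp` for truly NODR patients.
#' @param stage_conditional_on_gradable if `TRUE` (default) stages are drawn
#'   for every patient independently of gradability, so the stage mix among
#'   gradable patients matches `stage_distribution`; if `FALSE`, ungradable
#'   patients are forced to `NODR` so that the configured STDR share applies
#'   to the whole cohort instead.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        stage_distribution = c(NODR = 0.7902, MILD = 0.0919,
                                               MOD = 0.1124, SEV = 0.0033,
                                               PROL = 0.0022),
                        dme_rate_given_mod_or_worse = 0.21,
                        ung_rate = 0.116,
                        rater_models = list(
                          ALG = list(se = 0.85, sp = 0.81, p_ung = 0.263),
                          PCP = list(se = 0.635, sp = 0.896, p_ung = 0.131)),
                        stage_conditional_on_gradable = TRUE,
                        seed = 1L) {
  if (n_patients <= 0) stop("n_patients must be positive")
  stage_distribution <- stage_distribution[stage_levels()]
  if (anyNA(stage_distribution))
    stop("stage_distribution must name all of ", paste(stage_levels(), collapse = ", "))
  if (abs(sum(stage_distribution) - 1) > 1e-6)
    stop("stage_distribution must sum to 1")
  probs <- c(unlist(stage_distribution), dme_rate_given_mod_or_worse, ung_rate,
             unlist(lapply(rater_models, unlist)))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 stage_distribution = stage_distribution,
                 dme_rate_given_mod_or_worse = dme_rate_given_mod_or_worse,
                 ung_rate = ung_rate, rater_models = rater_models,
                 stage_conditional_on_gradable = stage_conditional_on_gradable,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic screening cohort
#'
#' Draws patient-level truth and the capture manifest (two eyes, three
#' captures per eye, six rows per patient) and, when rater models are
#' configured, the simulated per-rater diagnoses. Reproducible: the output
#' is a pure function of the specification including its seed. No pixels
#' are rendered here; [run_synth()] renders the manifest to image files.
#'
#' @param spec a [cohort_spec()].
#' @param image_dir directory name recorded in the manifest `path` column.
#' @return list with `manifest` (one row per capture), `truth` (one row per
#'   patient: `patient_id`, `status`, `stage`, `dme`, `stdr`), and
#'   `rater_calls` (long data frame `patient_id`, `rater_id`, `diagnosis`,
#'   or `NULL` when no rater models are configured).
#' @export
generate_cohort <- function(spec, image_dir = "images") {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    stage <- sample(stage_levels(), n, replace = TRUE,
                    prob = spec$stage_distribution)
    ung <- runif(n) < spec$ung_rate
    if (!spec$stage_conditional_on_gradable) stage[ung] <- "NODR"
    dme <- stage_rank(stage) >= 3 &
      runif(n) < spec$dme_rate_given_mod_or_worse
    worst_eye <- sample(c("OD", "OS"), n, replace = TRUE)
    fellow_stage <- vapply(stage_rank(stage), function(rk)
      stage_levels()[sample.int(rk, 1)], "")

    underlying <- ifelse(stage == "NODR", "NODR", "DR")
    status <- ifelse(ung, "UNG", underlying)
    truth <- data.frame(
      patient_id = ids, status = status, stage = stage, dme = dme,
      stdr = dme | stage %in% c("SEV", "PROL"),
      underlying = underlying, ungradable = ung,
      worst_eye = worst_eye, fellow_stage = fellow_stage,
      stringsAsFactors = FALSE)

    eye <- rep(c("OD", "OD", "OD", "OS", "OS", "OS"), n)
    rows_worst <- eye == rep(worst_eye, each = 6)
    manifest <- data.frame(
      patient_id = rep(ids, each = 6), eye = eye,
      capture = rep(1:3, 2 * n),
      path = file.path(image_dir,
                       sprintf("%s_%s_%d.png", rep(ids, each = 6), eye,
                               rep(1:3, 2 * n))),
      stage_truth = ifelse(rows_worst, rep(stage, each = 6),
                           rep(fellow_stage, each = 6)),
      dme_truth = rows_worst & rep(dme, each = 6),
      gradable_truth = !rep(ung, each = 6),
      stringsAsFactors = FALSE)

    rater_calls <- NULL
    if (length(spec$rater_models)) {
      rater_calls <- do.call(rbind, lapply(names(spec$rater_models), function(nm)
        data.frame(patient_id = ids, rater_id = nm,
                   diagnosis = simulate_rater(underlying,
                                              spec$rater_models[[nm]]),
                   stringsAsFactors = FALSE)))
    }
    list(manifest = manifest, truth = truth, rater_calls = rater_calls)
  })
}

#' Simulate a screening rater
#'
#' Applies a rater error model to true patient statuses: the rater emits
#' `UNG` with probability `p_ung` independently of truth; otherwise `DR`
#' with probability `se` (sensitivity) when the truth is `DR`, and with
#' probability `1 - sp` (one minus specificity) when the truth is `NODR`.
#'
#' @param truth character vector of `"DR"` / `"NODR"` true statuses.
#' @param model list with `se`, `sp`, `p_ung` in `[0, 1]`.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_cohort()]).
#' @return character vector of simulated diagnoses in `DR, NODR, UNG`.
#' @export
simulate_rater <- function(truth, model, seed = NULL) {
  if (!all(truth %in% c("DR", "NODR")))
    stop("simulate_rater needs DR/NODR truth statuses")
  stopifnot(all(unlist(model[c("se", "sp", "p_ung")]) >= 0),
            all(unlist(model[c("se", "sp", "p_ung")]) <= 1))
  draw <- function() {
    n <- length(truth)
    p_dr <- ifelse(truth == "DR", model$se, 1 - model$sp)
    call <- ifelse(runif(n) < p_dr, "DR", "NODR")
    ifelse(runif(n) < model$p_ung, "UNG", call)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
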