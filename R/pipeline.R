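#' Generate a cohort and render its images to disk
#'
#' Renders every manifest row of a synthetic cohort to a PNG file and writes
#' `manifest.csv`, `truth.csv` and (when rater models are configured)
#' `rater_calls.csv` into `outdir`. The three captures of an eye share the
#' lesion layout and differ in noise; ungradable patients are rendered with
#' degradation beyond the documented generator thresholds in both eyes.
#'
#' @param outdir output directory (created if needed).
#' @param spec a [cohort_spec()].
#' @param image_config template [synth_image_config()] providing geometry
#'   (its lesions/degradation/seed fields are overridden per capture).
#' @param write_images set `FALSE` to write only the CSV files.
#' @param verbose print progress.
#' @return the [generate_cohort()] list, invisibly, with `outdir` attached.
#' @export
run_synth <- function(outdir, spec = cohort_spec(),
                      image_config = synth_image_config(),
                      write_images = TRUE, verbose = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  coh <- generate_cohort(spec)
  if (verbose) message("cohort seed: ", spec$seed)
  if (write_images) {
    dir.create(file.path(outdir, "images"), showWarnings = FALSE)
    for (pid in coh$truth$patient_id) {
      pt <- coh$truth[coh$truth$patient_id == pid, ]
      rows <- coh$manifest[coh$manifest$patient_id == pid, ]
      for (eye in c("OD", "OS")) {
        stage <- if (pt$worst_eye == eye) pt$stage else pt$fellow_stage
        dme <- pt$dme && pt$worst_eye == eye
        eseed <- child_seed(spec$seed, match(pid, coh$truth$patient_id) * 2L +
                              (eye == "OS"))
        cfg <- image_config
        cfg$eye <- eye
        cfg$seed <- eseed
        # mirror the template geometry for the left eye
        base <- synth_image_config(width = cfg$width, height = cfg$height,
                                   eye = eye, seed = eseed)
        cfg$disc_center <- base$disc_center
        cfg$fovea_center <- base$fovea_center
        cfg$disc_radius <- base$disc_radius; cfg$dd <- base$dd
        if (pt$ungradable) cfg$blur_sigma <- 8
        cfg <- sample_lesions(cfg, stage = stage, dme = dme)
        for (cap in 1:3) {
          ccfg <- cfg
          # captures share geometry/lesions and differ only in pixel noise
          ccfg$noise_seed <- child_seed(eseed, cap)
          res <- generate_eye_image(ccfg, patient_id = pid, capture = cap)
          path <- rows$path[rows$eye == eye & rows$capture == cap]
          write_fundus(res$image, file.path(outdir, path))
        }
      }
      if (verbose) message("rendered ", pid)
    }
  }
  write.csv(coh$manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  write.csv(coh$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  if (!is.null(coh$rater_calls))
    write.csv(coh$rater_calls, file.path(outdir, "rater_calls.csv"),
              row.names = FALSE)
  coh$outdir <- outdir
  invisible(coh)
}

#' Analyze a rendered cohort and emit per-patient diagnoses
#'
#' Reads every image of the manifest, runs [analyze_image()], grades eyes
#' and patients, and writes `diagnoses.csv` (`patient_id`, `status`,
#' `stage`, `dme`, `stdr`) plus one JSON analysis per image. Unreadable
#' files produce a warning and are treated as ungradable captures; the run
#' continues.
#'
#' @param manifest_path path to a manifest CSV (columns `patient_id`, `eye`,
#'   `capture`, `path`).
#' @param outdir output directory for `diagnoses.csv` and `analysis/*.json`.
#' @param image_root directory the manifest paths are relative to; defaults
#'   to the manifest's directory.
#' @param params analysis parameters.
#' @param overlays write overlay PNGs for images with a coordinate frame.
#' @param verbose print progress.
#' @return data frame of per-patient diagnoses, invisibly.
#' @export
run_analyze <- function(manifest_path, outdir,
                        image_root = dirname(manifest_path),
                        params = default_params(), overlays = FALSE,
                        verbose = FALSE) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "capture", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "analysis"), showWarnings = FALSE)
  if (overlays) dir.create(file.path(outdir, "overlays"), showWarnings = FALSE)

  failed_quality <- structure(
    list(gradable = FALSE, sharpness = 0, illuminated_fraction = 0,
         saturation_fraction = 0, reasons = "unreadable", field = NULL),
    class = "quality_report")

  out <- list()
  for (pid in unique(manifest$patient_id)) {
    eyes <- list()
    for (eye in c("OD", "OS")) {
      rows <- manifest[manifest$patient_id == pid & manifest$eye == eye, ]
      if (nrow(rows) == 0) next
      analyses <- lapply(seq_len(nrow(rows)), function(i) {
        f <- file.path(image_root, rows$path[i])
        an <- tryCatch({
          img <- read_fundus(f, pid, eye, rows$capture[i])
          analyze_image(img, params)
        }, error = function(e) {
          warning("unreadable capture ", rows$path[i], ": ",
                  conditionMessage(e), call. = FALSE)
          structure(list(quality = failed_quality, frame = NULL,
                         vessels = NULL, lesions = list(),
                         reasons = "unreadable", patient_id = pid, eye = eye,
                         capture = rows$capture[i]),
                    class = "image_analysis")
        })
        jsonlite::write_json(
          analysis_to_list(an),
          file.path(outdir, "analysis",
                    sprintf("%s_%s_%d.json", pid, eye, rows$capture[i])),
          auto_unbox = TRUE, digits = NA, null = "null")
        if (overlays && !is.null(an$frame)) {
          ov <- render_overlay(read_fundus(file.path(image_root, rows$path[i]),
                                           pid, eye, rows$capture[i]), an)
          write_fundus(ov, file.path(outdir, "overlays",
                                     sprintf("%s_%s_%d.png", pid, eye,
                                             rows$capture[i])))
        }
        an
      })
      eyes[[eye]] <- grade_eye(analyses, eye = eye)
    }
    pd <- aggregate_patient(eyes[["OD"]], eyes[["OS"]],
                            ung_precedence = params$grading$ung_precedence)
    out[[length(out) + 1]] <- data.frame(
      patient_id = pid, status = pd$status, stage = pd$stage,
      dme = pd$dme, stdr = pd$stdr, stringsAsFactors = FALSE)
    if (verbose) message(pid, " -> ", pd$status)
  }
  diagnoses <- do.call(rbind, out)
  write.csv(diagnoses, file.path(outdir, "diagnoses.csv"), row.names = FALSE)
  invisible(diagnoses)
}

#' Read a per-patient diagnosis CSV
#'
#' Accepts either the wide form written by [run_analyze()] (`patient_id`,
#' `status`) or the long rater-calls form (`patient_id`, `rater_id`,
#' `diagnosis`), optionally filtered to one rater.
#'
#' @param path CSV file.
#' @param rater when reading a long rater-calls file, which rater to keep.
#' @return data frame with `patient_id` and `status`.
#' @export
read_diagnosis_csv <- function(path, rater = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("patient_id", "rater_id", "diagnosis") %in% names(df))) {
    if (!is.null(rater)) df <- df[df$rater_id == rater, ]
    if (nrow(df) == 0) stop("no rows for rater ", rater, " in ", path)
    df <- data.frame(patient_id = df$patient_id, status = df$diagnosis,
                     stringsAsFactors = FALSE)
  } else if (all(c("patient_id", "status") %in% names(df))) {
    df <- df[, c("patient_id", "status")]
  } else stop("unrecognized diagnosis CSV layout in ", path)
  bad <- setdiff(unique(df$status), diag_levels())
  if (length(bad)) stop("malformed diagnosis labels in ", path, ": ",
                        paste(bad, collapse = ", "))
  df
}

#' Validate a test rater against a reference from CSV files
#'
#' Joins the two per-patient diagnosis files on `patient_id` (erroring with
#' the offending ids when they do not match), computes the
#' [validation_report()], and writes it as JSON plus a human-readable text
#' table.
#'
#' @param test_csv,reference_csv diagnosis CSVs, see [read_diagnosis_csv()].
#' @param outdir output directory for `report.json` / `report.txt`
#'   (`NULL` to skip writing).
#' @param labels rater names for the report.
#' @param test_rater,reference_rater rater filters for long-form CSVs.
#' @param alpha significance level.
#' @return the `validation_report`, invisibly.
#' @export
run_validate <- function(test_csv, reference_csv, outdir = NULL,
                         labels = c(test = "test", reference = "reference"),
                         test_rater = NULL, reference_rater = NULL,
                         alpha = 0.05) {
  test <- read_diagnosis_csv(test_csv, test_rater)
  ref <- read_diagnosis_csv(reference_csv, reference_rater)
  extra_t <- setdiff(test$patient_id, ref$patient_id)
  extra_r <- setdiff(ref$patient_id, test$patient_id)
  if (length(extra_t) || length(extra_r))
    stop("patient ids do not match; only in test: ",
         paste(head(extra_t, 5), collapse = ", "),
         "; only in reference: ", paste(head(extra_r, 5), collapse = ", "))
  if (nrow(test) == 0) stop("empty patient overlap")
  ref <- ref[match(test$patient_id, ref$patient_id), ]
  rep <- validation_report(test$status, ref$status, labels, alpha)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(rep, file.path(outdir, "report.json"))
    con <- file(file.path(outdir, "report.txt"), "w")
    sink(con); print(rep); sink()
    close(con)
  }
  invisible(rep)
}
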