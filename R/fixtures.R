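#' Bundled screening-study cross-tabulations
#'
#' Patient-level diagnosis cross-tabulations from a large primary-care
#' diabetic-retinopathy screening programme (3520 patients), bundled as
#' worked-example inputs: an automated grader (`ALG`) and the screening
#' primary-care physicians (`PCP`), each cross-tabulated against the
#' consensus diagnosis of three reference ophthalmologists (`OPH`) over the
#' categories `DR`, `NODR`, `UNG`; plus the 2x2 tables of the paired
#' subsample (the 2335 patients gradable by all three strategies).
#'
#' @return list with `alg_oph` and `pcp_oph` ([rater_table()]s, n = 3520
#'   each), and `paired` (named list of [contingency_2x2()]: `ALG`, `PCP`,
#'   n = 2335 each). Also `ung_counts`: the per-strategy ungradable patient
#'   counts out of 3520 (`OPH` 407, `PCP` 461, `ALG` 927).
#' @export
screening_tables <- function() {
  dir <- system.file("extdata", "screening", package = "fundusdr")
  read3 <- function(f, lab) {
    df <- read.csv(file.path(dir, f), row.names = 1)
    rater_table(as.matrix(df), labels = lab)
  }
  paired <- read.csv(file.path(dir, "paired_2x2.csv"))
  list(
    alg_oph = read3("alg_vs_oph.csv", c(test = "ALG", reference = "OPH")),
    pcp_oph = read3("pcp_vs_oph.csv", c(test = "PCP", reference = "OPH")),
    paired = setNames(lapply(seq_len(nrow(paired)), function(i)
      contingency_2x2(paired$tp[i], paired$fp[i], paired$fn[i], paired$tn[i])),
      paired$rater),
    ung_counts = c(OPH = 407L, PCP = 461L, ALG = 927L, total = 3520L))
}
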