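.fundusdr_cache <- new.env(parent = emptyenv())

#' Default analysis parameters
#'
#' Returns the full set of pipeline thresholds (quality gates, vessel and
#' lesion detector settings, grading cut-offs) as a nested list. Values were
#' calibrated once against the synthetic generator at its default geometry
#' and are stored in `inst/extdata/default_params.yml`.
#'
#' @param ... named overrides, e.g. `default_params(quality = list(saturation_max = 0.2))`;
#'   supplied sublists are merged field-by-field into the defaults.
#' @return nested named list of parameters.
#' @export
default_params <- function(...) {
  if (is.null(.fundusdr_cache$params)) {
    path <- system.file("extdata", "default_params.yml", package = "fundusdr")
    .fundusdr_cache$params <- yaml::read_yaml(path)
  }
  p <- .fundusdr_cache$params
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(p[[nm]])) {
      for (k in names(mods[[nm]])) p[[nm]][[k]] <- mods[[nm]][[k]]
    } else p[[nm]] <- mods[[nm]]
  }
  p
}
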