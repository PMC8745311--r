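#' Fundus image container
#'
#' Wraps one colour fundus capture as an `H x W x 3` numeric array in
#' `[0, 1]` together with its patient/eye/capture identity. Pixel
#' coordinates throughout the package are 1-based with `x` the column and
#' `y` the row.
#'
#' @param pixels numeric `H x W x 3` array in `[0, 1]` (8-bit rasters are
#'   accepted as integers 0–255 and rescaled).
#' @param patient_id character scalar.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param capture capture index 1–3.
#' @param source_path originating file, if any.
#' @return object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, patient_id = "anon", eye = "OD",
                         capture = 1L, source_path = NA_character_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1)) stop("empty raster")
  if (is.integer(pixels) || max(pixels, na.rm = TRUE) > 1 + 1e-9)
    pixels <- pixels / 255
  eye <- match.arg(eye, c("OD", "OS"))
  structure(list(pixels = pixels, patient_id = patient_id, eye = eye,
                 capture = as.integer(capture), source_path = source_path),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %s %s capture %d, %d x %d px\n",
              x$patient_id, x$eye, x$capture, d[1], d[2]))
  invisible(x)
}

#' Read a fundus photograph from disk
#'
#' Reads TIFF, PNG or JPEG into a [fundus_image()]. 16-bit inputs are
#' rescaled to `[0, 1]`; grayscale inputs are replicated across channels.
#'
#' @param path image file.
#' @inheritParams fundus_image
#' @return a `fundus_image`.
#' @export
read_fundus <- function(path, patient_id = "anon", eye = "OD", capture = 1L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)  # W x H (x, y[, c]) in [0,1]
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  px <- aperm(px, c(2, 1, 3))    # -> H x W x 3
  fundus_image(clamp(px), patient_id, eye, capture, source_path = path)
}

#' Write a fundus image or RGB raster
#'
#' Writes PNG (lossless, the package default) or TIFF depending on the file
#' extension.
#'
#' @param image a `fundus_image` or plain `H x W x 3` array in `[0, 1]`.
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(image, path) {
  px <- if (inherits(image, "fundus_image")) image$pixels else image
  ebi <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported output format: ", ext)
  EBImage::writeImage(ebi, path, type = if (ext == "png") "png" else "tiff")
  invisible(path)
}
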