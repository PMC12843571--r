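## Raster I/O (PNG and TIFF), YAML/JSON configuration loading and run
## provenance records.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("jpg", "jpeg")) {
    stop("JPEG I/O is not supported; please convert to PNG or TIFF",
         call. = FALSE)
  }
  stop(sprintf("unsupported image format '%s' (%s)", ext, path), call. = FALSE)
}

#' Read a raster image
#'
#' PNG and TIFF are supported; 8- and 16-bit files are normalized to
#' \[0,1\] by their maximum code value (the underlying readers already
#' deliver this scale). Grayscale conversion of color files uses the
#' luminance row of the YUV transform.
#'
#' @param path image file path.
#' @param as `"gray"` for an Image2D matrix, `"rgb"` for an H x W x 3
#'   array.
#' @return Image2D or `rgb_image`.
#' @export
read_image <- function(path, as = c("gray", "rgb")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fmt <- img_format(path)
  x <- switch(fmt,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path)
  )
  nd <- length(dim(x))
  if (nd == 3L && dim(x)[3] >= 3L) {
    rgb <- x[, , 1:3, drop = FALSE]
    if (as == "gray") return(luminance(rgb))
    class(rgb) <- c("rgb_image", "array")
    return(rgb)
  }
  gray <- if (nd == 3L) x[, , 1] else x
  if (as == "gray") return(gray)
  rgb_image(gray, gray, gray)
}

#' Write an image to disk
#'
#' Values are clipped to \[0,1\] and quantized; PNG is written at 8 bits,
#' TIFF at 8 or 16 bits.
#'
#' @param img Image2D or 3-plane array.
#' @param path output path (extension selects the format).
#' @param bits 8 (default) or 16 (TIFF only).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  fmt <- img_format(path)
  x <- clip01(unclass(img))
  if (fmt == "png") {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

## keys accepted in a config file, mapped onto fusion_config() arguments
.config_keys <- c("mode", "color_space", "k", "working_size", "seed",
                  "denoise", "backbone",
                  "noise_mri", "noise_pet", "bilateral", "nlm", "guided")

#' Load a fusion configuration from a YAML or JSON file
#'
#' Missing keys take the package defaults; unknown keys are rejected with
#' an error naming the key. Nested sections `noise_mri`, `noise_pet`,
#' `bilateral`, `nlm`, `guided` take the corresponding constructor
#' arguments; `k: full` (or null) selects the full decomposition.
#'
#' @param path YAML or JSON file path; an empty file yields the full
#'   default configuration.
#' @return a [fusion_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  args <- list()
  for (key in c("mode", "color_space", "working_size", "seed", "denoise",
                "backbone")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$k) && !identical(raw$k, "full")) args$k <- raw$k
  build <- function(ctor, lst) do.call(ctor, as.list(lst))
  if (!is.null(raw$noise_mri)) args$noise_mri <- build(noise_spec, raw$noise_mri)
  if (!is.null(raw$noise_pet)) args$noise_pet <- build(noise_spec, raw$noise_pet)
  if (!is.null(raw$bilateral)) args$bilateral <- build(bilateral_params, raw$bilateral)
  if (!is.null(raw$nlm)) args$nlm <- build(nlm_params, raw$nlm)
  if (!is.null(raw$guided)) args$guided <- build(guided_params, raw$guided)
  tryCatch(do.call(fusion_config, args), error = function(e) {
    stop(sprintf("invalid configuration in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
}

## Serializable snapshot of a config (feature_extractor backbones are
## summarized by their architecture string).
config_snapshot <- function(config) {
  snap <- unclass(config)
  if (inherits(snap$backbone, "feature_extractor")) {
    snap$backbone <- snap$backbone$arch
  }
  snap$noise_mri <- unclass(snap$noise_mri)
  snap$noise_pet <- unclass(snap$noise_pet)
  snap$bilateral <- unclass(snap$bilateral)
  snap$nlm <- unclass(snap$nlm)
  snap$guided <- unclass(snap$guided)
  snap$k <- if (is.null(snap$k)) "full" else snap$k
  snap
}

#' Write a run provenance record
#'
#' JSON snapshot of the configuration, seeds, stage wall-times, output
#' paths and package version, written alongside every CLI run so that a
#' deterministic run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param config a [fusion_config()] (or NULL).
#' @param timings named numeric vector of stage wall-times in seconds.
#' @param outputs named character vector of output paths.
#' @param extra optional named list merged into the record.
#' @return the record, invisibly.
#' @export
write_run_record <- function(path, config = NULL, timings = NULL,
                             outputs = NULL, extra = NULL) {
  rec <- list(
    package = "svdfusion",
    version = as.character(utils::packageVersion("svdfusion")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else config_snapshot(config),
    timings_sec = as.list(timings),
    outputs = as.list(outputs)
  )
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}
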