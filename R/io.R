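# Slice-pair I/O and intensity normalization. The exact array container is
# RDS (lossless doubles, byte-deterministic); raster fallbacks are PNG
# (8-bit) and 32-bit float TIFF, chosen by file extension.

#' Intensity normalization specification
#'
#' `none` assumes the files are already on a common `[0, 1]` scale and only
#' clips; `global_minmax` maps the normal-dose image's min/max affinely to
#' `[0, 1]` and applies the same mapping to both images (one shared scale,
#' as the simulator does); `fixed_window` maps the window
#' `[window_low, window_high]` in source units to `[0, 1]`. Values outside
#' the range are clipped.
#'
#' @param mode `"global_minmax"`, `"fixed_window"` or `"none"`.
#' @param window_low,window_high Window bounds (required for
#'   `fixed_window`; e.g. Hounsfield units for clinical data).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(mode = c("global_minmax", "fixed_window",
                                        "none"),
                               window_low = NA_real_, window_high = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "fixed_window") {
    if (!is.finite(window_low) || !is.finite(window_high) ||
        window_low >= window_high)
      stop("normalization_spec: fixed_window needs window_low < window_high",
           call. = FALSE)
  }
  structure(list(mode = mode, window_low = as.numeric(window_low),
                 window_high = as.numeric(window_high)),
            class = "normalization_spec")
}

.img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rds")) return("rds")
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
}

#' Read / write a single image
#'
#' @param path File path; format chosen by extension (`.rds`, `.png`,
#'   `.tif`/`.tiff`).
#' @return `read_image` returns a numeric matrix in source units.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path, call. = FALSE)
  fmt <- .img_format(path)
  img <- switch(fmt,
                rds = readRDS(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  as.matrix(img)
}

#' @rdname read_image
#' @param img Numeric matrix (raster formats expect values in `[0, 1]`).
#' @export
write_image <- function(img, path) {
  img <- as.matrix(img)
  fmt <- .img_format(path)
  switch(fmt,
         rds = saveRDS(img, path),
         png = png::writePNG(pmin(pmax(img, 0), 1), path),
         tiff = tiff::writeTIFF(pmin(pmax(img, 0), 1), path,
                                bits.per.sample = 32L,
                                compression = "none"))
  invisible(path)
}

#' Write a slice pair
#'
#' @param pair An [image_pair()].
#' @param path_ldct,path_ndct Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pair <- function(pair, path_ldct, path_ndct) {
  stopifnot(inherits(pair, "image_pair"))
  write_image(pair$ldct, path_ldct)
  write_image(pair$ndct, path_ndct)
  invisible(c(path_ldct, path_ndct))
}

#' Read a slice pair with shared normalization
#'
#' Both images are mapped to `[0, 1]` under one shared intensity mapping so
#' a single mask threshold is meaningful across the pair.
#'
#' @param path_ldct,path_ndct Image paths (same pixel dimensions).
#' @param norm A [normalization_spec()].
#' @return An [image_pair()] with provenance `"file"`.
#' @export
read_pair <- function(path_ldct, path_ndct,
                      norm = normalization_spec("global_minmax")) {
  l <- read_image(path_ldct)
  n <- read_image(path_ndct)
  if (!all(dim(l) == dim(n)))
    stop(sprintf("read_pair: dimension mismatch %dx%d vs %dx%d",
                 nrow(l), ncol(l), nrow(n), ncol(n)), call. = FALSE)
  if (norm$mode == "fixed_window") {
    lo <- norm$window_low; hi <- norm$window_high
  } else if (norm$mode == "none") {
    lo <- 0; hi <- 1
  } else {
    lo <- min(n); hi <- max(n)
    if (hi - lo < 1e-12) { lo <- 0; hi <- 1 }  # constant reference: identity
  }
  scale01 <- function(x) pmin(pmax((x - lo) / (hi - lo), 0), 1)
  image_pair(scale01(l), scale01(n), provenance = "file")
}

#' Load a fixture set written by [make_fixture_set()]
#'
#' Pairs are read without renormalization (they were written on a common
#' scale), so the round trip is exact.
#'
#' @param dir Directory containing `manifest.json`.
#' @return List of [image_pair()] objects.
#' @export
read_fixture_set <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("read_fixture_set: no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_pair(file.path(dir, manifest$ldct[i]),
              file.path(dir, manifest$ndct[i]),
              norm = normalization_spec("none")))
}
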