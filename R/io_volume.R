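# Stacked TIFF + JSON sidecar I/O and the format-dispatching reader/writer.

#' Write a volume as a stacked TIFF with a JSON sidecar
#'
#' One 32-bit float TIFF page per slice. TIFF stores intensities normalized
#' to [0, 1]; the sidecar (\code{<path>.json}) records the value range,
#' spacings, origin and metadata needed to restore the original scale.
#'
#' @param volume a \code{recon_volume}.
#' @param path output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_tiff_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  rng <- range(volume$data)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(dim(volume$data)[1]), function(s) {
    m <- matrix(volume$data[s, , ], dim(volume$data)[2], dim(volume$data)[3])
    (m - rng[1]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    format = "tomoqa-tiff-volume", version = "1.0",
    spacing = as.numeric(volume$spacing),   # dz, dy, dx
    origin = as.numeric(volume$origin),     # x, y, z
    value_min = rng[1], value_max = rng[2],
    n_slices = dim(volume$data)[1],
    metadata = volume$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_tiff_volume <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stopf("missing JSON sidecar for TIFF volume: %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("spacing", "origin", "value_min", "value_max"))
    if (is.null(sc[[f]]))
      stopf("TIFF sidecar is missing required field '%s'", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (sc$value_max > sc$value_min) sc$value_max - sc$value_min else 1
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (s in seq_along(pages))
    arr[s, , ] <- sc$value_min + pages[[s]] * scale
  recon_volume(arr, spacing = sc$spacing, origin = sc$origin,
               metadata = as.list(sc$metadata))
}

#' Read a reconstructed volume
#'
#' @param path a multi-frame DICOM file, a directory of single-frame
#'   \code{.dcm} files, or a stacked TIFF (with its \code{.json} sidecar
#'   next to it).
#' @param format \code{"auto"} (default, decided from the path), or one of
#'   \code{"dicom"}, \code{"dicom-series"}, \code{"tiff"}.
#' @return A \code{\link{recon_volume}} with slices ordered by increasing z
#'   and row 1 at the chest-wall edge. Intensities are returned with the
#'   declared DICOM rescale slope/intercept applied (and recorded in the
#'   metadata); no other rescaling is performed.
#' @export
read_volume <- function(path, format = c("auto", "dicom", "dicom-series",
                                         "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("input path does not exist: %s", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom-series"
      else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff"
      else "dicom"
  }
  switch(format,
         "dicom" = read_dicom_volume(path),
         "dicom-series" = read_dicom_volume(path),
         "tiff" = read_tiff_volume(path))
}

#' Write a reconstructed volume
#'
#' @param volume a \code{recon_volume}.
#' @param path output path (file for \code{dicom}/\code{tiff}, directory
#'   for \code{dicom-series}).
#' @param format one of \code{"dicom"}, \code{"dicom-series"},
#'   \code{"tiff"}.
#' @export
write_volume <- function(volume, path, format = c("dicom", "dicom-series",
                                                  "tiff")) {
  format <- match.arg(format)
  switch(format,
         "dicom" = write_dicom(volume, path),
         "dicom-series" = write_dicom_series(volume, path),
         "tiff" = write_tiff_volume(volume, path))
}
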