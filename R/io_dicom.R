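# Minimal DICOM codec: Explicit VR Little Endian only, secondary-capture
# style, covering exactly the geometry/pixel tags the QA pipeline needs
# (multi-frame and single-frame series). Written in-package because no
# DICOM reader is available in the supported R dependency set; scanner
# data using other transfer syntaxes should be converted or supplied as
# TIFF+JSON.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TOMOQA_UID_ROOT <- "1.2.826.0.1.3680043.10.9999"

# VRs with a 2-byte length field; everything else uses 4-byte + 2 reserved
SHORT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
               "US")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
uint32le <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(uint16le(lo), uint16le(hi))
}

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH", "DA", "TM")) {
    v <- charToRaw(paste(value, collapse = "\\"))
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    v <- uint16le(value)
  } else if (vr == "UL") {
    v <- uint32le(value)
  } else if (vr %in% c("OB", "OW")) {
    v <- value  # already raw
  } else stopf("unsupported VR in writer: %s", vr)
  hdr <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% SHORT_VRS) {
    c(hdr, uint16le(length(v)), v)
  } else {
    c(hdr, as.raw(c(0, 0)), uint32le(length(v)), v)
  }
}

fmt_ds <- function(x) {
  s <- formatC(x, format = "g", digits = 10)
  gsub(" ", "", s)
}

# choose rescale slope/intercept: exact for 16-bit-integral data, otherwise
# full-range quantization (recorded in the file and applied on read)
quantize_pixels <- function(data) {
  rng <- range(data)
  if (all(data == round(data)) && rng[1] >= 0 && rng[2] <= 65535) {
    list(stored = as.integer(data), slope = 1, intercept = 0)
  } else {
    slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 65535 else 1
    list(stored = as.integer(round((data - rng[1]) / slope)),
         slope = slope, intercept = rng[1])
  }
}

dcm_dataset_bytes <- function(stored, nframes, nrow_, ncol_, spacing, origin,
                              slope, intercept, metadata, instance = 1L,
                              sop_uid) {
  els <- list(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "OT"),
    dcm_element(0x0018, 0x0050, "DS", fmt_ds(metadata$slice_thickness %||%
                                              spacing[["dz"]])),
    dcm_element(0x0018, 0x0088, "DS", fmt_ds(spacing[["dz"]])),
    if (!is.null(metadata$mas))
      dcm_element(0x0018, 0x1152, "IS", as.character(round(metadata$mas))),
    dcm_element(0x0020, 0x000D, "UI", paste0(TOMOQA_UID_ROOT, ".1.1")),
    dcm_element(0x0020, 0x000E, "UI", paste0(TOMOQA_UID_ROOT, ".1.2")),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", fmt_ds(c(origin[["x"]], origin[["y"]],
                                               origin[["z"]]))),
    dcm_element(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    if (nframes > 1L)
      dcm_element(0x0028, 0x0008, "IS", as.character(nframes)),
    dcm_element(0x0028, 0x0010, "US", nrow_),
    dcm_element(0x0028, 0x0011, "US", ncol_),
    dcm_element(0x0028, 0x0030, "DS", fmt_ds(c(spacing[["dy"]],
                                               spacing[["dx"]]))),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x0028, 0x1052, "DS", fmt_ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", fmt_ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(stored, raw(), size = 2, endian = "little"))
  )
  do.call(c, Filter(Negate(is.null), els))
}

dcm_file_bytes <- function(dataset_bytes, sop_uid) {
  meta_els <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(TOMOQA_UID_ROOT, ".0.1"))
  )
  group_len <- dcm_element(0x0002, 0x0000, "UL", length(meta_els))
  c(raw(128), charToRaw("DICM"), group_len, meta_els, dataset_bytes)
}

#' Write a volume as multi-frame DICOM
#'
#' Secondary-capture profile, Explicit VR Little Endian, with pixel spacing,
#' slice thickness, spacing-between-slices, image position and rescale
#' slope/intercept tags. Pixel data are stored as 16-bit unsigned integers;
#' integral volumes in range are stored exactly (slope 1, intercept 0),
#' anything else is range-quantized with the quantization recorded in the
#' rescale tags.
#'
#' @param volume a \code{recon_volume}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dicom <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$data)
  # frame-major pixel order: row-major within each frame
  stored_arr <- aperm(volume$data, c(3, 2, 1))  # [col, row, slice]
  q <- quantize_pixels(as.vector(stored_arr))
  sop_uid <- paste0(TOMOQA_UID_ROOT, ".2.1")
  ds <- dcm_dataset_bytes(q$stored, d[1], d[2], d[3], volume$spacing,
                          volume$origin, q$slope, q$intercept,
                          volume$metadata, sop_uid = sop_uid)
  writeBin(dcm_file_bytes(ds, sop_uid), path)
  invisible(path)
}

#' Write a volume as a single-frame DICOM series
#'
#' One file per slice (\code{slice_0001.dcm}, ...) in \code{dir}; slice
#' order is recoverable from the Image Position (Patient) z component
#' regardless of file naming.
#'
#' @param volume a \code{recon_volume}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "recon_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$data)
  q_all <- quantize_pixels(as.vector(volume$data))
  for (s in seq_len(d[1])) {
    sl <- matrix(volume$data[s, , ], d[2], d[3])
    stored <- as.integer(round((t(sl) - q_all$intercept) / q_all$slope))
    org <- volume$origin
    org[["z"]] <- org[["z"]] + (s - 1) * volume$spacing[["dz"]]
    sop_uid <- paste0(TOMOQA_UID_ROOT, ".2.", s)
    ds <- dcm_dataset_bytes(stored, 1L, d[2], d[3], volume$spacing, org,
                            q_all$slope, q_all$intercept, volume$metadata,
                            instance = s, sop_uid = sop_uid)
    writeBin(dcm_file_bytes(ds, sop_uid),
             file.path(dir, sprintf("slice_%04d.dcm", s)))
  }
  invisible(dir)
}

## ---- reader ----------------------------------------------------------------

parse_dicom_elements <- function(bytes) {
  n <- length(bytes)
  if (n < 140 || rawToChar(bytes[129:132]) != "DICM")
    stopf("not a DICOM file (missing DICM magic)")
  pos <- 133L
  out <- list()
  while (pos + 8 <= n) {
    group <- readBin(bytes[pos:(pos + 1)], "integer", size = 2,
                     endian = "little", signed = FALSE)
    elem <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                    endian = "little", signed = FALSE)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stopf("unsupported DICOM encoding (implicit VR?) at byte %d", pos)
    if (vr %in% SHORT_VRS) {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      vstart <- pos + 8L
    } else {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      if (len < 0) stopf("undefined-length DICOM element (%04X,%04X) not supported",
                         group, elem)
      vstart <- pos + 12L
    }
    val_raw <- if (len > 0) bytes[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, raw = val_raw)
    pos <- vstart + len
  }
  out
}

dcm_value <- function(els, key, required_name = NULL) {
  e <- els[[key]]
  if (is.null(e)) {
    if (!is.null(required_name))
      stopf("required DICOM tag (%s) %s is missing", key, required_name)
    return(NULL)
  }
  switch(e$vr,
    US = readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
                 endian = "little", signed = FALSE),
    UL = readBin(e$raw, "integer", n = length(e$raw) / 4, size = 4,
                 endian = "little"),
    DS = as.numeric(strsplit(trimws(rawToChar(e$raw)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(e$raw)), "\\\\")[[1]]),
    OW = readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
                 endian = "little", signed = FALSE),
    trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
  )
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  els <- parse_dicom_elements(bytes)
  nrow_ <- dcm_value(els, "0028,0010", "Rows")
  ncol_ <- dcm_value(els, "0028,0011", "Columns")
  nframes <- dcm_value(els, "0028,0008") %||% 1L
  spacing_xy <- dcm_value(els, "0028,0030", "PixelSpacing")
  dz <- dcm_value(els, "0018,0088")
  if (is.null(dz)) dz <- dcm_value(els, "0018,0050", "SpacingBetweenSlices/SliceThickness")
  ipp <- dcm_value(els, "0020,0032", "ImagePositionPatient")
  slope <- dcm_value(els, "0028,1053") %||% 1
  intercept <- dcm_value(els, "0028,1052") %||% 0
  px <- dcm_value(els, "7FE0,0010", "PixelData")
  if (length(px) != nrow_ * ncol_ * nframes)
    stopf("PixelData length %d does not match %d x %d x %d",
          length(px), nframes, nrow_, ncol_)
  arr <- array(px, dim = c(ncol_, nrow_, nframes))  # stored col-major
  arr <- aperm(arr, c(3, 2, 1)) * slope + intercept
  list(data = arr, spacing_xy = spacing_xy, dz = as.numeric(dz),
       ipp = ipp, slope = slope, intercept = intercept,
       instance = dcm_value(els, "0020,0013") %||% NA_integer_,
       mas = dcm_value(els, "0018,1152"))
}

read_dicom_volume <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
    if (!length(files)) stopf("no .dcm files in %s", path)
    frames <- lapply(files, read_dicom_file)
    zpos <- vapply(frames, function(f) f$ipp[3], numeric(1))
    ord <- order(zpos)
    frames <- frames[ord]; zpos <- zpos[ord]
    if (length(zpos) > 1) {
      dzs <- diff(zpos)
      if (any(abs(dzs - mean(dzs)) > 0.01 * abs(mean(dzs))))
        stopf("inconsistent inter-slice spacing in series (beyond 1%%): %s",
              paste(format(dzs), collapse = ", "))
      dz <- mean(dzs)
    } else dz <- frames[[1]]$dz
    d1 <- frames[[1]]
    arr <- array(0, dim = c(length(frames), dim(d1$data)[2], dim(d1$data)[3]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]$data[1, , ]
    meta <- list(rescale_slope = d1$slope, rescale_intercept = d1$intercept)
    if (!is.null(d1$mas)) meta$mas <- d1$mas
    recon_volume(arr, spacing = c(dz, d1$spacing_xy[1], d1$spacing_xy[2]),
                 origin = c(d1$ipp[1], d1$ipp[2], zpos[1]), metadata = meta)
  } else {
    f <- read_dicom_file(path)
    meta <- list(rescale_slope = f$slope, rescale_intercept = f$intercept)
    if (!is.null(f$mas)) meta$mas <- f$mas
    recon_volume(f$data, spacing = c(f$dz, f$spacing_xy[1], f$spacing_xy[2]),
                 origin = c(f$ipp[1], f$ipp[2], f$ipp[3]), metadata = meta)
  }
}
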