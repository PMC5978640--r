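# All DICOM/TIFF fixtures are written by the simulator at test time.

io_volume <- function() {
  fx_cache("io_vol", function() {
    render(fx_geometry(), acquisition_model(seed = 11),
           region = list(min = c(x = -20, y = 6, z = 14),
                         max = c(x = 20, y = 22, z = 28)))
  })
}

test_that("multi-frame DICOM round-trips within the recorded quantization", {
  v <- io_volume()
  path <- withr::local_tempfile(fileext = ".dcm")
  write_volume(v, path, "dicom")
  v2 <- read_volume(path)
  quantum <- (max(v$data) - min(v$data)) / 65535
  expect_lt(max(abs(v2$data - v$data)), quantum)
  expect_equal(unname(v2$spacing), unname(v$spacing))
  expect_equal(unname(v2$origin), unname(v$origin))
  expect_equal(v2$metadata$mas, 100L)
})

test_that("integral volumes round-trip voxel-identically through DICOM", {
  v <- io_volume()
  v$data <- round(v$data)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_volume(v, path, "dicom")
  expect_identical(read_volume(path)$data, v$data)
})

test_that("a shuffled DICOM series reads the same as the sorted one", {
  v <- io_volume()
  d1 <- withr::local_tempdir()
  write_volume(v, d1, "dicom-series")
  ref <- read_volume(d1)
  # scramble the file names; order must be recovered from slice positions
  d2 <- withr::local_tempdir()
  files <- list.files(d1, full.names = TRUE)
  set.seed(1)
  for (i in seq_along(files))
    file.copy(files[i], file.path(d2, sprintf("scrambled_%03d.dcm",
                                              sample(1000, 1))))
  v2 <- read_volume(d2)
  expect_identical(v2$data, ref$data)
  expect_equal(unname(v2$origin), unname(ref$origin))
})

test_that("missing spacing tags and bad series spacing are hard errors", {
  v <- io_volume()
  path <- withr::local_tempfile(fileext = ".dcm")
  write_volume(v, path, "dicom")
  bytes <- readBin(path, raw(), file.size(path))
  # retag PixelSpacing (0028,0030) to a private group so the reader
  # cannot find it
  pat <- as.raw(c(0x28, 0x00, 0x30, 0x00, 0x44, 0x53))
  hit <- NULL
  for (i in seq_len(length(bytes) - 5)) {
    if (all(bytes[i:(i + 5)] == pat)) { hit <- i; break }
  }
  expect_false(is.null(hit))
  bytes[hit] <- as.raw(0x29)
  bad <- withr::local_tempfile(fileext = ".dcm")
  writeBin(bytes, bad)
  expect_error(read_volume(bad), "PixelSpacing")

  # series with an inconsistent slice gap
  d <- withr::local_tempdir()
  sl <- v; sl$data <- v$data[1, , , drop = FALSE]
  for (z in c(0, 1, 2.6)) {
    sl$origin[["z"]] <- z
    write_dicom(sl, file.path(d, sprintf("s%g.dcm", z)))
  }
  expect_error(read_volume(d), "spacing")
})

test_that("TIFF + JSON sidecar round-trips volumes and spacings", {
  v <- io_volume()
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, path, "tiff")
  v2 <- read_volume(path)
  expect_equal(unname(v2$spacing), c(1, 0.1, 0.1))
  expect_lt(max(abs(v2$data - v$data)) / diff(range(v$data)), 1e-6)
  file.remove(paste0(path, ".json"))
  expect_error(read_volume(path), "sidecar")
})

test_that("pydicom independently reads volumes written by the codec", {
  py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  skip_if(!nzchar(py), "no python interpreter on PATH")
  v <- io_volume()
  path <- withr::local_tempfile(fileext = ".dcm")
  write_volume(v, path, "dicom")
  out <- withr::local_tempfile(fileext = ".json")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "a = ds.pixel_array.astype(float)*float(ds.RescaleSlope)+float(ds.RescaleIntercept)",
    "res = dict(shape=list(a.shape), mean=float(a.mean()),",
    "           v000=float(a[0,0,0]), v123=float(a[1,2,3]),",
    "           spacing=[float(x) for x in ds.PixelSpacing],",
    "           sbs=float(ds.SpacingBetweenSlices))",
    "json.dump(res, open(sys.argv[2], 'w'))"), script)
  status <- system2(py, c(script, path, out))
  skip_if(status != 0, "pydicom unavailable")
  res <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(res$shape, unname(dim(v$data)))
  quantum <- (max(v$data) - min(v$data)) / 65535
  expect_equal(res$mean, mean(v$data), tolerance = 1e-4)
  expect_lt(abs(res$v000 - v$data[1, 1, 1]), quantum)
  expect_lt(abs(res$v123 - v$data[2, 3, 4]), quantum)
  expect_equal(res$spacing, c(0.1, 0.1))
  expect_equal(res$sbs, 1)
})

test_that("reports round-trip and rewrite byte-identically", {
  recs <- list(
    report_record("z_geometry", "mean_spacing", 10.01, "mm",
                  list(beads = 3), "ok"),
    report_record("uniformity", "global_uniformity", 0.42, "percent",
                  list(slice = 22)))
  rep <- qa_report(recs, provenance = list(config_hash = "abc"))
  stem <- file.path(withr::local_tempdir(), "report")
  paths <- write_report(rep, stem)
  back <- read_report(paths[["json"]])
  expect_length(back$records, 2L)
  expect_equal(back$records[[1]]$value, 10.01)
  expect_equal(back$records[[2]]$units, "percent")
  # identical rerun -> identical bytes
  stem2 <- file.path(withr::local_tempdir(), "report")
  paths2 <- write_report(rep, stem2)
  expect_identical(readBin(paths[["json"]], raw(), 1e6),
                   readBin(paths2[["json"]], raw(), 1e6))
  expect_identical(readLines(paths[["csv"]]), readLines(paths2[["csv"]]))
  # single-record report -> one JSON entry
  one <- qa_report(recs[1])
  p3 <- write_report(one, file.path(withr::local_tempdir(), "r1"))
  doc <- jsonlite::read_json(p3[["json"]])
  expect_length(doc$records, 1L)
  # units and provenance are mandatory
  expect_error(report_record("m", "n", 1, "", list(a = 1)), "units")
  expect_error(report_record("m", "n", 1, "mm", list()), "provenance")
})
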