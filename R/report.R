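# QA report: every computed metric with units, provenance (ROI and curve
# definitions) and an optional tolerance status, written as machine-readable
# JSON plus a fixed-column CSV.

#' Create a report record
#'
#' @param metric metric family (e.g. \code{"chest_wall"}).
#' @param name specific measurement name.
#' @param value numeric value(s).
#' @param units unit string (use \code{"ratio"}, \code{"percent"},
#'   \code{"mm"}, \code{"deg"}, ... -- never empty).
#' @param provenance named list describing ROIs/curves/slices used
#'   (must be non-empty).
#' @param status \code{"ok"}, \code{"warn"}, \code{"fail"} or \code{NA}
#'   when no tolerance applies.
#' @return An object of class \code{report_record}.
#' @export
report_record <- function(metric, name, value, units, provenance,
                          status = NA_character_) {
  if (!nzchar(units)) stopf("every report value needs units")
  if (!length(provenance)) stopf("provenance must be non-empty")
  r <- list(metric = metric, name = name, value = value, units = units,
            provenance = provenance, status = status)
  class(r) <- "report_record"
  r
}

#' Assemble a QA report
#'
#' @param records list of \code{report_record}s.
#' @param provenance named list of run-level provenance (config hash,
#'   geometry schema version, software version, optional timestamp).
#' @return An object of class \code{qa_report}.
#' @export
qa_report <- function(records, provenance = list()) {
  stopifnot(length(records) >= 1)
  provenance$software <- provenance$software %||%
    paste0("tomoqa ", as.character(utils::packageVersion("tomoqa")))
  rep <- list(records = records, provenance = provenance)
  class(rep) <- "qa_report"
  rep
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("QA report: %d records\n", length(x$records)))
  fams <- unique(vapply(x$records, function(r) r$metric, character(1)))
  for (f in fams) {
    recs <- Filter(function(r) r$metric == f, x$records)
    cat(sprintf("  %-18s", f))
    cat(paste(vapply(recs, function(r)
      sprintf("%s = %s %s", r$name,
              paste(signif(unlist(r$value), 4), collapse = ","),
              r$units), character(1)), collapse = "; "), "\n")
  }
  invisible(x)
}

report_to_df <- function(report) {
  rows <- lapply(report$records, function(r) {
    data.frame(metric = r$metric, name = r$name,
               value = paste(signif(unlist(r$value), 8), collapse = ";"),
               units = r$units,
               status = ifelse(is.na(r$status), "", r$status))
  })
  do.call(rbind, rows)
}

#' Write a QA report to disk
#'
#' Emits \code{<path>.json} (machine-readable, schema-versioned) and
#' \code{<path>.csv} (fixed column order: metric, name, value, units,
#' status). Re-running on identical input produces byte-identical files;
#' a timestamp is included only if supplied in the report provenance.
#'
#' @param report a \code{qa_report}.
#' @param path output path stem (no extension).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  doc <- list(schema = "tomoqa-report", schema_version = "1.0",
              provenance = report$provenance,
              records = lapply(report$records, unclass))
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(report_to_df(report), csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read back a QA report written by \code{\link{write_report}}
#' @param json_path path to the \code{.json} file.
#' @return A \code{qa_report}.
#' @export
read_report <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (!identical(doc$schema, "tomoqa-report"))
    stopf("not a tomoqa report: %s", json_path)
  records <- lapply(doc$records, function(r) {
    r$value <- unlist(r$value)
    r$status <- r$status %||% NA_character_
    class(r) <- "report_record"
    r
  })
  qa_report(records, provenance = doc$provenance)
}
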