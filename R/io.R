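#' Write a recording to the CSV + JSON-sidecar layout
#'
#' The on-disk layout is a plain-text pair: `<stem>.csv` holds the sample
#' table (`time` plus one column per channel and wavelength, named
#' `CH01_780`, ...); `<stem>.json` holds the metadata sidecar
#' (`schema_version`, `sample_rate`, `wavelengths`, `channels`, and the
#' `events` table with `onset`/`label`).
#'
#' @param od An `od_series` object.
#' @param path Output path; a `.csv` or `.json` extension is stripped and
#'   both files are written next to each other.
#' @return The stem path, invisibly.
#' @export
write_recording <- function(od, path) {
  stopifnot(inherits(od, "od_series"))
  stem <- sub("\\.(csv|json)$", "", path)
  utils::write.csv(od$data, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(schema_version = 1,
               sample_rate = od$sample_rate,
               wavelengths = od$wavelengths,
               channels = od$channels,
               events = as.data.frame(od$events))
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a recording from the CSV + JSON-sidecar layout
#'
#' Reads the pair written by [write_recording()], validates the declared
#' metadata, and normalizes the wavelength column order to (780, 805, 830)
#' regardless of the order in the file.
#'
#' @param path Path to either file of the pair (or the bare stem).
#' @return An `od_series` object.
#' @export
read_recording <- function(path) {
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    abort(paste0("Recording pair not found at stem '", stem, "'."))
  }
  meta <- tryCatch(jsonlite::read_json(json, simplifyVector = TRUE),
                   error = function(e) {
                     abort(paste0("Malformed metadata sidecar: ",
                                  conditionMessage(e)))
                   })
  for (field in c("sample_rate", "wavelengths", "channels", "events")) {
    if (is.null(meta[[field]])) {
      abort(paste0("Metadata sidecar is missing required field '",
                   field, "'."))
    }
  }
  dat <- tryCatch(as_tibble(utils::read.csv(csv, check.names = FALSE)),
                  error = function(e) {
                    abort(paste0("Malformed sample table: ",
                                 conditionMessage(e)))
                  })
  wl <- sort(as.integer(meta$wavelengths))
  if (!identical(wl, c(780L, 805L, 830L))) {
    abort("Recording must declare wavelengths {780, 805, 830} nm.")
  }
  wanted <- c("time",
              as.vector(t(outer(meta$channels, wl, paste, sep = "_"))))
  missing_cols <- setdiff(wanted, names(dat))
  if (length(missing_cols)) {
    abort(paste0("Sample table is missing column(s): ",
                 paste(head(missing_cols, 5), collapse = ", "), "."))
  }
  dat <- dat[, wanted]
  if (anyNA(dat) || !all(vapply(dat, is.numeric, logical(1)))) {
    abort("Sample table is truncated or contains non-numeric values.")
  }
  new_od_series(data = dat,
                sample_rate = meta$sample_rate,
                wavelengths = wl,
                channels = meta$channels,
                events = as_tibble(meta$events))
}
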