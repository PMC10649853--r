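#' Construct a CompoundProfile
#'
#' @param compound compound identifier.
#' @param data data.frame with columns `system`, `biomarker`,
#'   `readout_class`, `dose`, `log10_ratio`.
#' @param doseGrid the full tested concentration series; defaults to the
#'   doses present in `data`.
#' @return a validated [CompoundProfile-class].
#' @export
CompoundProfile <- function(compound, data, doseGrid = NULL) {
  data <- as.data.frame(data)[, .PROFILE_COLS]
  data$dose <- as.numeric(data$dose)
  data$log10_ratio <- as.numeric(data$log10_ratio)
  doses <- sort(unique(data$dose))
  if (is.null(doseGrid)) doseGrid <- doses
  data <- data[order(data$system, data$biomarker, data$dose), , drop = FALSE]
  rownames(data) <- NULL
  new("CompoundProfile", compound = as.character(compound), doses = doses,
      doseGrid = sort(as.numeric(doseGrid)), data = data)
}

#' Construct a VehicleControlSet
#'
#' @param data data.frame with columns `system`, `biomarker`, `log10_ratio`;
#'   one row per historical vehicle replicate.
#' @return a validated [VehicleControlSet-class].
#' @export
VehicleControlSet <- function(data) {
  data <- as.data.frame(data)[, c("system", "biomarker", "log10_ratio")]
  data$log10_ratio <- as.numeric(data$log10_ratio)
  rownames(data) <- NULL
  new("VehicleControlSet", data = data)
}

#' Construct a SignedActivitySet
#'
#' Entries are deduplicated on (system, biomarker, direction): the set has
#' order-free set semantics.
#'
#' @param compound compound identifier.
#' @param doseLabel a dose ("17 uM") or dose-range ("1.9-50 uM") label.
#' @param entries data.frame with columns `system`, `biomarker`, `direction`.
#' @return a validated [SignedActivitySet-class].
#' @export
SignedActivitySet <- function(compound, doseLabel = "", entries) {
  entries <- as.data.frame(entries)[, c("system", "biomarker", "direction")]
  entries <- unique(entries)
  entries <- entries[order(entries$system, entries$biomarker,
                           entries$direction), , drop = FALSE]
  rownames(entries) <- NULL
  new("SignedActivitySet", compound = as.character(compound),
      doseLabel = as.character(doseLabel), entries = entries)
}

#' Construct a HitCountTable
#'
#' @param compound compound identifier.
#' @param counts named numeric vector: names are doses (uM), values are
#'   non-negative hit counts; or a numeric vector with `doses` given.
#' @param doses doses, if `counts` is unnamed.
#' @return a validated [HitCountTable-class].
#' @export
HitCountTable <- function(compound, counts, doses = NULL) {
  if (is.null(doses)) doses <- as.numeric(names(counts))
  ord <- order(doses)
  new("HitCountTable", compound = as.character(compound),
      doses = as.numeric(doses)[ord],
      counts = as.integer(round(unname(counts)))[ord])
}

.stopParse <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

.readTsv <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  dat <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) .stopParse(path, 1L, conditionMessage(e))
  )
  if (!all(required %in% names(dat))) {
    .stopParse(path, 1L, sprintf(
      "malformed header; need columns: %s (found: %s)",
      paste(required, collapse = ", "), paste(names(dat), collapse = ", ")))
  }
  dat
}

#' Read a compound profile table
#'
#' The profile format is UTF-8 tab-separated values with header
#' `compound  system  biomarker  readout_class  dose_uM  log10_ratio`,
#' one row per readout per dose; lines starting with `#` are comments.
#' System ids and biomarker names are canonicalized on input; doses are
#' sorted ascending; duplicate (system, biomarker, dose) rows are an error.
#'
#' @param path path to a TSV file describing exactly one compound.
#' @param strict if TRUE, unknown system ids are an error.
#' @return a validated [CompoundProfile-class].
#' @seealso [writeProfileTable()]
#' @export
readProfileTable <- function(path, strict = FALSE) {
  cols <- c("compound", "system", "biomarker", "readout_class", "dose_uM",
            "log10_ratio")
  dat <- .readTsv(path, cols)
  if (nrow(dat) == 0L) .stopParse(path, 1L, "no data rows")
  if (length(unique(dat$compound)) != 1L) {
    .stopParse(path, 1L, sprintf("expected one compound, found: %s",
                                 paste(unique(dat$compound), collapse = ", ")))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(dat$dose_uM))))
  if (length(bad)) {
    .stopParse(path, bad[1L] + 1L, paste0("non-numeric dose: ",
                                          dat$dose_uM[bad[1L]]))
  }
  num <- suppressWarnings(as.numeric(dat$log10_ratio))
  # NA is a legitimate explicit gap; anything else non-numeric is an error
  bad <- which(is.na(num) & !is.na(dat$log10_ratio) &
                 !(as.character(dat$log10_ratio) %in% c("NA", "")))
  if (length(bad)) {
    .stopParse(path, bad[1L] + 1L, paste0("non-numeric log10 ratio: ",
                                          dat$log10_ratio[bad[1L]]))
  }
  sys <- canonicalSystem(dat$system, strict = strict)
  bm <- canonicalBiomarker(dat$biomarker, system = sys)
  key <- paste(sys, bm, dat$dose_uM, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    .stopParse(path, i + 1L, sprintf(
      "duplicate row for (%s, %s, %s uM)", sys[i], bm[i], dat$dose_uM[i]))
  }
  CompoundProfile(
    compound = dat$compound[1L],
    data = data.frame(system = sys, biomarker = bm,
                      readout_class = dat$readout_class,
                      dose = as.numeric(dat$dose_uM), log10_ratio = num,
                      stringsAsFactors = FALSE)
  )
}

#' Write a compound profile table
#'
#' Writes the TSV profile format read by [readProfileTable()]; reading the
#' file back yields a value-for-value identical profile.
#'
#' @param profile a [CompoundProfile-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProfileTable <- function(profile, path) {
  stopifnot(is(profile, "CompoundProfile"))
  dat <- profile@data
  out <- data.frame(compound = profile@compound, system = dat$system,
                    biomarker = dat$biomarker,
                    readout_class = dat$readout_class,
                    dose_uM = dat$dose, log10_ratio = dat$log10_ratio,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read historical vehicle-control readouts
#'
#' TSV with header `system  biomarker  log10_ratio`, one row per historical
#' vehicle replicate.
#'
#' @param path path to the controls TSV.
#' @param strict if TRUE, unknown system ids are an error.
#' @return a validated [VehicleControlSet-class].
#' @export
readControlTable <- function(path, strict = FALSE) {
  dat <- .readTsv(path, c("system", "biomarker", "log10_ratio"))
  num <- suppressWarnings(as.numeric(dat$log10_ratio))
  bad <- which(!is.finite(num))
  if (length(bad)) {
    .stopParse(path, bad[1L] + 1L, paste0("non-finite control value: ",
                                          dat$log10_ratio[bad[1L]]))
  }
  VehicleControlSet(data.frame(
    system = canonicalSystem(dat$system, strict = strict),
    biomarker = canonicalBiomarker(dat$biomarker, system = dat$system),
    log10_ratio = num, stringsAsFactors = FALSE))
}

#' Write historical vehicle-control readouts
#'
#' @param controls a [VehicleControlSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeControlTable <- function(controls, path) {
  stopifnot(is(controls, "VehicleControlSet"))
  utils::write.table(controls@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
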