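#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes; prefer these
#' over direct slot access.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return `compoundName` the compound identifier; `doses` the concentration
#'   grid; `profileData` the long-format readout table; `activityEntries` the
#'   (system, biomarker, direction) entries of a signature; `nMatches` the
#'   number of direction-matched shared activities of a report.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundName", function(x) standardGeneric("compoundName"))

#' @rdname accessors
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' @rdname accessors
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))

#' @rdname accessors
#' @export
setGeneric("activityEntries", function(x) standardGeneric("activityEntries"))

#' @rdname accessors
#' @export
setGeneric("nMatches", function(x) standardGeneric("nMatches"))

#' Look up envelope half-widths
#'
#' @param x an [EnvelopeSet-class].
#' @param system,biomarker character vectors (recycled to common length).
#' @return numeric vector of half-widths; readouts without control history get
#'   the set's default half-width.
#' @export
setGeneric("halfWidth", function(x, system, biomarker)
  standardGeneric("halfWidth"))

#' @rdname accessors
setMethod("compoundName", "CompoundProfile", function(x) x@compound)
#' @rdname accessors
setMethod("compoundName", "SignedActivitySet", function(x) x@compound)
#' @rdname accessors
setMethod("compoundName", "HitCountTable", function(x) x@compound)

#' @rdname accessors
setMethod("doses", "CompoundProfile", function(x) x@doses)
#' @rdname accessors
setMethod("doses", "HitCountTable", function(x) x@doses)
#' @rdname accessors
setMethod("doses", "PanelSpec", function(x) x@doses)

#' @rdname accessors
setMethod("profileData", "CompoundProfile", function(x) x@data)
#' @rdname accessors
setMethod("profileData", "VehicleControlSet", function(x) x@data)

#' @rdname accessors
setMethod("activityEntries", "SignedActivitySet", function(x) x@entries)
#' @rdname accessors
setMethod("activityEntries", "SharedActivityReport", function(x) x@matches)

#' @rdname accessors
setMethod("nMatches", "SharedActivityReport", function(x) x@nMatches)

setMethod("show", "CompoundProfile", function(object) {
  dat <- object@data
  nr <- length(unique(paste(dat$system, dat$biomarker, sep = "\r")))
  cat("CompoundProfile:", object@compound, "\n")
  cat("  ", nr, " readouts across ", length(unique(dat$system)),
      " systems\n", sep = "")
  cat("  doses (uM):", paste(object@doses, collapse = ", "))
  if (length(object@doses) < length(object@doseGrid)) {
    cat("  [of tested grid:", paste(object@doseGrid, collapse = ", "), "]")
  }
  cat("\n")
})

setMethod("show", "VehicleControlSet", function(object) {
  dat <- object@data
  cat("VehicleControlSet:",
      length(unique(paste(dat$system, dat$biomarker, sep = "\r"))),
      "readouts,", nrow(dat), "historical replicates\n")
})

setMethod("show", "EnvelopeSet", function(object) {
  cat("EnvelopeSet (", object@method, " method, ",
      format(100 * object@confidence), "% coverage)\n", sep = "")
  cat("  ", nrow(object@table), " readout-specific envelopes; default",
      " half-width ", format(object@defaultHalfWidth), "\n", sep = "")
})

setMethod("show", "SignedActivitySet", function(object) {
  cat("SignedActivitySet:", object@compound, "@", object@doseLabel, "\n")
  cat("  ", nrow(object@entries), " signed activities in ",
      length(unique(object@entries$system)), " systems\n", sep = "")
})

setMethod("show", "HitCountTable", function(object) {
  cat("HitCountTable:", object@compound, "\n")
  print(stats::setNames(object@counts, paste0(object@doses, " uM")))
})

setMethod("show", "SharedActivityReport", function(object) {
  cat("SharedActivityReport: ", object@compoundA, " @ ", object@doseLabelA,
      "  vs  ", object@compoundB, " @ ", object@doseLabelB, "\n", sep = "")
  cat("  ", object@nMatches, " direction-matched shared activities across ",
      length(object@systemsWithMatches), " systems (",
      round(100 * object@systemsFraction), "%)\n", sep = "")
})

setMethod("show", "AnnotationConfig", function(object) {
  cat("AnnotationConfig\n")
  cat("  effect-size threshold (|log10 ratio|):", object@effectSizeThreshold, "\n")
  cat("  min consecutive doses:", object@minConsecutive, "\n")
  cat("  cytotoxic / antiproliferative below:", object@cytotoxThreshold, "/",
      object@antiproliferativeThreshold, "\n")
  cat("  broad cytotoxicity at >=", object@broadCytotoxMinSystems, "systems\n")
})

setMethod("show", "PanelSpec", function(object) {
  cat("PanelSpec:", object@nSystems, "systems x",
      object@biomarkersPerSystem, "biomarkers",
      if (object@viability) "(+ SRB)", "x",
      length(object@doses), "doses; noise sd", object@noiseSd,
      "; seed", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@effects), "injected effects,",
      nrow(object@expected), "expected annotations (envelope half-width",
      format(object@halfWidth), ")\n")
})
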