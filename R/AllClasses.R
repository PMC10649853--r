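#' @import methods
NULL

.PROFILE_COLS <- c("system", "biomarker", "readout_class", "dose", "log10_ratio")
.READOUT_CLASSES <- c("soluble", "cell_associated", "proliferation", "viability")

#' CompoundProfile: a compound's dose x system x biomarker matrix
#'
#' Holds the full phenotypic profile of one compound: for every measured
#' (cell system, biomarker) readout, a log10 ratio of the treated readout
#' against vehicle control at each tested concentration. Values live on the
#' log10-ratio scale throughout; 0 means no change from vehicle.
#'
#' The `doseGrid` slot keeps the originally tested concentration series even
#' after doses have been removed (e.g. by broad-cytotoxicity exclusion), so
#' that "consecutive concentrations" always refers to adjacency in the tested
#' series: a removed interior dose breaks adjacency for run finding.
#'
#' @slot compound single compound identifier.
#' @slot doses numeric, strictly ascending retained concentrations (uM).
#' @slot doseGrid numeric, the full tested concentration series (uM).
#' @slot data data.frame with columns `system`, `biomarker`, `readout_class`,
#'   `dose`, `log10_ratio`; one row per readout per retained dose.
#'
#' @seealso [readProfileTable()], [annotateActivities()]
#' @export
setClass("CompoundProfile",
  slots = c(
    compound = "character",
    doses = "numeric",
    doseGrid = "numeric",
    data = "data.frame"
  )
)

setValidity("CompoundProfile", function(object) {
  msg <- character()
  if (length(object@compound) != 1L || is.na(object@compound) ||
      !nzchar(object@compound)) {
    msg <- c(msg, "'compound' must be a single non-empty string")
  }
  d <- object@doses
  if (anyNA(d) || is.unsorted(d, strictly = TRUE)) {
    msg <- c(msg, "'doses' must be finite and strictly ascending")
  }
  if (!all(d %in% object@doseGrid)) {
    msg <- c(msg, "'doses' must be a subset of 'doseGrid'")
  }
  if (is.unsorted(object@doseGrid, strictly = TRUE)) {
    msg <- c(msg, "'doseGrid' must be strictly ascending")
  }
  dat <- object@data
  if (!all(.PROFILE_COLS %in% names(dat))) {
    msg <- c(msg, sprintf("'data' must have columns: %s",
                          paste(.PROFILE_COLS, collapse = ", ")))
  } else if (nrow(dat) > 0L) {
    if (!all(dat$dose %in% d)) {
      msg <- c(msg, "'data' contains doses not listed in 'doses'")
    }
    if (!all(dat$readout_class %in% .READOUT_CLASSES)) {
      msg <- c(msg, sprintf("'readout_class' must be one of: %s",
                            paste(.READOUT_CLASSES, collapse = ", ")))
    }
    key <- paste(dat$system, dat$biomarker, dat$dose, sep = "\r")
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicate (system, biomarker, dose) rows")
    }
    # every readout present must cover every retained dose (gaps are explicit
    # NA values, never silently missing rows)
    nd <- tapply(dat$dose, paste(dat$system, dat$biomarker, sep = "\r"),
                 function(x) length(unique(x)))
    if (any(nd != length(d))) {
      msg <- c(msg, "every (system, biomarker) must have a row for every dose")
    }
  }
  if (length(msg)) msg else TRUE
})

#' VehicleControlSet: historical vehicle-control readouts
#'
#' Log10 ratios of historical vehicle-control wells (nominally centered at 0)
#' per (system, biomarker) readout, from which per-readout significance
#' envelopes are estimated.
#'
#' @slot data data.frame with columns `system`, `biomarker`, `log10_ratio`;
#'   one row per historical replicate.
#' @export
setClass("VehicleControlSet", slots = c(data = "data.frame"))

setValidity("VehicleControlSet", function(object) {
  dat <- object@data
  need <- c("system", "biomarker", "log10_ratio")
  if (!all(need %in% names(dat))) {
    return(sprintf("'data' must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(dat) > 0L && !all(is.finite(dat$log10_ratio))) {
    return("control log10 ratios must all be finite")
  }
  TRUE
})

#' EnvelopeSet: per-readout significance envelopes
#'
#' The significance envelope of a readout is the symmetric interval
#' [-half_width, +half_width] around 0 on the log10-ratio scale, covering the
#' stated fraction (default 95%) of the historical vehicle-control
#' distribution. Readouts falling inside it are treated as noise.
#'
#' @slot table data.frame with columns `system`, `biomarker`, `half_width`,
#'   `n_controls`; one row per readout with control history.
#' @slot method "normal" (z x sample SD) or "empirical" (symmetrized sample
#'   quantiles).
#' @slot confidence coverage level in (0, 1).
#' @slot defaultHalfWidth half-width used for readouts without control history.
#' @seealso [estimateEnvelopes()], [halfWidth()], [classifyReadout()]
#' @export
setClass("EnvelopeSet",
  slots = c(
    table = "data.frame",
    method = "character",
    confidence = "numeric",
    defaultHalfWidth = "numeric"
  )
)

setValidity("EnvelopeSet", function(object) {
  msg <- character()
  need <- c("system", "biomarker", "half_width", "n_controls")
  if (!all(need %in% names(object@table))) {
    msg <- c(msg, sprintf("'table' must have columns: %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(object@table) > 0L) {
    if (any(object@table$half_width < 0, na.rm = TRUE)) {
      msg <- c(msg, "half-widths must be non-negative")
    }
    if (anyDuplicated(paste(object@table$system, object@table$biomarker,
                            sep = "\r"))) {
      msg <- c(msg, "one envelope per (system, biomarker)")
    }
  }
  if (!object@method %in% c("normal", "empirical")) {
    msg <- c(msg, "'method' must be \"normal\" or \"empirical\"")
  }
  if (object@confidence <= 0 || object@confidence >= 1) {
    msg <- c(msg, "'confidence' must be in (0, 1)")
  }
  if (length(object@defaultHalfWidth) != 1L || object@defaultHalfWidth < 0) {
    msg <- c(msg, "'defaultHalfWidth' must be a single non-negative value")
  }
  if (length(msg)) msg else TRUE
})

#' SignedActivitySet: a compound's signed activity signature
#'
#' A set of (system, canonical biomarker, direction) entries for one compound
#' at one dose or dose range: the unit of cross-compound comparison. Entries
#' have set semantics (order-free, no duplicate triples). The same
#' (system, biomarker) pair may appear with both directions, as happens for
#' U-shaped responses crossing zero.
#'
#' @slot compound compound identifier.
#' @slot doseLabel a single dose ("17 uM") or a range ("1.9-50 uM").
#' @slot entries data.frame with columns `system`, `biomarker`, `direction`
#'   (each "up" or "down").
#' @seealso [activitySet()], [sharedActivities()]
#' @export
setClass("SignedActivitySet",
  slots = c(
    compound = "character",
    doseLabel = "character",
    entries = "data.frame"
  )
)

setValidity("SignedActivitySet", function(object) {
  msg <- character()
  if (length(object@compound) != 1L || !nzchar(object@compound)) {
    msg <- c(msg, "'compound' must be a single non-empty string")
  }
  e <- object@entries
  need <- c("system", "biomarker", "direction")
  if (!all(need %in% names(e))) {
    msg <- c(msg, sprintf("'entries' must have columns: %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(e) > 0L) {
    if (!all(e$direction %in% c("up", "down"))) {
      msg <- c(msg, "'direction' must be \"up\" or \"down\"")
    }
    if (anyDuplicated(paste(e$system, e$biomarker, e$direction, sep = "\r"))) {
      msg <- c(msg, "duplicate (system, biomarker, direction) entries")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HitCountTable: biomarker hit counts per dose
#'
#' The number of single-dose biomarker hits of a compound at each tested
#' concentration; the input to optimal-dose determination.
#'
#' @slot compound compound identifier.
#' @slot doses numeric, strictly ascending concentrations (uM).
#' @slot counts non-negative integer hit count per dose.
#' @seealso [optimalDose()]
#' @export
setClass("HitCountTable",
  slots = c(compound = "character", doses = "numeric", counts = "integer")
)

setValidity("HitCountTable", function(object) {
  msg <- character()
  if (length(object@doses) != length(object@counts)) {
    msg <- c(msg, "'doses' and 'counts' must have equal length")
  }
  if (length(object@doses) < 1L) msg <- c(msg, "table must be non-empty")
  if (is.unsorted(object@doses, strictly = TRUE)) {
    msg <- c(msg, "'doses' must be strictly ascending")
  }
  if (any(object@counts < 0L)) msg <- c(msg, "'counts' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AnnotationConfig: thresholds of the activity-calling rules
#'
#' All thresholds act on the log10-ratio scale and all comparators are strict,
#' so boundary values never qualify.
#'
#' @slot effectSizeThreshold minimum |log10 ratio| (default 0.1, i.e. a >20%
#'   effect) that at least one concentration of a run (and any single-dose
#'   hit) must exceed.
#' @slot minConsecutive minimum number of consecutive same-direction
#'   outside-envelope concentrations for a dose-dependent activity (default 2).
#' @slot cytotoxThreshold viability (SRB/alamarBlue) log10 ratio below which a
#'   condition is cytotoxic (default -0.3, i.e. >50% loss of total protein).
#' @slot antiproliferativeThreshold low-density proliferation-context readout
#'   log10 ratio below which a condition is antiproliferative (default -0.1).
#' @slot broadCytotoxMinSystems number of distinct systems with cytotoxicity
#'   at one concentration that makes it broadly cytotoxic (default 3); such
#'   concentrations are excluded from annotation.
#' @slot includeViability whether viability readouts themselves are eligible
#'   as hits/activities (default TRUE; reference signatures list SRB entries).
#' @seealso [annotationConfig()]
#' @export
setClass("AnnotationConfig",
  slots = c(
    effectSizeThreshold = "numeric",
    minConsecutive = "integer",
    cytotoxThreshold = "numeric",
    antiproliferativeThreshold = "numeric",
    broadCytotoxMinSystems = "integer",
    includeViability = "logical"
  )
)

setValidity("AnnotationConfig", function(object) {
  msg <- character()
  if (object@effectSizeThreshold <= 0) {
    msg <- c(msg, "'effectSizeThreshold' must be > 0")
  }
  if (object@minConsecutive < 2L) msg <- c(msg, "'minConsecutive' must be >= 2")
  if (!(object@cytotoxThreshold < object@antiproliferativeThreshold &&
        object@antiproliferativeThreshold < 0)) {
    msg <- c(msg, "need cytotoxThreshold < antiproliferativeThreshold < 0")
  }
  if (object@broadCytotoxMinSystems < 1L) {
    msg <- c(msg, "'broadCytotoxMinSystems' must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' SharedActivityReport: direction-matched overlap of two signatures
#'
#' Matches are entries equal in (system, canonical biomarker, direction);
#' opposite directions on the same readout never match. Symmetric in the two
#' compounds.
#'
#' @slot compoundA,compoundB compound identifiers.
#' @slot doseLabelA,doseLabelB dose labels of the two signatures.
#' @slot matches data.frame of matching (system, biomarker, direction) rows.
#' @slot nMatches number of matches.
#' @slot systemsWithMatches distinct systems among the matches.
#' @slot systemsFraction |systemsWithMatches| / panel size.
#' @seealso [sharedActivities()]
#' @export
setClass("SharedActivityReport",
  slots = c(
    compoundA = "character", compoundB = "character",
    doseLabelA = "character", doseLabelB = "character",
    matches = "data.frame",
    nMatches = "integer",
    systemsWithMatches = "character",
    systemsFraction = "numeric"
  )
)

#' PanelSpec: layout and noise model of a synthetic screening panel
#'
#' Defaults emulate the reference panel: 12 cell systems with 12 biomarker
#' readouts each (~148 readouts in total), 4 ascending doses, vehicle noise
#' of 0.025 on the log10 scale and 100 historical control replicates per
#' readout.
#'
#' @slot nSystems number of cell systems.
#' @slot biomarkersPerSystem soluble biomarker readouts per system.
#' @slot doses strictly ascending concentrations (uM).
#' @slot noiseSd standard deviation of vehicle noise (log10-ratio units).
#' @slot controlReplicates historical vehicle replicates per readout.
#' @slot viability whether each system also carries an SRB viability readout.
#' @slot seed integer seed governing all random draws.
#' @seealso [panelSpec()], [generateControls()], [generateProfile()]
#' @export
setClass("PanelSpec",
  slots = c(
    nSystems = "integer",
    biomarkersPerSystem = "integer",
    doses = "numeric",
    noiseSd = "numeric",
    controlReplicates = "integer",
    viability = "logical",
    seed = "integer"
  )
)

setValidity("PanelSpec", function(object) {
  msg <- character()
  if (object@nSystems < 1L) msg <- c(msg, "'nSystems' must be positive")
  if (object@biomarkersPerSystem < 1L) {
    msg <- c(msg, "'biomarkersPerSystem' must be positive")
  }
  if (length(object@doses) < 2L ||
      is.unsorted(object@doses, strictly = TRUE)) {
    msg <- c(msg, "'doses' must be >= 2 strictly ascending values")
  }
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@controlReplicates < 2L) {
    msg <- c(msg, "'controlReplicates' must be >= 2")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth of a simulated panel
#'
#' Records the injected effects and the annotations the pipeline is expected
#' to recover from the noise-free signal under a stated envelope half-width,
#' for sensitivity/specificity evaluation.
#'
#' @slot effects data.frame of injected effects (`system`, `biomarker`,
#'   `shape`, `amplitude`, `onset`).
#' @slot expected data.frame of expected annotations (`system`, `biomarker`,
#'   `direction`).
#' @slot halfWidth the envelope half-width under which `expected` was derived.
#' @seealso [generateProfile()], [evaluateRecovery()]
#' @export
setClass("SyntheticTruth",
  slots = c(
    effects = "data.frame",
    expected = "data.frame",
    halfWidth = "numeric"
  )
)
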