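#' Create an annotation configuration
#'
#' Thresholds of the activity-calling rules, all on the log10-ratio scale and
#' all compared strictly (boundary values never qualify). See
#' [AnnotationConfig-class] for the meaning of each field.
#'
#' @param effectSizeThreshold default 0.1 (a >20% effect).
#' @param minConsecutive default 2.
#' @param cytotoxThreshold default -0.3 (>50% viability loss).
#' @param antiproliferativeThreshold default -0.1.
#' @param broadCytotoxMinSystems default 3.
#' @param includeViability default TRUE.
#' @return an [AnnotationConfig-class].
#' @export
annotationConfig <- function(effectSizeThreshold = 0.1,
                             minConsecutive = 2L,
                             cytotoxThreshold = -0.3,
                             antiproliferativeThreshold = -0.1,
                             broadCytotoxMinSystems = 3L,
                             includeViability = TRUE) {
  new("AnnotationConfig",
      effectSizeThreshold = effectSizeThreshold,
      minConsecutive = as.integer(minConsecutive),
      cytotoxThreshold = cytotoxThreshold,
      antiproliferativeThreshold = antiproliferativeThreshold,
      broadCytotoxMinSystems = as.integer(broadCytotoxMinSystems),
      includeViability = includeViability)
}

# annotate/hit-eligible rows: optionally drop viability channels
.eligibleRows <- function(dat, cfg) {
  if (cfg@includeViability) dat else dat[dat$readout_class != "viability", ,
                                         drop = FALSE]
}

#' Call single-dose biomarker hits
#'
#' A hit is a single (system, biomarker, dose) measurement that is both
#' outside the significance envelope and larger than the effect-size
#' threshold in absolute value (strictly). The direction comes from the
#' envelope classification.
#'
#' @param profile a [CompoundProfile-class] (with broadly cytotoxic doses
#'   already excluded, if exclusion is applied).
#' @param envelopes an [EnvelopeSet-class].
#' @param cfg an [AnnotationConfig-class].
#' @return data.frame with columns `system`, `biomarker`, `dose`,
#'   `direction`, `log10_ratio`.
#' @seealso [annotateActivities()] for the dose-dependent tier.
#' @export
callHits <- function(profile, envelopes, cfg = annotationConfig()) {
  stopifnot(is(profile, "CompoundProfile"), is(envelopes, "EnvelopeSet"),
            is(cfg, "AnnotationConfig"))
  dat <- .eligibleRows(profile@data, cfg)
  if (nrow(dat) == 0L) return(.emptyHits())
  hw <- halfWidth(envelopes, dat$system, dat$biomarker)
  cls <- classifyReadout(dat$log10_ratio, hw)
  sel <- !is.na(cls) & cls != "inside" &
    abs(dat$log10_ratio) > cfg@effectSizeThreshold
  out <- data.frame(system = dat$system[sel], biomarker = dat$biomarker[sel],
                    dose = dat$dose[sel], direction = cls[sel],
                    log10_ratio = dat$log10_ratio[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.emptyHits <- function() {
  data.frame(system = character(), biomarker = character(), dose = numeric(),
             direction = character(), log10_ratio = numeric(),
             stringsAsFactors = FALSE)
}

.emptyActivities <- function() {
  data.frame(system = character(), biomarker = character(),
             direction = character(), supporting_doses = character(),
             n_supporting = integer(), max_abs_log10_ratio = numeric(),
             stringsAsFactors = FALSE)
}

#' Annotate dose-dependent activities
#'
#' For each (system, biomarker) readout, each retained dose is classified
#' against the envelope as up/down/inside; an activity is emitted for every
#' maximal run of at least `minConsecutive` adjacent doses sharing one
#' non-inside direction, provided the largest |log10 ratio| over the run
#' strictly exceeds the effect-size threshold. Adjacency refers to the
#' originally tested dose grid, so a removed (excluded) interior dose breaks
#' a run. At most one activity is reported per (system, biomarker,
#' direction); if several disjoint qualifying runs share a direction, the one
#' with the largest peak effect (earliest run on ties) is kept.
#'
#' @inheritParams callHits
#' @return data.frame with columns `system`, `biomarker`, `direction`,
#'   `supporting_doses` (comma-separated uM values), `n_supporting`,
#'   `max_abs_log10_ratio`.
#' @examples
#' prof <- CompoundProfile("ex", data.frame(
#'   system = "3C", biomarker = "MCP-1", readout_class = "soluble",
#'   dose = c(1.9, 5.6, 17, 50), log10_ratio = c(0.02, 0.12, 0.15, 0.08)))
#' env <- new("EnvelopeSet",
#'   table = data.frame(system = character(), biomarker = character(),
#'                      half_width = numeric(), n_controls = integer()),
#'   method = "normal", confidence = 0.95, defaultHalfWidth = 0.05)
#' annotateActivities(prof, env)
#' @export
annotateActivities <- function(profile, envelopes, cfg = annotationConfig()) {
  stopifnot(is(profile, "CompoundProfile"), is(envelopes, "EnvelopeSet"),
            is(cfg, "AnnotationConfig"))
  dat <- .eligibleRows(profile@data, cfg)
  if (nrow(dat) == 0L) return(.emptyActivities())

  pos <- match(dat$dose, profile@doseGrid)
  ord <- order(dat$system, dat$biomarker, pos)
  dat <- dat[ord, , drop = FALSE]
  pos <- pos[ord]

  hw <- halfWidth(envelopes, dat$system, dat$biomarker)
  cls <- classifyReadout(dat$log10_ratio, hw)
  cls[is.na(cls)] <- "gap"

  # vectorized maximal-run segmentation: a new run starts at a readout
  # change, a classification change, or a dose-grid adjacency break
  grp <- paste(dat$system, dat$biomarker, sep = "\r")
  n <- nrow(dat)
  newrun <- c(TRUE, grp[-1L] != grp[-n] | cls[-1L] != cls[-n] |
                pos[-1L] != pos[-n] + 1L)
  runid <- cumsum(newrun)

  runlen <- tabulate(runid)
  first <- which(newrun)
  runcls <- cls[first]
  keep <- runcls %in% c("up", "down") & runlen[runid[first]] >= cfg@minConsecutive
  if (!any(keep)) return(.emptyActivities())

  maxabs <- vapply(split(abs(dat$log10_ratio), runid), max, numeric(1))
  kidx <- which(keep)
  runs <- data.frame(
    system = dat$system[first[kidx]],
    biomarker = dat$biomarker[first[kidx]],
    direction = runcls[kidx],
    start = first[kidx],
    len = runlen[runid[first[kidx]]],
    max_abs_log10_ratio = unname(maxabs[as.character(runid[first[kidx]])]),
    stringsAsFactors = FALSE
  )
  runs <- runs[runs$max_abs_log10_ratio > cfg@effectSizeThreshold, ,
               drop = FALSE]
  if (nrow(runs) == 0L) return(.emptyActivities())

  # one activity per (system, biomarker, direction): strongest run wins,
  # earliest on ties
  runs <- runs[order(runs$system, runs$biomarker, runs$direction,
                     -runs$max_abs_log10_ratio, runs$start), , drop = FALSE]
  dup <- duplicated(paste(runs$system, runs$biomarker, runs$direction,
                          sep = "\r"))
  runs <- runs[!dup, , drop = FALSE]

  runs$supporting_doses <- vapply(seq_len(nrow(runs)), function(i) {
    paste(dat$dose[runs$start[i] + seq_len(runs$len[i]) - 1L], collapse = ",")
  }, character(1))
  out <- data.frame(system = runs$system, biomarker = runs$biomarker,
                    direction = runs$direction,
                    supporting_doses = runs$supporting_doses,
                    n_supporting = as.integer(runs$len),
                    max_abs_log10_ratio = runs$max_abs_log10_ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(out$system, out$biomarker, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag cytotoxic and antiproliferative conditions
#'
#' A (system, dose) condition is flagged cytotoxic when a viability readout
#' (SRB or alamarBlue) has a log10 ratio strictly below the cytotoxicity
#' threshold (-0.3, i.e. more than 50% loss of total protein), and
#' antiproliferative when a proliferation-context readout (cells plated at
#' low density) falls strictly below -0.1. A single qualifying concentration
#' suffices for a flag.
#'
#' @inheritParams callHits
#' @return data.frame with columns `system`, `dose`, `kind` ("cytotoxic" or
#'   "antiproliferative"), `log10_ratio` (the most extreme qualifying value).
#' @export
flagCytotoxicity <- function(profile, cfg = annotationConfig()) {
  stopifnot(is(profile, "CompoundProfile"), is(cfg, "AnnotationConfig"))
  dat <- profile@data
  empty <- data.frame(system = character(), dose = numeric(),
                      kind = character(), log10_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(dat$readout_class %in% c("viability", "proliferation"))) {
    message("profile has no viability or proliferation readouts; ",
            "no cytotoxicity flags can be assessed")
    return(empty)
  }
  pick <- function(class, threshold, kind) {
    d <- dat[dat$readout_class == class & !is.na(dat$log10_ratio) &
               dat$log10_ratio < threshold, , drop = FALSE]
    if (nrow(d) == 0L) return(empty)
    agg <- stats::aggregate(log10_ratio ~ system + dose, data = d, FUN = min)
    data.frame(system = agg$system, dose = agg$dose, kind = kind,
               log10_ratio = agg$log10_ratio, stringsAsFactors = FALSE)
  }
  out <- rbind(pick("viability", cfg@cytotoxThreshold, "cytotoxic"),
               pick("proliferation", cfg@antiproliferativeThreshold,
                    "antiproliferative"))
  out <- out[order(out$kind, out$system, out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude broadly cytotoxic doses from a profile
#'
#' A concentration is broadly cytotoxic when cytotoxicity is flagged in at
#' least `broadCytotoxMinSystems` distinct systems at that concentration.
#' Such concentrations are removed from the profile before hit calling and
#' annotation. Remaining doses keep their position on the original tested
#' grid, so a removed interior dose breaks consecutiveness for run finding.
#'
#' @param profile a [CompoundProfile-class].
#' @param flags output of [flagCytotoxicity()] on the same profile.
#' @param cfg an [AnnotationConfig-class].
#' @return list with elements `profile` (doses removed) and `excludedDoses`
#'   (numeric, possibly empty).
#' @export
applyBroadCytotoxExclusion <- function(profile, flags,
                                       cfg = annotationConfig()) {
  stopifnot(is(profile, "CompoundProfile"), is(cfg, "AnnotationConfig"))
  cyto <- flags[flags$kind == "cytotoxic", , drop = FALSE]
  if (nrow(cyto) == 0L) {
    return(list(profile = profile, excludedDoses = numeric()))
  }
  nsys <- tapply(cyto$system, cyto$dose, function(s) length(unique(s)))
  excl <- as.numeric(names(nsys))[nsys >= cfg@broadCytotoxMinSystems]
  if (length(excl) == 0L) {
    return(list(profile = profile, excludedDoses = numeric()))
  }
  keep <- !(profile@data$dose %in% excl)
  if (!any(keep)) {
    warning("all doses of ", profile@compound,
            " are broadly cytotoxic; returning an empty profile",
            call. = FALSE)
  }
  out <- new("CompoundProfile", compound = profile@compound,
             doses = setdiff(profile@doses, excl),
             doseGrid = profile@doseGrid,
             data = profile@data[keep, , drop = FALSE])
  list(profile = out, excludedDoses = sort(excl))
}

#' Modulated biomarkers
#'
#' A biomarker is modulated when its annotated activities increase in some
#' systems but decrease in others: it must carry an up activity in one system
#' and a down activity in a *different* system.
#'
#' @param activities data.frame as returned by [annotateActivities()].
#' @return character vector of modulated canonical biomarker names.
#' @export
labelModulated <- function(activities) {
  if (nrow(activities) == 0L) return(character())
  mods <- vapply(split(activities, activities$biomarker), function(d) {
    up <- unique(d$system[d$direction == "up"])
    dn <- unique(d$system[d$direction == "down"])
    length(up) > 0L && length(dn) > 0L && length(union(up, dn)) >= 2L
  }, logical(1))
  sort(names(mods)[mods])
}
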