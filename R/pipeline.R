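.CONFIG_DEFAULTS <- list(
  envelope.method = "normal",
  envelope.confidence = 0.95,
  envelope.default_half_width = 0.1,
  annotation.effect_size_threshold = 0.1,
  annotation.min_consecutive = 2L,
  annotation.cytotox_threshold = -0.3,
  annotation.antiproliferative_threshold = -0.1,
  annotation.broad_cytotox_min_systems = 3L,
  annotation.include_viability = TRUE,
  tie_break = "lowest",
  seed = 1L,
  verbose = FALSE
)

#' Resolve a run configuration
#'
#' Flat key-value configuration for the pipeline entry points. Precedence is
#' defaults < config file < direct arguments. The resolved configuration is
#' serialized into every run's machine-readable summary, so identical
#' configurations and inputs give byte-identical outputs.
#'
#' @param configFile optional path to a YAML file with any of the keys of
#'   the defaults (see Details).
#' @param ... individual key overrides, e.g. `envelope.method = "empirical"`.
#' @return named list with class `"phenoscreenConfig"`.
#' @details Keys and defaults: `envelope.method` ("normal"),
#'   `envelope.confidence` (0.95), `envelope.default_half_width` (0.1),
#'   `annotation.effect_size_threshold` (0.1), `annotation.min_consecutive`
#'   (2), `annotation.cytotox_threshold` (-0.3),
#'   `annotation.antiproliferative_threshold` (-0.1),
#'   `annotation.broad_cytotox_min_systems` (3),
#'   `annotation.include_viability` (TRUE), `tie_break` ("lowest"), `seed`
#'   (1), `verbose` (FALSE).
#' @export
runConfig <- function(configFile = NULL, ...) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) {
      stop("config file not found: ", configFile, call. = FALSE)
    }
    fromFile <- yaml::read_yaml(configFile)
    bad <- setdiff(names(fromFile), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(fromFile)] <- fromFile
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "phenoscreenConfig")
}

.annotationConfigFrom <- function(cfg) {
  annotationConfig(
    effectSizeThreshold = cfg$annotation.effect_size_threshold,
    minConsecutive = cfg$annotation.min_consecutive,
    cytotoxThreshold = cfg$annotation.cytotox_threshold,
    antiproliferativeThreshold = cfg$annotation.antiproliferative_threshold,
    broadCytotoxMinSystems = cfg$annotation.broad_cytotox_min_systems,
    includeViability = cfg$annotation.include_viability)
}

.writeReport <- function(dat, path) {
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

.writeSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the annotation pipeline on profile and control tables
#'
#' Full pipeline for one or more compounds: estimate envelopes from the
#' historical vehicle controls, flag cytotoxic/antiproliferative conditions,
#' exclude broadly cytotoxic doses, call single-dose hits, annotate
#' dose-dependent activities and label modulated biomarkers. Writes, per
#' compound, `<compound>_activities.tsv`, `<compound>_hits.tsv` and
#' `<compound>_cytotox.tsv`, plus a machine-readable `summary.json` carrying
#' the resolved configuration and all counts. Reruns with identical inputs
#' and configuration are byte-identical.
#'
#' @param profilePaths character vector of profile TSV paths (one compound
#'   each; see [readProfileTable()]).
#' @param controlsPath path to the vehicle-control TSV.
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()] list.
#' @return invisibly, a named list per compound with elements `profile`,
#'   `envelopes`, `flags`, `excludedDoses`, `hits`, `activities`,
#'   `modulated`.
#' @export
runAnnotate <- function(profilePaths, controlsPath, outDir,
                        config = runConfig()) {
  stopifnot(inherits(config, "phenoscreenConfig"))
  missing <- c(profilePaths, controlsPath)[!file.exists(c(profilePaths,
                                                          controlsPath))]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  controls <- readControlTable(controlsPath)
  envelopes <- estimateEnvelopes(
    controls, method = config$envelope.method,
    confidence = config$envelope.confidence,
    defaultHalfWidth = config$envelope.default_half_width)
  acfg <- .annotationConfigFrom(config)

  results <- list()
  summary <- list(config = unclass(config), compounds = list())
  for (path in profilePaths) {
    profile <- readProfileTable(path)
    flags <- flagCytotoxicity(profile, acfg)
    excl <- applyBroadCytotoxExclusion(profile, flags, acfg)
    hits <- callHits(excl$profile, envelopes, acfg)
    activities <- annotateActivities(excl$profile, envelopes, acfg)
    modulated <- labelModulated(activities)

    cmp <- compoundName(profile)
    slug <- gsub("[^[:alnum:].-]+", "_", cmp)
    .writeReport(cbind(compound = if (nrow(activities)) cmp else character(),
                       activities),
                 file.path(outDir, paste0(slug, "_activities.tsv")))
    .writeReport(cbind(compound = if (nrow(hits)) cmp else character(), hits),
                 file.path(outDir, paste0(slug, "_hits.tsv")))
    .writeReport(cbind(compound = if (nrow(flags)) cmp else character(),
                       flags),
                 file.path(outDir, paste0(slug, "_cytotox.tsv")))

    results[[cmp]] <- list(profile = excl$profile, envelopes = envelopes,
                           flags = flags, excludedDoses = excl$excludedDoses,
                           hits = hits, activities = activities,
                           modulated = modulated)
    summary$compounds[[cmp]] <- list(
      doses = profile@doseGrid,
      excluded_doses = excl$excludedDoses,
      n_hits = nrow(hits),
      n_activities = nrow(activities),
      n_cytotox_flags = sum(flags$kind == "cytotoxic"),
      n_antiproliferative_flags = sum(flags$kind == "antiproliferative"),
      modulated_biomarkers = modulated,
      activities = activities
    )
  }
  .writeSummary(summary, file.path(outDir, "summary.json"))
  invisible(results)
}

#' Compare compound activity signatures
#'
#' Computes the [summarizeCompound()] row for every signature and the
#' direction-matched [sharedActivities()] report for every pair; writes
#' `comparison.tsv` (pairwise) plus `summary.json` (resolved configuration,
#' summaries, pairwise reports).
#'
#' @param sets list of at least two [SignedActivitySet-class] objects.
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()] list.
#' @param panel character vector of panel system ids.
#' @return invisibly, list with `summaries` (data.frame) and `reports`
#'   (list of [SharedActivityReport-class]).
#' @export
runCompare <- function(sets, outDir, config = runConfig(),
                       panel = bioMapPanel()$id) {
  stopifnot(inherits(config, "phenoscreenConfig"))
  if (length(sets) < 2L) {
    stop("need at least two compounds to compare", call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  summaries <- do.call(rbind, lapply(sets, summarizeCompound, panel = panel))
  rownames(summaries) <- NULL

  pairs <- utils::combn(length(sets), 2L)
  reports <- lapply(seq_len(ncol(pairs)), function(j) {
    sharedActivities(sets[[pairs[1L, j]]], sets[[pairs[2L, j]]], panel)
  })
  pairwise <- do.call(rbind, lapply(reports, function(r) {
    data.frame(compound_a = r@compoundA, dose_label_a = r@doseLabelA,
               compound_b = r@compoundB, dose_label_b = r@doseLabelB,
               n_matches = r@nMatches,
               n_systems = length(r@systemsWithMatches),
               systems_fraction = r@systemsFraction,
               systems = paste(r@systemsWithMatches, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  .writeReport(pairwise, file.path(outDir, "comparison.tsv"))
  .writeSummary(list(config = unclass(config), summaries = summaries,
                     pairwise = pairwise),
                file.path(outDir, "summary.json"))
  invisible(list(summaries = summaries, reports = reports))
}

#' Simulate a panel run to disk
#'
#' Generates vehicle controls and a compound profile with injected effects,
#' then writes `controls.tsv`, `profile.tsv` and `truth.json` (injected
#' effects, expected annotations and the envelope half-width they assume) to
#' the output directory. Deterministic under the spec's seed.
#'
#' @param spec a [PanelSpec-class].
#' @param effects data.frame of [effectSpec()] rows (may be NULL for a null
#'   panel).
#' @param outDir output directory (created if needed).
#' @param compound compound identifier for the profile.
#' @return invisibly, the [generateProfile()] result plus the controls.
#' @export
simulatePanel <- function(spec, effects = NULL, outDir,
                          compound = "synthetic") {
  stopifnot(is(spec, "PanelSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  controls <- generateControls(spec)
  sim <- generateProfile(spec, effects, compound = compound)
  writeControlTable(controls, file.path(outDir, "controls.tsv"))
  writeProfileTable(sim$profile, file.path(outDir, "profile.tsv"))
  .writeSummary(list(
    seed = spec@seed, noise_sd = spec@noiseSd, doses = spec@doses,
    effects = sim$truth@effects,
    envelope_half_width = sim$truth@halfWidth,
    expected_annotations = sim$truth@expected
  ), file.path(outDir, "truth.json"))
  invisible(list(controls = controls, profile = sim$profile,
                 truth = sim$truth))
}
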