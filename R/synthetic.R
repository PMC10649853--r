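#' Create a synthetic panel specification
#'
#' Defaults describe the study conditions the package is calibrated on: a
#' 12-system panel with 12 soluble biomarkers per system (plus an SRB
#' viability readout per system), the 4-dose ascending grid 1.9/5.6/17/50 uM,
#' vehicle noise of sd 0.025 on the log10-ratio scale and 100 historical
#' control replicates per readout.
#'
#' @param nSystems number of cell systems (the first 12 take the reference
#'   panel ids; extra systems get generic ids).
#' @param biomarkersPerSystem soluble biomarkers per system.
#' @param doses strictly ascending concentrations (uM).
#' @param noiseSd vehicle noise sd (log10-ratio units).
#' @param controlReplicates historical control replicates per readout.
#' @param viability add an SRB viability readout per system.
#' @param seed integer seed.
#' @return a [PanelSpec-class].
#' @export
panelSpec <- function(nSystems = 12L, biomarkersPerSystem = 12L,
                      doses = c(1.9, 5.6, 17, 50), noiseSd = 0.025,
                      controlReplicates = 100L, viability = TRUE,
                      seed = 1L) {
  new("PanelSpec", nSystems = as.integer(nSystems),
      biomarkersPerSystem = as.integer(biomarkersPerSystem),
      doses = as.numeric(doses), noiseSd = noiseSd,
      controlReplicates = as.integer(controlReplicates),
      viability = viability, seed = as.integer(seed))
}

.panelSystems <- function(spec) {
  n <- spec@nSystems
  if (n <= length(.PANEL_IDS)) {
    .PANEL_IDS[seq_len(n)]
  } else {
    c(.PANEL_IDS, sprintf("S%02d", seq_len(n - length(.PANEL_IDS))))
  }
}

.panelReadouts <- function(spec) {
  systems <- .panelSystems(spec)
  bm <- sprintf("bm%02d", seq_len(spec@biomarkersPerSystem))
  out <- expand.grid(system = systems, biomarker = bm,
                     stringsAsFactors = FALSE)
  out$readout_class <- "soluble"
  if (spec@viability) {
    out <- rbind(out, data.frame(system = systems, biomarker = "SRB",
                                 readout_class = "viability",
                                 stringsAsFactors = FALSE))
  }
  out[order(out$system, out$biomarker), , drop = FALSE]
}

#' Declare an injected dose-response effect
#'
#' Shapes of the noise-free signal over the ascending dose grid (all on the
#' log10-ratio scale, `amplitude >= 0`):
#' \describe{
#'   \item{null}{identically 0.}
#'   \item{monotone_up / monotone_down}{a graded ramp: 0 below the onset
#'     dose, rising (falling) linearly from the onset dose to +-`amplitude`
#'     at the top dose.}
#'   \item{threshold_onset}{a step: 0 below the onset dose, +`amplitude` at
#'     the onset dose and above.}
#'   \item{u_shape}{+`amplitude` at an interior peak dose, half amplitude at
#'     its neighbours, 0 elsewhere — the inverted-U magnitude profile of a
#'     compound whose activity recedes at the top dose.}
#' }
#'
#' @param system system id.
#' @param biomarker canonical biomarker id.
#' @param shape one of the shapes above.
#' @param amplitude peak |log10 ratio|, >= 0.
#' @param onset 1-based dose index: first affected dose (peak dose for
#'   u_shape, which must be interior).
#' @return one-row data.frame; rbind rows to build an effect list.
#' @export
effectSpec <- function(system, biomarker,
                       shape = c("null", "monotone_up", "monotone_down",
                                 "u_shape", "threshold_onset"),
                       amplitude = 0, onset = 2L) {
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, shape != "null" || amplitude == 0)
  data.frame(system = system, biomarker = biomarker, shape = shape,
             amplitude = amplitude, onset = as.integer(onset),
             stringsAsFactors = FALSE)
}

# noise-free signal of one effect over an n-dose grid
.shapeSignal <- function(shape, amplitude, onset, nDoses) {
  i <- seq_len(nDoses)
  switch(shape,
    null = rep(0, nDoses),
    monotone_up = ifelse(i >= onset,
                         amplitude * (i - onset + 1) / (nDoses - onset + 1), 0),
    monotone_down = -ifelse(i >= onset,
                            amplitude * (i - onset + 1) / (nDoses - onset + 1),
                            0),
    threshold_onset = ifelse(i >= onset, amplitude, 0),
    u_shape = {
      if (onset <= 1L || onset >= nDoses) {
        stop("u_shape peak must be at an interior dose", call. = FALSE)
      }
      s <- rep(0, nDoses)
      s[onset] <- amplitude
      s[c(onset - 1L, onset + 1L)] <- amplitude / 2
      s
    },
    stop("unknown shape: ", shape, call. = FALSE)
  )
}

#' Generate historical vehicle controls for a synthetic panel
#'
#' Per readout, draws `controlReplicates` values from a normal distribution
#' with mean 0 and sd `noiseSd`. Reproducible under the spec's seed.
#'
#' @param spec a [PanelSpec-class].
#' @return a [VehicleControlSet-class].
#' @export
generateControls <- function(spec) {
  stopifnot(is(spec, "PanelSpec"))
  ro <- .panelReadouts(spec)
  set.seed(spec@seed)
  k <- spec@controlReplicates
  VehicleControlSet(data.frame(
    system = rep(ro$system, each = k),
    biomarker = rep(ro$biomarker, each = k),
    log10_ratio = stats::rnorm(nrow(ro) * k, 0, spec@noiseSd),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic compound profile with ground truth
#'
#' Builds value(system, biomarker, dose) = shape signal + independent
#' N(0, noiseSd) noise for every readout of the panel, and records in the
#' returned truth the annotations the pipeline is expected to produce from
#' the *noise-free* signal under a stated envelope half-width (default: the
#' normal-method envelope at the given confidence for the spec's noise sd).
#' Profile noise uses `seed + 1` so it is independent of the control draws
#' of [generateControls()] under the same spec.
#'
#' @param spec a [PanelSpec-class].
#' @param effects data.frame of [effectSpec()] rows; effects must reference
#'   readouts that exist in the panel.
#' @param compound compound identifier for the profile.
#' @param truthHalfWidth envelope half-width used to derive the expected
#'   annotations from the noise-free signal.
#' @param cfg [AnnotationConfig-class] used for the expected annotations.
#' @param confidence coverage used for the default `truthHalfWidth`.
#' @return list with elements `profile` ([CompoundProfile-class]) and
#'   `truth` ([SyntheticTruth-class]).
#' @examples
#' spec <- panelSpec(nSystems = 2, biomarkersPerSystem = 3, seed = 7)
#' eff <- effectSpec("3C", "bm01", "monotone_down", amplitude = 0.3)
#' sim <- generateProfile(spec, eff)
#' sim$truth@expected
#' @export
generateProfile <- function(spec, effects = NULL, compound = "synthetic",
                            truthHalfWidth = NULL,
                            cfg = annotationConfig(), confidence = 0.95) {
  stopifnot(is(spec, "PanelSpec"))
  ro <- .panelReadouts(spec)
  nd <- length(spec@doses)
  if (is.null(effects) || nrow(effects) == 0L) {
    effects <- data.frame(system = character(), biomarker = character(),
                          shape = character(), amplitude = numeric(),
                          onset = integer(), stringsAsFactors = FALSE)
  }
  rokey <- paste(ro$system, ro$biomarker, sep = "\r")
  effkey <- paste(effects$system, effects$biomarker, sep = "\r")
  if (!all(effkey %in% rokey)) {
    miss <- effects[!(effkey %in% rokey), c("system", "biomarker")]
    stop("effect(s) reference unknown readouts: ",
         paste(paste(miss$system, miss$biomarker), collapse = "; "),
         call. = FALSE)
  }

  signal <- matrix(0, nrow = nrow(ro), ncol = nd)
  for (i in seq_len(nrow(effects))) {
    signal[match(effkey[i], rokey), ] <- signal[match(effkey[i], rokey), ] +
      .shapeSignal(effects$shape[i], effects$amplitude[i], effects$onset[i],
                   nd)
  }

  base <- data.frame(
    system = rep(ro$system, each = nd),
    biomarker = rep(ro$biomarker, each = nd),
    readout_class = rep(ro$readout_class, each = nd),
    dose = rep(spec@doses, times = nrow(ro)),
    stringsAsFactors = FALSE
  )
  sig <- as.vector(t(signal))

  set.seed(spec@seed + 1L)
  noise <- if (spec@noiseSd > 0) {
    stats::rnorm(nrow(base), 0, spec@noiseSd)
  } else {
    rep(0, nrow(base))
  }
  base$log10_ratio <- sig + noise
  profile <- CompoundProfile(compound, base)

  if (is.null(truthHalfWidth)) {
    truthHalfWidth <- stats::qnorm(1 - (1 - confidence) / 2) * spec@noiseSd
  }
  clean <- base
  clean$log10_ratio <- sig
  expected <- annotateActivities(
    CompoundProfile(compound, clean),
    new("EnvelopeSet",
        table = data.frame(system = character(), biomarker = character(),
                           half_width = numeric(), n_controls = integer()),
        method = "normal", confidence = confidence,
        defaultHalfWidth = truthHalfWidth),
    cfg)
  truth <- new("SyntheticTruth", effects = effects,
               expected = expected[, c("system", "biomarker", "direction"),
                                   drop = FALSE],
               halfWidth = truthHalfWidth)
  list(profile = profile, truth = truth)
}

#' Score recovered annotations against synthetic ground truth
#'
#' Annotations match on (system, biomarker, direction). Negatives are all
#' readout-direction pairs of the truth's panel that carry no expected
#' annotation.
#'
#' @param called data.frame as returned by [annotateActivities()].
#' @param truth a [SyntheticTruth-class].
#' @param nReadouts total readouts of the panel (needed for specificity /
#'   per-readout false-annotation rate); if NA those fields are NA.
#' @return one-row data.frame with `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `fp_per_readout`.
#' @export
evaluateRecovery <- function(called, truth, nReadouts = NA_integer_) {
  stopifnot(is(truth, "SyntheticTruth"))
  key <- function(d) paste(d$system, d$biomarker, d$direction, sep = "\r")
  ck <- if (nrow(called)) unique(key(called)) else character()
  ek <- if (nrow(truth@expected)) key(truth@expected) else character()
  tp <- sum(ck %in% ek)
  fp <- sum(!(ck %in% ek))
  fn <- sum(!(ek %in% ck))
  total <- if (is.na(nReadouts)) NA_integer_ else 2L * nReadouts
  tn <- if (is.na(total)) NA_integer_ else total - tp - fp - fn
  data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (length(ek)) tp / length(ek) else NA_real_,
    specificity = if (is.na(tn)) NA_real_ else tn / (tn + fp),
    fp_per_readout = if (is.na(nReadouts)) NA_real_ else fp / nReadouts,
    stringsAsFactors = FALSE
  )
}
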