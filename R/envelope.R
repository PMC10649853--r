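#' Estimate significance envelopes from historical vehicle controls
#'
#' For each (system, biomarker) readout with control history, estimates the
#' half-width of the symmetric significance envelope
#' `[-half_width, +half_width]` on the log10-ratio scale. The envelope is a
#' tolerance band covering the stated fraction of the vehicle-control
#' *distribution* (not a confidence interval of its mean), and is centered at
#' 0: controls determine the width only.
#'
#' Methods:
#' \describe{
#'   \item{normal}{`half_width = z(1 - (1 - confidence)/2) * sd(controls)`,
#'     i.e. 1.959964 x sample SD at 95%.}
#'   \item{empirical}{the symmetrized sample quantile band,
#'     `max(|q[(1-c)/2]|, |q[1-(1-c)/2]|)`.}
#' }
#'
#' Readouts with fewer than 2 control replicates get no specific envelope and
#' fall back to `defaultHalfWidth` at lookup time (with a warning here).
#' Zero-variance controls yield a zero half-width.
#'
#' @param controls a [VehicleControlSet-class].
#' @param method "normal" or "empirical".
#' @param confidence coverage level in (0, 1); default 0.95.
#' @param defaultHalfWidth half-width for readouts without control history;
#'   default 0.1, matching the effect-size threshold.
#' @return an [EnvelopeSet-class].
#' @examples
#' set.seed(1)
#' ctl <- VehicleControlSet(data.frame(
#'   system = "3C", biomarker = "MCP-1", log10_ratio = rnorm(100, 0, 0.05)))
#' estimateEnvelopes(ctl)
#' @export
estimateEnvelopes <- function(controls, method = c("normal", "empirical"),
                              confidence = 0.95, defaultHalfWidth = 0.1) {
  stopifnot(is(controls, "VehicleControlSet"),
            confidence > 0, confidence < 1, defaultHalfWidth >= 0)
  method <- match.arg(method)
  dat <- controls@data
  key <- paste(dat$system, dat$biomarker, sep = "\r")
  groups <- split(dat$log10_ratio, key)
  n <- vapply(groups, length, integer(1))

  few <- n < 2L
  if (any(few)) {
    warning(sum(few), " readout(s) have fewer than 2 control replicates; ",
            "the default half-width ", defaultHalfWidth,
            " will be used for them", call. = FALSE)
  }
  keep <- names(groups)[!few]
  alpha <- 1 - confidence
  hw <- vapply(groups[!few], function(x) {
    if (method == "normal") {
      stats::qnorm(1 - alpha / 2) * stats::sd(x)
    } else {
      q <- stats::quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      max(abs(q))
    }
  }, numeric(1))

  parts <- strsplit(keep, "\r", fixed = TRUE)
  tab <- data.frame(
    system = vapply(parts, `[`, character(1), 1L),
    biomarker = vapply(parts, `[`, character(1), 2L),
    half_width = unname(hw),
    n_controls = unname(n[!few]),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  new("EnvelopeSet", table = tab, method = method, confidence = confidence,
      defaultHalfWidth = defaultHalfWidth)
}

#' @describeIn halfWidth vectorized lookup; any (system, biomarker) yields a
#'   usable half-width (readout-specific if estimated, otherwise the default).
setMethod("halfWidth", "EnvelopeSet", function(x, system, biomarker) {
  len <- max(length(system), length(biomarker))
  system <- rep_len(system, len)
  biomarker <- rep_len(biomarker, len)
  idx <- match(paste(system, biomarker, sep = "\r"),
               paste(x@table$system, x@table$biomarker, sep = "\r"))
  out <- x@table$half_width[idx]
  out[is.na(idx)] <- x@defaultHalfWidth
  out
})

#' Classify readouts against a significance envelope
#'
#' A readout is `"up"` iff its log10 ratio is strictly greater than
#' `+half_width`, `"down"` iff strictly less than `-half_width`, and
#' `"inside"` otherwise; values exactly on the boundary are inside. `NA`
#' values classify as `NA` (an explicit gap).
#'
#' @param value numeric vector of log10 ratios.
#' @param halfWidth non-negative numeric vector (recycled).
#' @return character vector in `{"inside", "up", "down"}` (or NA).
#' @examples
#' classifyReadout(c(0, 0.15, -0.2), 0.098)
#' @export
classifyReadout <- function(value, halfWidth) {
  stopifnot(all(halfWidth >= 0, na.rm = TRUE))
  halfWidth <- rep_len(halfWidth, length(value))
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- "inside"
  out[ok & value > halfWidth] <- "up"
  out[ok & value < -halfWidth] <- "down"
  out
}
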