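# Shared builders and independent oracles for the test suite.

# single-readout profile over a 4-dose grid
seriesProfile <- function(values, doses = c(1.9, 5.6, 17, 50),
                          system = "3C", biomarker = "MCP-1",
                          readout_class = "soluble", compound = "test") {
  CompoundProfile(compound, data.frame(
    system = system, biomarker = biomarker, readout_class = readout_class,
    dose = doses, log10_ratio = values, stringsAsFactors = FALSE))
}

# multi-readout profile: series = named list biomarker -> values (one system)
multiProfile <- function(series, doses = c(1.9, 5.6, 17, 50), system = "3C",
                         readout_class = "soluble", compound = "test") {
  rows <- do.call(rbind, lapply(names(series), function(bm) {
    data.frame(system = system, biomarker = bm,
               readout_class = readout_class, dose = doses,
               log10_ratio = series[[bm]], stringsAsFactors = FALSE)
  }))
  CompoundProfile(compound, rows)
}

# envelope set with a single global half-width
constEnvelope <- function(hw) {
  new("EnvelopeSet",
      table = data.frame(system = character(), biomarker = character(),
                         half_width = numeric(), n_controls = integer()),
      method = "normal", confidence = 0.95, defaultHalfWidth = hw)
}

# Independent brute-force activity scanner for one dose series: examines
# every contiguous window, keeps maximal same-direction outside-envelope
# windows of sufficient length whose peak passes the effect-size gate, then
# keeps the strongest (earliest on ties) window per direction. Deliberately
# written as explicit loops, unrelated to the package's vectorized path.
oracleActivities <- function(values, halfWidth, effectThreshold = 0.1,
                             minConsecutive = 2L) {
  n <- length(values)
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- if (is.na(values[i])) "gap"
      else if (values[i] > halfWidth) "up"
      else if (values[i] < -halfWidth) "down"
      else "inside"
  }
  cand <- data.frame(direction = character(), start = integer(),
                     end = integer(), maxabs = numeric(),
                     stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    for (e in seq(s, n)) {
      w <- s:e
      if (length(w) < minConsecutive) next
      d <- unique(cls[w])
      if (length(d) != 1L || !(d %in% c("up", "down"))) next
      if (s > 1L && cls[s - 1L] == d) next        # not maximal on the left
      if (e < n && cls[e + 1L] == d) next         # not maximal on the right
      m <- max(abs(values[w]))
      if (m > effectThreshold) {
        cand <- rbind(cand, data.frame(direction = d, start = s, end = e,
                                       maxabs = m, stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(cand) == 0L) return(cand)
  out <- NULL
  for (d in unique(cand$direction)) {
    sub <- cand[cand$direction == d, , drop = FALSE]
    sub <- sub[order(-sub$maxabs, sub$start), , drop = FALSE]
    out <- rbind(out, sub[1L, , drop = FALSE])
  }
  out[order(out$direction), , drop = FALSE]
}

# compare package annotation of a single series against the oracle
expectSeriesMatchesOracle <- function(values, hw, thr = 0.1, minConsec = 2L,
                                      doses = c(1.9, 5.6, 17, 50)) {
  prof <- seriesProfile(values, doses = doses)
  got <- annotateActivities(prof, constEnvelope(hw),
                            annotationConfig(effectSizeThreshold = thr,
                                             minConsecutive = minConsec))
  want <- oracleActivities(values, hw, thr, minConsec)
  expect_equal(nrow(got), nrow(want),
               info = paste("series:", paste(values, collapse = ",")))
  if (nrow(want)) {
    got <- got[order(got$direction), , drop = FALSE]
    expect_equal(got$direction, want$direction,
                 info = paste("series:", paste(values, collapse = ",")))
    wantDoses <- vapply(seq_len(nrow(want)), function(i) {
      paste(doses[want$start[i]:want$end[i]], collapse = ",")
    }, character(1))
    expect_equal(got$supporting_doses, wantDoses,
                 info = paste("series:", paste(values, collapse = ",")))
    expect_equal(got$max_abs_log10_ratio, want$maxabs,
                 info = paste("series:", paste(values, collapse = ",")))
  }
  invisible(NULL)
}
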