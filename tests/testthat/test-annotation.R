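test_that("hits need both envelope exit and effect size, strictly", {
  env <- constEnvelope(0.098)
  expect_equal(nrow(callHits(seriesProfile(c(0, 0, 0, 0)), env)), 0L)

  hits <- callHits(seriesProfile(c(0, 0, 0.15, 0)), env)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$direction, "up")
  expect_equal(hits$dose, 17)

  # outside the effect gate but inside a wide envelope: not a hit
  expect_equal(nrow(callHits(seriesProfile(c(0, 0, 0.105, 0)),
                             constEnvelope(0.12))), 0L)
  # exactly at the effect threshold: not a hit (strict >)
  expect_equal(nrow(callHits(seriesProfile(c(0, 0, 0.1, 0)),
                             constEnvelope(0.05))), 0L)
  # direction follows the sign
  expect_equal(callHits(seriesProfile(c(0, 0, -0.15, 0)), env)$direction,
               "down")
})

test_that("dose-dependent activities follow the consecutive-run rule", {
  env <- constEnvelope(0.05)
  # three consecutive up doses, peak above the effect gate
  act <- annotateActivities(seriesProfile(c(0.02, 0.12, 0.15, 0.08)), env)
  expect_equal(nrow(act), 1L)
  expect_equal(act$direction, "up")
  expect_equal(act$supporting_doses, "5.6,17,50")
  expect_equal(act$n_supporting, 3L)
  expect_equal(act$max_abs_log10_ratio, 0.15)

  # alternating directions never build a run
  expect_equal(nrow(annotateActivities(
    seriesProfile(c(0.12, -0.12, 0.12, -0.12)), env)), 0L)

  # a run without any dose above the effect gate is not an activity
  expect_equal(nrow(annotateActivities(
    seriesProfile(c(0.08, 0.09, 0, 0)), env)), 0L)

  # U-shape crossing zero: both directions reported separately
  both <- annotateActivities(seriesProfile(c(0.12, 0.15, -0.12, -0.15)), env)
  expect_setequal(both$direction, c("up", "down"))
})

test_that("annotation agrees with the brute-force scanner on random series", {
  set.seed(42)
  for (i in 1:200) {
    values <- round(runif(4, -0.3, 0.3), 3)
    expectSeriesMatchesOracle(values, hw = 0.05)
  }
  # and on 5-dose grids with a larger minimum run length
  for (i in 1:100) {
    values <- round(runif(5, -0.3, 0.3), 3)
    expectSeriesMatchesOracle(values, hw = 0.05, minConsec = 3L,
                              doses = c(1, 3, 10, 30, 100))
  }
})

test_that("cytotoxic and antiproliferative conditions are flagged strictly", {
  prof <- CompoundProfile("t", data.frame(
    system = rep(c("3C", "4H"), each = 8),
    biomarker = rep(rep(c("SRB", "proliferation"), each = 4), 2),
    readout_class = rep(rep(c("viability", "proliferation"), each = 4), 2),
    dose = rep(c(1.9, 5.6, 17, 50), 4),
    log10_ratio = c(0, 0, 0, -0.31,      # 3C SRB: cytotoxic at top dose
                    0, 0, -0.15, -0.35,  # 3C prolif: antiprolif at 17 and 50
                    0, 0, 0, -0.3,       # 4H SRB: exactly -0.3, no flag
                    0, 0, 0, -0.05)))    # 4H prolif: above threshold
  flags <- flagCytotoxicity(prof)
  expect_equal(sum(flags$kind == "cytotoxic"), 1L)
  expect_equal(flags$system[flags$kind == "cytotoxic"], "3C")
  expect_equal(flags$dose[flags$kind == "cytotoxic"], 50)
  anti <- flags[flags$kind == "antiproliferative", ]
  expect_equal(anti$dose, c(17, 50))
  expect_true(all(anti$system == "3C"))

  # a profile without viability channels yields no flags, with a message
  expect_message(
    out <- flagCytotoxicity(seriesProfile(c(0, 0, -0.5, -0.5))),
    "no viability or proliferation readouts")
  expect_equal(nrow(out), 0L)
})

test_that("broad cytotoxicity excludes a dose panel-wide", {
  mk <- function(systems, value) {
    CompoundProfile("t", do.call(rbind, lapply(systems, function(s) {
      rbind(
        data.frame(system = s, biomarker = "SRB",
                   readout_class = "viability", dose = c(1.9, 5.6, 17, 50),
                   log10_ratio = c(0, 0, 0, value)),
        data.frame(system = s, biomarker = "MCP-1",
                   readout_class = "soluble", dose = c(1.9, 5.6, 17, 50),
                   log10_ratio = c(0, 0.15, 0.2, 0.25))
      )
    })))
  }
  cfg <- annotationConfig()

  # cytotoxicity in three systems at the top dose: dose removed everywhere
  prof <- mk(c("3C", "4H", "LPS"), -0.4)
  excl <- applyBroadCytotoxExclusion(prof, flagCytotoxicity(prof, cfg), cfg)
  expect_equal(excl$excludedDoses, 50)
  expect_equal(doses(excl$profile), c(1.9, 5.6, 17))
  expect_false(50 %in% profileData(excl$profile)$dose)
  # the original tested grid is remembered
  expect_equal(excl$profile@doseGrid, c(1.9, 5.6, 17, 50))

  # two systems only: below the broad threshold, nothing excluded
  prof2 <- mk(c("3C", "4H"), -0.4)
  excl2 <- applyBroadCytotoxExclusion(prof2, flagCytotoxicity(prof2, cfg),
                                      cfg)
  expect_equal(excl2$excludedDoses, numeric())
  expect_identical(excl2$profile, prof2)

  # no flags at all: unchanged
  prof3 <- mk("3C", 0)
  excl3 <- applyBroadCytotoxExclusion(prof3, flagCytotoxicity(prof3, cfg),
                                      cfg)
  expect_equal(excl3$excludedDoses, numeric())
})

test_that("an excluded interior dose breaks run adjacency", {
  # all four doses up and strong; removing dose 3 must split the run into
  # (1,2) and a lone dose 4, leaving one 2-dose activity
  prof <- seriesProfile(c(0.15, 0.16, 0.17, 0.18))
  cut <- new("CompoundProfile", compound = "test",
             doses = c(1.9, 5.6, 50), doseGrid = prof@doseGrid,
             data = profileData(prof)[profileData(prof)$dose != 17, ])
  act <- annotateActivities(cut, constEnvelope(0.05))
  expect_equal(nrow(act), 1L)
  expect_equal(act$supporting_doses, "1.9,5.6")

  # whereas dropping the top dose keeps a 3-dose run
  cut2 <- new("CompoundProfile", compound = "test",
              doses = c(1.9, 5.6, 17), doseGrid = prof@doseGrid,
              data = profileData(prof)[profileData(prof)$dose != 50, ])
  expect_equal(annotateActivities(cut2, constEnvelope(0.05))$supporting_doses,
               "1.9,5.6,17")
})

test_that("deleting a dose never increases the number of activities", {
  set.seed(99)
  env <- constEnvelope(0.05)
  for (i in 1:50) {
    values <- round(runif(4, -0.3, 0.3), 3)
    prof <- seriesProfile(values)
    full <- nrow(annotateActivities(prof, env))
    for (drop in 1:4) {
      dat <- profileData(prof)[-drop, ]
      cut <- new("CompoundProfile", compound = "test",
                 doses = sort(unique(dat$dose)), doseGrid = prof@doseGrid,
                 data = dat)
      expect_lte(nrow(annotateActivities(cut, env)), full)
    }
  }
})

test_that("every activity is anchored by at least one same-direction hit", {
  set.seed(123)
  env <- constEnvelope(0.05)
  cfg <- annotationConfig()
  for (i in 1:50) {
    prof <- multiProfile(list(a = round(runif(4, -0.3, 0.3), 3),
                              b = round(runif(4, -0.3, 0.3), 3)))
    act <- annotateActivities(prof, env, cfg)
    hits <- callHits(prof, env, cfg)
    if (nrow(act)) {
      for (j in seq_len(nrow(act))) {
        supp <- as.numeric(strsplit(act$supporting_doses[j], ",")[[1]])
        anchored <- any(hits$system == act$system[j] &
                          hits$biomarker == act$biomarker[j] &
                          hits$direction == act$direction[j] &
                          hits$dose %in% supp)
        expect_true(anchored)
      }
    }
  }
})

.emptyActivitiesForTest <- function() {
  data.frame(system = character(), biomarker = character(),
             direction = character(), supporting_doses = character(),
             n_supporting = integer(), max_abs_log10_ratio = numeric())
}

test_that("modulated biomarkers need opposite directions in distinct systems", {
  act <- function(system, biomarker, direction) {
    data.frame(system = system, biomarker = biomarker, direction = direction,
               supporting_doses = "1,2", n_supporting = 2L,
               max_abs_log10_ratio = 0.2, stringsAsFactors = FALSE)
  }
  expect_equal(labelModulated(rbind(act("3C", "X", "down"),
                                    act("MyoF", "X", "up"))), "X")
  expect_equal(labelModulated(rbind(act("3C", "X", "down"),
                                    act("MyoF", "X", "down"))), character())
  # both directions in one and the same system only: not modulated
  expect_equal(labelModulated(rbind(act("3C", "X", "down"),
                                    act("3C", "X", "up"))), character())
  expect_equal(labelModulated(.emptyActivitiesForTest()), character())
})

test_that("annotation config rejects inconsistent thresholds", {
  expect_error(annotationConfig(minConsecutive = 1), ">= 2")
  expect_error(annotationConfig(cytotoxThreshold = -0.05), "cytotoxThreshold")
  expect_error(annotationConfig(effectSizeThreshold = 0), "> 0")
})

test_that("viability readouts can be excluded from hit tallies", {
  prof <- CompoundProfile("t", data.frame(
    system = "3C", biomarker = "SRB", readout_class = "viability",
    dose = c(1.9, 5.6, 17, 50), log10_ratio = c(0, -0.15, -0.2, -0.25)))
  env <- constEnvelope(0.05)
  expect_gt(nrow(callHits(prof, env)), 0L)
  off <- annotationConfig(includeViability = FALSE)
  expect_equal(nrow(callHits(prof, env, off)), 0L)
  expect_equal(nrow(annotateActivities(prof, env, off)), 0L)
})
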