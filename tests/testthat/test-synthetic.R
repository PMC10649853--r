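test_that("synthetic generation is deterministic under the seed", {
  spec <- panelSpec(nSystems = 3, biomarkersPerSystem = 4, seed = 7)
  c1 <- generateControls(spec)
  c2 <- generateControls(spec)
  expect_identical(profileData(c1), profileData(c2))

  eff <- effectSpec("3C", "bm01", "monotone_up", amplitude = 0.3)
  p1 <- generateProfile(spec, eff)
  p2 <- generateProfile(spec, eff)
  expect_identical(profileData(p1$profile), profileData(p2$profile))

  # a different seed decorrelates the draws
  p3 <- generateProfile(panelSpec(nSystems = 3, biomarkersPerSystem = 4,
                                  seed = 8), eff)
  expect_false(identical(profileData(p1$profile), profileData(p3$profile)))
})

test_that("zero noise gives exactly the noise-free signal", {
  spec <- panelSpec(nSystems = 2, biomarkersPerSystem = 3, noiseSd = 0,
                    seed = 1)
  ctl <- generateControls(spec)
  expect_true(all(profileData(ctl)$log10_ratio == 0))

  sim <- generateProfile(spec, NULL)
  expect_true(all(profileData(sim$profile)$log10_ratio == 0))
  expect_equal(nrow(sim$truth@expected), 0L)
})

test_that("control draws match the stated noise level", {
  spec <- panelSpec(nSystems = 2, biomarkersPerSystem = 2,
                    controlReplicates = 100, noiseSd = 0.025, seed = 3)
  dat <- profileData(generateControls(spec))
  sds <- tapply(dat$log10_ratio, paste(dat$system, dat$biomarker), sd)
  expect_true(all(abs(sds - 0.025) / 0.025 < 0.25))
  expect_equal(unname(table(paste(dat$system, dat$biomarker))[1]), 100L)
})

test_that("injected effects yield the hand-derived annotations at zero noise", {
  spec <- panelSpec(nSystems = 2, biomarkersPerSystem = 3, noiseSd = 0,
                    seed = 5)
  # ramp down from dose 2: signals 0, -0.1, -0.2, -0.3
  eff <- effectSpec("3C", "bm02", "monotone_down", amplitude = 0.3,
                    onset = 2L)
  sim <- generateProfile(spec, eff, truthHalfWidth = 0.098)
  act <- annotateActivities(sim$profile, constEnvelope(0.098))
  expect_equal(nrow(act), 1L)
  expect_equal(act$direction, "down")
  expect_equal(act$n_supporting, 3L)
  expect_equal(act$biomarker, "bm02")
  expect_equal(act, annotateActivities(sim$profile,
                                       constEnvelope(sim$truth@halfWidth)))
  expect_equal(sim$truth@expected,
               act[, c("system", "biomarker", "direction")])

  # step onset: full amplitude from the onset dose
  stp <- generateProfile(spec, effectSpec("3C", "bm01", "threshold_onset",
                                          amplitude = 0.3, onset = 3L))
  v <- profileData(stp$profile)
  v <- v[v$biomarker == "bm01" & v$system == "3C", ]
  expect_equal(v$log10_ratio, c(0, 0, 0.3, 0.3))

  # U-shape: peak 0.3 at dose 3, half-amplitude shoulders -> 3-dose run
  ush <- generateProfile(spec, effectSpec("3C", "bm03", "u_shape",
                                          amplitude = 0.3, onset = 3L))
  actU <- annotateActivities(ush$profile, constEnvelope(0.098))
  expect_equal(actU$direction, "up")
  expect_equal(actU$n_supporting, 3L)
  expect_equal(actU$supporting_doses, "5.6,17,50")

  # a u_shape peak on the grid boundary is rejected
  expect_error(generateProfile(spec, effectSpec("3C", "bm03", "u_shape",
                                                amplitude = 0.3,
                                                onset = 4L)),
               "interior")
  # effects must reference readouts that exist
  expect_error(generateProfile(spec, effectSpec("3C", "nope", "monotone_up",
                                                amplitude = 0.3)),
               "unknown readout")
})

test_that("recovery evaluation scores confusion outcomes", {
  truth <- new("SyntheticTruth",
               effects = effectSpec("3C", "bm01", "monotone_up",
                                    amplitude = 0.3),
               expected = data.frame(system = "3C", biomarker = "bm01",
                                     direction = "up"),
               halfWidth = 0.05)
  called <- data.frame(system = "3C", biomarker = "bm01", direction = "up")
  perfect <- evaluateRecovery(called, truth, nReadouts = 10)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fp, 0L)
  expect_equal(perfect$tn, 19L)

  none <- evaluateRecovery(called[0, ], truth, nReadouts = 10)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fn, 1L)

  wrong <- evaluateRecovery(data.frame(system = "3C", biomarker = "bm02",
                                       direction = "down"), truth,
                            nReadouts = 10)
  expect_equal(wrong$fp, 1L)
  expect_equal(wrong$fp_per_readout, 0.1)
})

test_that("null panels stay within the analytic false-annotation bound", {
  # with per-dose outside-probability p, a same-direction run of >=2 among 4
  # doses has probability < 3 p^2; the effect-size gate only lowers it
  nAct <- 0L
  nReadouts <- 0L
  pOut <- numeric()
  for (s in 1:20) {
    spec <- panelSpec(nSystems = 4, biomarkersPerSystem = 6,
                      viability = FALSE, seed = 1000L + s)
    sim <- generateProfile(spec, NULL)
    env <- constEnvelope(qnorm(0.975) * 0.025)
    act <- annotateActivities(sim$profile, env)
    nAct <- nAct + nrow(act)
    nReadouts <- nReadouts + 24L
    pOut <- c(pOut, mean(classifyReadout(
      profileData(sim$profile)$log10_ratio, env@defaultHalfWidth) != "inside"))
  }
  p <- mean(pOut)
  expect_lte(nAct / nReadouts, 3 * p^2 + 10 * p^3)
})
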