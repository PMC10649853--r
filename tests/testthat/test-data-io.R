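test_that("profile tables round-trip value-for-value and sort doses", {
  prof <- multiProfile(list("MCP-1" = c(0.01, 0.12, 0.2, 0.05),
                            "HLA-DR" = c(-0.02, -0.15, -0.22, -0.1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTable(prof, path)
  back <- readProfileTable(path)
  expect_equal(profileData(back), profileData(prof))
  expect_equal(doses(back), doses(prof))
  expect_equal(compoundName(back), "test")

  # rows listed out of dose order parse to the same profile
  lines <- readLines(path)
  shuffled <- c(lines[1], rev(lines[-1]))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shuffled, path2)
  expect_equal(profileData(readProfileTable(path2)), profileData(prof))
})

test_that("malformed profile input fails with the offending location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "compound\tsystem\tbiomarker\treadout_class\tdose_uM\tlog10_ratio"
  row <- function(dose, val) {
    paste("t", "3C", "MCP-1", "soluble", dose, val, sep = "\t")
  }
  # duplicate (system, biomarker, dose)
  writeLines(c(hdr, row(1.9, 0.1), row(17, 0.2), row(17, 0.3)), path)
  expect_error(readProfileTable(path), "duplicate.*3C.*MCP-1.*17")
  # non-numeric value
  writeLines(c(hdr, row(1.9, "abc")), path)
  expect_error(readProfileTable(path), "non-numeric log10 ratio")
  # missing column
  writeLines(c("compound\tsystem\tvalue", "t\t3C\t0.1"), path)
  expect_error(readProfileTable(path), "malformed header")
  # unknown system under strict parsing
  writeLines(c(hdr, paste("t", "XX", "MCP-1", "soluble", 1, 0.1,
                          sep = "\t")), path)
  expect_error(readProfileTable(path, strict = TRUE), "unknown cell system")
  expect_error(readProfileTable(withr::local_tempfile()), "not found")
})

test_that("biomarker canonicalization folds synonyms and is idempotent", {
  expect_identical(canonicalBiomarker("PAI-I"), canonicalBiomarker("PAI-1"))
  expect_identical(canonicalBiomarker("TIMP1"), canonicalBiomarker("TIMP-1"))
  expect_identical(canonicalBiomarker("Esel"),
                   canonicalBiomarker("E-selectin"))
  expect_identical(canonicalBiomarker("Eot3"),
                   canonicalBiomarker("eotaxin-3"))
  expect_identical(canonicalBiomarker("Col-I"),
                   canonicalBiomarker("collagen-I"))
  expect_identical(canonicalBiomarker("TM"), "thrombomodulin")
  expect_identical(canonicalBiomarker("TF"), "tissue factor")
  expect_identical(canonicalBiomarker("MMP9"), "MMP-9")
  expect_identical(canonicalBiomarker("sIgG"), canonicalBiomarker("IgG"))
  expect_identical(canonicalBiomarker("MCP-1"), "MCP-1")

  # bare proliferation readouts resolve through the system context
  expect_identical(canonicalBiomarker("proliferation", system = "SAg"),
                   "T cell proliferation")
  expect_identical(canonicalBiomarker("proliferation", system = "3C"),
                   "endothelial cell proliferation")
  expect_identical(canonicalBiomarker("T cellproliferation"),
                   "T cell proliferation")

  # idempotent over every name appearing in the packaged tables
  dir <- system.file("extdata", package = "phenoscreen")
  for (f in c("table2_activities.tsv", "table4_activities.tsv")) {
    raw <- utils::read.delim(file.path(dir, f), comment.char = "#")
    once <- canonicalBiomarker(raw$biomarker, system = raw$system)
    expect_identical(canonicalBiomarker(once, system = raw$system), once)
  }

  # unknown names pass through folded, with a warning
  expect_warning(out <- canonicalBiomarker("Totally-Unknown Marker"),
                 "not in the synonym dictionary")
  expect_identical(out, "totallyunknownmarker")
})

test_that("system ids canonicalize, including the typeset /Mphg variant", {
  expect_identical(canonicalSystem(c("/Mphg", "lMphg", "3c")),
                   c("lMphg", "lMphg", "3C"))
  expect_error(canonicalSystem("nope", strict = TRUE), "unknown cell system")
})

test_that("packaged fixtures transcribe the reference tables", {
  t3 <- loadFixture("table3")
  expect_named(t3, c("C15:0", "rapamycin", "metformin", "acarbose"))
  c15 <- t3[["C15:0"]]
  expect_equal(doses(c15), c(1.9, 5.6, 17, 50))
  expect_equal(c15@counts, c(28L, 56L, 81L, 40L))

  t2 <- loadFixture("table2")
  aca <- t2[["acarbose"]]
  expect_equal(nrow(activityEntries(aca)), 5L)
  expect_setequal(unique(activityEntries(aca)$system),
                  c("CASM3C", "HDF3CGF", "MyoF"))

  t4 <- loadFixture("table4")
  c15opt <- activityEntries(t4[["C15:0"]])
  expect_equal(sum(c15opt$system == "BF4T"), 0L)  # printed "None"
  expect_true(all(c15opt$direction %in% c("up", "down")))

  # transcription consistency: per-compound totals equal the sum of
  # per-system set sizes
  for (set in t2) {
    e <- activityEntries(set)
    expect_equal(nrow(e), sum(table(e$system)))
    expect_equal(anyDuplicated(paste(e$system, e$biomarker, e$direction)), 0L)
  }
  expect_error(loadFixture("table5"), "arg")
  expect_error(loadFixture("table2", dir = withr::local_tempdir()),
               "not found")
})

test_that("signed activity sets keep set semantics", {
  e <- data.frame(system = c("3C", "3C", "3C"),
                  biomarker = c("MCP-1", "MCP-1", "MCP-1"),
                  direction = c("down", "down", "up"))
  set <- SignedActivitySet("x", "17 uM", e)
  expect_equal(nrow(activityEntries(set)), 2L)  # dedup, directions distinct
  expect_error(
    SignedActivitySet("x", "17 uM",
                      data.frame(system = "3C", biomarker = "MCP-1",
                                 direction = "sideways")),
    "direction")
})

test_that("hit count tables validate their shape", {
  expect_error(HitCountTable("x", c("5" = 3, "1" = -2)), "non-negative")
  tab <- HitCountTable("x", c("5" = 3, "1" = 2))
  expect_equal(doses(tab), c(1, 5))   # sorted ascending
  expect_equal(tab@counts, c(2L, 3L))
})
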