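#' Load a packaged reference-table fixture
#'
#' The package ships plain-text transcriptions of the published activity
#' tables for C15:0 (pentadecanoic acid), rapamycin, metformin, acarbose and
#' the EPA reference profile on the 12-system panel:
#' \describe{
#'   \item{table2}{dose-dependent annotated activities per compound over its
#'     full dose range; each printed arrow is one (system, biomarker,
#'     direction) entry; "None" cells are empty sets.}
#'   \item{table3}{biomarker hit counts per compound per dose (these counts
#'     are inputs: the underlying per-biomarker appendix profiles are not
#'     published in the main text).}
#'   \item{table4}{signed activities at each compound's optimal dose.}
#' }
#' System ids and biomarker names are canonicalized on load (the typeset
#' tables use variant spellings such as "/Mphg", "PAI-I", "TIMP1", "Esel"),
#' so activity sets from different tables are directly comparable.
#'
#' @param name one of "table2", "table3", "table4".
#' @param dir optional directory holding the fixture TSVs (for testing);
#'   defaults to the package's `extdata`.
#' @return for table2/table4, a named list of [SignedActivitySet-class];
#'   for table3, a named list of [HitCountTable-class].
#' @examples
#' loadFixture("table3")[["C15:0"]]
#' @export
loadFixture <- function(name = c("table2", "table3", "table4"), dir = NULL) {
  name <- match.arg(name)
  if (is.null(dir)) {
    dir <- system.file("extdata", package = "phenoscreen", mustWork = TRUE)
  }
  path <- file.path(dir, paste0(name, if (name == "table3") {
    "_hit_counts.tsv"
  } else {
    "_activities.tsv"
  }))
  if (!file.exists(path)) {
    stop("fixture file not found: ", path, call. = FALSE)
  }

  if (name == "table3") {
    dat <- .readTsv(path, c("compound", "dose_uM", "hits"))
    sets <- lapply(split(dat, dat$compound), function(d) {
      HitCountTable(d$compound[1L], counts = d$hits, doses = d$dose_uM)
    })
    return(sets[unique(dat$compound)])
  }

  dat <- .readTsv(path, c("compound", "dose_label", "system", "biomarker",
                          "direction"))
  sys <- canonicalSystem(dat$system, strict = TRUE)
  dat$system <- sys
  dat$biomarker <- canonicalBiomarker(dat$biomarker, system = sys)
  sets <- lapply(split(dat, dat$compound), function(d) {
    SignedActivitySet(d$compound[1L], d$dose_label[1L],
                      d[, c("system", "biomarker", "direction")])
  })
  sets[unique(dat$compound)]
}
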