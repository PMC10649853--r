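# Biomarker name canonicalization.
#
# The reference activity tables spell several readouts inconsistently
# (PAI-1/PAI-I, TIMP-1/TIMP1, Esel/E-selectin, Eot3/eotaxin-3, ITAC/I-TAC,
# Col-I/collagen-I, TM/thrombomodulin, TF/tissue factor, MMP9/MMP-9, and
# soluble readouts with or without an "s" prefix). Matching across compounds
# and tables therefore goes through a deterministic synonym dictionary keyed
# on a case/hyphen/whitespace-folded form of the raw name.

.foldName <- function(x) {
  gsub("[-_/ ]+", "", tolower(trimws(x)))
}

# folded key -> canonical display name; must map each canonical name's own
# folded form to itself so that canonicalization is idempotent
.BIOMARKER_SYNONYMS <- local({
  canon <- c(
    "MCP-1", "HLA-DR", "VCAM-1", "uPAR", "IL-8", "IL-6", "IL-2", "IL-10",
    "IL-17A", "IL-17F", "IL-1α", "TNFα", "MIP-1α", "IgG",
    "CD38", "CD40", "CD69", "VEGFR", "VEGFR2", "PAI-1", "tPA", "IP-10",
    "I-TAC", "MIG", "M-CSF", "EGFR", "eotaxin-3", "E-selectin", "P-selectin",
    "thrombomodulin", "tissue factor", "collagen-I", "collagen-III",
    "collagen-IV", "decorin", "TIMP-1", "MMP-1", "MMP-3", "MMP-9", "PGE2",
    "SRB", "alamarBlue",
    "endothelial cell proliferation", "coronary artery proliferation",
    "T cell proliferation", "B cell proliferation", "fibroblast proliferation"
  )
  map <- stats::setNames(canon, .foldName(canon))
  extra <- c(
    paii = "PAI-1",
    esel = "E-selectin",
    eot3 = "eotaxin-3",
    tm = "thrombomodulin",
    tf = "tissue factor",
    coli = "collagen-I",
    coliii = "collagen-III",
    coliv = "collagen-IV",
    sigg = "IgG",
    secretedigg = "IgG",
    sil2 = "IL-2",
    sil6 = "IL-6",
    sil10 = "IL-10",
    sil17a = "IL-17A",
    sil17f = "IL-17F",
    il1a = "IL-1α",
    il1alpha = "IL-1α",
    tnfa = "TNFα",
    tnfalpha = "TNFα",
    mip1a = "MIP-1α",
    mip1alpha = "MIP-1α",
    cellproliferation = "proliferation"   # resolved per system below
  )
  c(map, extra)
})

# systems whose bare "proliferation" readout has a conventional qualified name
.PROLIF_BY_SYSTEM <- c(
  "3C" = "endothelial cell proliferation",
  "CASM3C" = "coronary artery proliferation",
  "SAg" = "T cell proliferation",
  "BT" = "B cell proliferation",
  "HDF3CGF" = "fibroblast proliferation"
)

#' Canonicalize biomarker names
#'
#' Maps raw biomarker names to a canonical identifier via a packaged synonym
#' dictionary on top of case/hyphen/whitespace folding. A bare
#' "proliferation" (or "cell proliferation") is resolved to the system's
#' qualified readout name (e.g. "T cell proliferation" in SAg) when the
#' system is given. Unknown names pass through in folded form with a single
#' warning listing them. The mapping is idempotent.
#'
#' @param raw character vector of raw names.
#' @param system optional character vector of system ids (recycled), used
#'   only to resolve bare proliferation readouts.
#' @return character vector of canonical identifiers.
#' @examples
#' canonicalBiomarker(c("PAI-I", "TIMP1", "Esel"))
#' canonicalBiomarker("proliferation", system = "SAg")
#' @export
canonicalBiomarker <- function(raw, system = NA_character_) {
  stopifnot(is.character(raw) | is.factor(raw), all(nzchar(trimws(raw))))
  raw <- as.character(raw)
  system <- rep_len(canonicalSystem(ifelse(is.na(system), "", system)),
                    length(raw))
  key <- .foldName(raw)
  out <- unname(.BIOMARKER_SYNONYMS[key])

  # bare proliferation readouts take the system's qualified name
  bare <- (!is.na(out) & out == "proliferation") | key == "proliferation"
  if (any(bare)) {
    qual <- .PROLIF_BY_SYSTEM[system[bare]]
    out[bare] <- ifelse(is.na(qual), "proliferation", unname(qual))
  }

  unknown <- is.na(out)
  if (any(unknown)) {
    out[unknown] <- key[unknown]
    miss <- unique(raw[unknown])
    warning(length(miss), " biomarker name(s) not in the synonym dictionary; ",
            "folded form used: ",
            paste(utils::head(miss, 8L), collapse = ", "),
            if (length(miss) > 8L) ", ...", call. = FALSE)
  }
  out
}
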