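.PANEL_IDS <- c("3C", "4H", "LPS", "SAg", "BT", "BF4T", "BE3C", "CASM3C",
                "HDF3CGF", "KF3CT", "MyoF", "lMphg")

#' The 12-system reference screening panel
#'
#' Returns the stimulated primary human cell systems of the reference panel:
#' each system is a cell type or co-culture under a disease-relevant cytokine
#' or ligand stimulus, read out through ~148 protein biomarkers in total.
#'
#' @return data.frame with columns `id`, `description`, `disease_relevance`.
#' @examples
#' bioMapPanel()$id
#' @export
bioMapPanel <- function() {
  data.frame(
    id = .PANEL_IDS,
    description = c(
      "Venular endothelial cells + IL-1b, TNFa, IFNg",
      "Venular endothelial cells + IL-4, histamine",
      "Venular endothelial cells and PBMC + TLR4 ligand",
      "Venular endothelial cells and PBMC + TCR ligands",
      "CD19+ B cells and PBMC + alpha-IgM, TCR ligands",
      "Bronchial epithelial cells and dermal fibroblasts + IL-4, TNFa",
      "Bronchial epithelial cells + IL-1b, TNFa, IFNg",
      "Coronary artery smooth muscle cells + IL-1b, TNFa, IFNg",
      "Dermal fibroblasts + IL-1b, TNFa, IFNg, EGF, bFGF, PDGF-BB",
      "Keratinocytes and dermal fibroblasts + IL-1b, TNFa, IFNg, TGFb",
      "Lung myofibroblasts + TNFa, TGFb",
      "Macrophages and venular endothelial cells + TLR2 ligand"
    ),
    disease_relevance = c(
      "Cardiovascular disease, chronic inflammation",
      "Autoimmunity, allergy, asthma",
      "Chronic inflammation, cardiovascular disease",
      "Chronic inflammation, autoimmune disease",
      "Asthma, cancer, autoimmunity, allergy",
      "Fibrosis, lung inflammation, asthma, allergy",
      "COPD, lung inflammation",
      "Cardiovascular inflammation, restenosis",
      "Fibrosis, chronic inflammation",
      "Dermatitis, psoriasis",
      "Wound healing, matrix remodeling, fibrosis",
      "Chronic inflammation, restenosis, cardiovascular disease"
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonicalize cell-system identifiers
#'
#' Folds case and accepts the typeset variant "/Mphg" for the macrophage
#' co-culture system, which is spelled "lMphg" internally.
#'
#' @param x character vector of system ids.
#' @param strict if TRUE, unknown ids are an error; otherwise they pass
#'   through unchanged.
#' @return character vector of canonical ids.
#' @examples
#' canonicalSystem(c("/Mphg", "3c", "SAg"))
#' @export
canonicalSystem <- function(x, strict = FALSE) {
  key <- tolower(trimws(x))
  key[key == "/mphg"] <- "lmphg"
  idx <- match(key, tolower(.PANEL_IDS))
  out <- ifelse(is.na(idx), as.character(x), .PANEL_IDS[idx])
  if (strict && anyNA(idx)) {
    stop("unknown cell system id(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  out
}
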