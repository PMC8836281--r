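## Central S4 classes. Constructors with validation live in the module files.

#' The 20 canonical amino-acid one-letter codes
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Standard monoisotopic residue masses (Da); water and proton constants.
## These are the universal values used by search engines for monoisotopic
## precursor mass; every bundled report mass is consistent with them.
RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MASS  <- 18.010565
PROTON_MASS <- 1.007276

## Nominal printed modification deltas -> exact monoisotopic deltas.
## Reports print rounded deltas (e.g. oxidised Met as "(+15.99)"); mass
## computation needs the exact value to land within 0.002 Da.
CANONICAL_MODS <- c("15.99" = 15.994915)

#' Peptide: a sequence with optional residue modifications
#'
#' An ordered run of canonical amino-acid residues plus a sparse map of
#' residue-level mass deltas (Da), e.g. oxidised methionine at +15.9949 Da.
#' Modification indices are 1-based residue positions.
#'
#' @slot residues character vector of one-letter codes, one per residue.
#' @slot modifications named numeric vector of mass deltas in Da; names are
#'   1-based residue indices.
#' @exportClass Peptide
setClass("Peptide", representation(
  residues      = "character",
  modifications = "numeric"
), prototype(modifications = setNames(numeric(0), character(0))))

setValidity("Peptide", function(object) {
  msgs <- character(0)
  if (length(object@residues) < 1L)
    msgs <- c(msgs, "a peptide must contain at least one residue")
  bad <- which(!object@residues %in% AA_CODES)
  if (length(bad))
    msgs <- c(msgs, sprintf("non-canonical residue '%s' at position %d",
                            object@residues[bad[1]], bad[1]))
  if (length(object@modifications)) {
    idx <- suppressWarnings(as.integer(names(object@modifications)))
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(object@residues)))
      msgs <- c(msgs, "modification indices must be residue positions within the sequence")
  }
  if (length(msgs)) msgs else TRUE
})

#' Residue classification used by physicochemical descriptors
#'
#' @slot hydrophobic residues counted as hydrophobic.
#' @slot basic residues counted as basic (positively charged at neutral pH).
#' @slot antioxidantProne residues commonly implicated in radical
#'   scavenging / electron transfer.
#' @exportClass ResidueClassConfig
setClass("ResidueClassConfig", representation(
  hydrophobic      = "character",
  basic            = "character",
  antioxidantProne = "character"
))

setValidity("ResidueClassConfig", function(object) {
  all_sets <- c(object@hydrophobic, object@basic, object@antioxidantProne)
  if (!all(all_sets %in% AA_CODES))
    return("residue class sets must be subsets of the 20 canonical codes")
  if (length(intersect(object@hydrophobic, object@basic)))
    return("hydrophobic and basic sets must be disjoint")
  TRUE
})

#' Library of short bioactive sequence fragments
#'
#' Each record pairs a short fragment (1-10 residues) with an activity class
#' and, where a published potency exists, an EC50 in micromolar.
#'
#' @slot records data.frame with columns `fragment`, `activity`, `ec50_uM`
#'   (NA when unquantified) and `source`.
#' @exportClass MotifLibrary
setClass("MotifLibrary", representation(records = "data.frame"))

setValidity("MotifLibrary", function(object) {
  r <- object@records
  need <- c("fragment", "activity", "ec50_uM", "source")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) == 0L) return(TRUE)
  if (any(nchar(r$fragment) < 1L))
    return("fragments must contain at least one residue")
  if (anyDuplicated(paste(r$fragment, r$activity)))
    return("(fragment, activity) pairs must be unique")
  if (any(!is.na(r$ec50_uM) & r$ec50_uM <= 0))
    return("EC50 values must be positive")
  TRUE
})

#' Protease cleavage specificity
#'
#' A rule cleaves on the C-terminal side of every residue in `p1` unless the
#' immediately following residue is in `blockP1prime` (classically proline).
#'
#' @slot name identifier of the rule (e.g. "pepsin_ph1.3").
#' @slot p1 residues cleaved after.
#' @slot blockP1prime residues that block cleavage when at P1'.
#' @exportClass EnzymeRule
setClass("EnzymeRule", representation(
  name         = "character",
  p1           = "character",
  blockP1prime = "character"
))

setValidity("EnzymeRule", function(object) {
  if (length(object@p1) < 1L) return("p1 set must be non-empty")
  if (!all(c(object@p1, object@blockP1prime) %in% AA_CODES))
    return("p1 and block sets must be canonical residues")
  TRUE
})

#' Result of digesting a peptide with one (or a chain of) protease rule(s)
#'
#' @slot parent the digested [Peptide-class].
#' @slot enzyme name(s) of the rule(s) applied.
#' @slot fragments character vector of fragment sequences in N-to-C order.
#' @slot cutSites integer vector of 1-based residue positions after which a
#'   cut was made (inter-residue bonds).
#' @slot annotations data.frame of whole-fragment bioactivity matches
#'   (columns `fragment`, `activity`, `ec50_uM`, `source`); empty until
#'   [annotateFragments()] is applied.
#' @exportClass DigestResult
setClass("DigestResult", representation(
  parent      = "Peptide",
  enzyme      = "character",
  fragments   = "character",
  cutSites    = "integer",
  annotations = "data.frame"
))

setValidity("DigestResult", function(object) {
  if (paste(object@fragments, collapse = "") !=
      paste(object@parent@residues, collapse = ""))
    return("fragments must concatenate to the parent sequence")
  if (length(object@fragments) != length(object@cutSites) + 1L)
    return("number of fragments must equal number of cut sites + 1")
  TRUE
})

#' Fluorescence plate for the ACE-inhibition assay
#'
#' Holds the control and blank references and per-concentration sample /
#' sample-blank readings. Replicates are rows sharing a concentration and
#' are averaged before use.
#'
#' @slot fc control fluorescence (enzyme, no inhibitor); replicates allowed.
#' @slot fb blank fluorescence (substrate only); replicates allowed.
#' @slot readings data.frame with columns `concentration` (uM), `fs`
#'   (sample fluorescence) and `fbs` (sample blank).
#' @exportClass AssayPlate
setClass("AssayPlate", representation(
  fc       = "numeric",
  fb       = "numeric",
  readings = "data.frame"
))

setValidity("AssayPlate", function(object) {
  if (mean(object@fc) <= mean(object@fb))
    return("invalid assay: mean control fluorescence must exceed mean blank")
  need <- c("concentration", "fs", "fbs")
  if (!all(need %in% names(object@readings)))
    return(paste("readings must have columns:", paste(need, collapse = ", ")))
  if (any(object@readings$concentration < 0))
    return("concentrations must be non-negative")
  TRUE
})

#' Trolox calibration curve for the ABTS assay
#'
#' @slot points data.frame with columns `concentration` (mM Trolox) and
#'   `response`.
#' @slot slope fitted least-squares slope (response per mM).
#' @slot intercept fitted intercept.
#' @slot r2 coefficient of determination of the fit.
#' @exportClass TroloxCalibration
setClass("TroloxCalibration", representation(
  points    = "data.frame",
  slope     = "numeric",
  intercept = "numeric",
  r2        = "numeric"
))

setValidity("TroloxCalibration", function(object) {
  if (length(unique(object@points$concentration)) < 2L)
    return("calibration needs at least two distinct concentrations")
  if (object@slope == 0) return("calibration slope must be non-zero")
  TRUE
})
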