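#' @export
setGeneric("monoisotopicMass", function(x, ...) standardGeneric("monoisotopicMass"))

#' @export
setGeneric("theoreticalMz", function(x, z, ...) standardGeneric("theoreticalMz"))

#' @export
setGeneric("hydrophobicFraction", function(x, config = residueClassConfig())
  standardGeneric("hydrophobicFraction"))

#' @export
setGeneric("ctermRule", function(x, config = residueClassConfig(), window = 3L)
  standardGeneric("ctermRule"))

#' @export
setGeneric("residueCensus", function(x) standardGeneric("residueCensus"))

#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @export
setGeneric("peptideString", function(x) standardGeneric("peptideString"))

#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setGeneric("modifications", function(x) standardGeneric("modifications"))

#' @export
setGeneric("scanMotifs", function(x, library, activity = "all")
  standardGeneric("scanMotifs"))

#' @export
setGeneric("cleave", function(x, rule) standardGeneric("cleave"))

#' @export
setGeneric("annotateFragments", function(x, library) standardGeneric("annotateFragments"))

#' @export
setGeneric("fragmentString", function(x) standardGeneric("fragmentString"))

#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @export
setGeneric("cutSites", function(x) standardGeneric("cutSites"))

#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @export
setGeneric("motifRecords", function(x) standardGeneric("motifRecords"))
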