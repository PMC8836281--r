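## FASTA import/export of peptide sequences (Biostrings-backed).

#' Write peptides to FASTA
#'
#' Modifications are flattened to the bare sequence; the annotated string is
#' kept in the FASTA header so no information is silently lost.
#'
#' @param peptides list of [Peptide-class] objects (or a single one).
#' @param path output file.
#' @param names optional record names; defaults to `pep1`, `pep2`, ...
#' @return Invisibly, the path.
#' @export
writePeptideFasta <- function(peptides, path, names = NULL) {
  if (is(peptides, "Peptide")) peptides <- list(peptides)
  bare <- vapply(peptides, peptideSequence, character(1))
  annotated <- vapply(peptides, peptideString, character(1))
  if (is.null(names)) names <- paste0("pep", seq_along(peptides))
  hdr <- ifelse(annotated == bare, names, paste(names, annotated))
  set <- Biostrings::AAStringSet(setNames(bare, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file of plain amino-acid sequences.
#' @return Named list of [Peptide-class] objects (no modifications; FASTA
#'   carries bare sequences only).
#' @export
readPeptideFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  peps <- lapply(as.character(set), parsePeptide)
  names(peps) <- sub("\\s.*$", "", names(set))
  peps
}
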