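## In-silico gastrointestinal digestion: declarative protease specificity
## engine plus whole-fragment bioactivity annotation.

#' Construct a protease cleavage rule
#'
#' @param name rule identifier.
#' @param p1 residues cleaved on their C-terminal side.
#' @param blockP1prime residues blocking cleavage when immediately following
#'   the site (default proline).
#' @return An [EnzymeRule-class].
#' @export
enzymeRule <- function(name, p1, blockP1prime = "P") {
  new("EnzymeRule", name = name, p1 = p1, blockP1prime = blockP1prime)
}

#' Bundled digestive-enzyme profiles
#'
#' Loads the editable specificity profiles shipped with the package:
#' `pepsin_ph1.3` (cleaves after F, L; no P1' block), `trypsin` (after K, R;
#' blocked before P) and `chymotrypsin_like` (after F, L, M, N, W, Y;
#' blocked before P). The chymotrypsin-like profile is broader than the
#' classical aromatic-only specificity: it is the rule set consistent with
#' published in-silico digestion tables of food peptides, which cut after
#' Asn and Leu as well.
#'
#' @param path optional path to an alternative profile TSV (columns `name`,
#'   `p1`, `blockP1prime`; residue sets written as strings like `"FLMNWY"`).
#' @return Named list of [EnzymeRule-class] objects.
#' @export
defaultEnzymes <- function(path = system.file("extdata", "enzyme_profiles.tsv",
                                              package = "pepscreen",
                                              mustWork = TRUE)) {
  tab <- read.delim(path, sep = "\t", colClasses = "character",
                    strip.white = TRUE)
  rules <- lapply(seq_len(nrow(tab)), function(i)
    enzymeRule(tab$name[i], strsplit(tab$p1[i], "")[[1]],
               strsplit(tab$blockP1prime[i], "")[[1]]))
  names(rules) <- tab$name
  rules
}

setMethod("show", "EnzymeRule", function(object) {
  cat(sprintf("EnzymeRule '%s': cleaves after {%s}%s\n", object@name,
              paste(object@p1, collapse = ","),
              if (length(object@blockP1prime))
                sprintf(" unless followed by {%s}",
                        paste(object@blockP1prime, collapse = ",")) else ""))
})

## 1-based positions i such that the bond after residue i is cleaved
ruleCutSites <- function(residues, rule) {
  n <- length(residues)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  i[residues[i] %in% rule@p1 & !residues[i + 1L] %in% rule@blockP1prime]
}

#' Digest a peptide with one cleavage rule
#'
#' Cuts after every P1 residue whose successor exists and is not blocked at
#' P1'. Fragments are returned in N-to-C order and always concatenate to
#' the parent's bare sequence.
#'
#' @param x a [Peptide-class].
#' @param rule an [EnzymeRule-class].
#' @return A [DigestResult-class] (annotations empty; see
#'   [annotateFragments()]).
#' @examples
#' \dontrun{
#' r <- defaultEnzymes()
#' fragmentString(cleave(parsePeptide("CPANGFY"), r$chymotrypsin_like))
#' # "CPAN-GF-Y"
#' }
#' @export
setMethod("cleave", "Peptide", function(x, rule) {
  sites <- ruleCutSites(x@residues, rule)
  bounds <- c(0L, sites, length(x@residues))
  frags <- vapply(seq_len(length(bounds) - 1L), function(k)
    paste(x@residues[(bounds[k] + 1L):bounds[k + 1L]], collapse = ""),
    character(1))
  new("DigestResult", parent = x, enzyme = rule@name, fragments = frags,
      cutSites = as.integer(sites), annotations = emptyAnnotations())
})

emptyAnnotations <- function()
  data.frame(fragment = character(0), activity = character(0),
             ec50_uM = numeric(0), source = character(0),
             stringsAsFactors = FALSE)

#' Digest a peptide with several enzymes
#'
#' Independent mode (default) digests the intact parent with each rule
#' separately, mirroring per-enzyme presentation; sequential mode feeds the
#' fragments of each rule into the next, accumulating cut sites, as in a
#' stomach-then-intestine passage.
#'
#' @param peptide a [Peptide-class].
#' @param rules list of [EnzymeRule-class] objects (e.g. [defaultEnzymes()]).
#' @param mode `"independent"` or `"sequential"`.
#' @return Named list of [DigestResult-class], one per rule (sequential
#'   mode: the result after applying rules 1..i).
#' @export
digestMulti <- function(peptide, rules, mode = c("independent", "sequential")) {
  mode <- match.arg(mode)
  if (length(rules) < 1L) stop("at least one enzyme rule is required")
  nms <- vapply(rules, function(r) r@name, character(1))
  if (mode == "independent") {
    out <- lapply(rules, function(r) cleave(peptide, r))
  } else {
    out <- vector("list", length(rules))
    sites <- integer(0)
    applied <- character(0)
    for (i in seq_along(rules)) {
      sites <- sort(union(sites, ruleCutSites(peptide@residues, rules[[i]])))
      applied <- c(applied, rules[[i]]@name)
      bounds <- c(0L, sites, length(peptide@residues))
      frags <- vapply(seq_len(length(bounds) - 1L), function(k)
        paste(peptide@residues[(bounds[k] + 1L):bounds[k + 1L]], collapse = ""),
        character(1))
      out[[i]] <- new("DigestResult", parent = peptide,
                      enzyme = paste(applied, collapse = "+"),
                      fragments = frags, cutSites = as.integer(sites),
                      annotations = emptyAnnotations())
    }
  }
  names(out) <- nms
  out
}

#' Annotate digestion fragments with known bioactivities
#'
#' A fragment is annotated when it matches a library fragment exactly
#' (whole-fragment identity, not substring containment): activity survives
#' digestion only if the active sequence itself is released intact.
#'
#' @param x a [DigestResult-class].
#' @param library a [MotifLibrary-class].
#' @return The [DigestResult-class] with its `annotations` slot populated.
#' @export
setMethod("annotateFragments", "DigestResult", function(x, library) {
  recs <- motifRecords(library)
  hit <- recs[recs$fragment %in% x@fragments, , drop = FALSE]
  rownames(hit) <- NULL
  x@annotations <- hit
  x
})

#' @describeIn cleave fragments in N-to-C order.
#' @export
setMethod("fragments", "DigestResult", function(x) x@fragments)

#' @describeIn cleave 1-based residue positions cut after.
#' @export
setMethod("cutSites", "DigestResult", function(x) x@cutSites)

#' @describeIn cleave whole-fragment bioactivity annotations.
#' @export
setMethod("annotations", "DigestResult", function(x) x@annotations)

#' @describeIn cleave hyphen-joined fragment notation, e.g. `"CPAN-GF-Y"`.
#' @export
setMethod("fragmentString", "DigestResult", function(x)
  paste(x@fragments, collapse = "-"))

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult (%s): %s\n", object@enzyme, fragmentString(object)))
  if (nrow(object@annotations)) {
    for (i in seq_len(nrow(object@annotations)))
      cat(sprintf("  %s: %s\n", object@annotations$fragment[i],
                  object@annotations$activity[i]))
  }
})

#' Write a digestion report
#'
#' One row per (peptide, enzyme): hyphen-joined fragments plus any
#' whole-fragment bioactivity annotations.
#'
#' @param digests named list (per peptide) of named lists (per enzyme) of
#'   [DigestResult-class] objects, as produced by [digestMulti()].
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writeDigestReport <- function(digests, path) {
  rows <- list()
  for (pep in names(digests)) {
    for (enz in names(digests[[pep]])) {
      d <- digests[[pep]][[enz]]
      ann <- if (nrow(d@annotations))
        paste(sprintf("%s: %s", d@annotations$fragment,
                      d@annotations$activity), collapse = "; ") else ""
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, enzyme = enz, fragments = fragmentString(d),
        bioactive_fragments = ann, stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
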