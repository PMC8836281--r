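## Bioactive-fragment dictionary and motif scanning.

#' Construct a motif library from a records data.frame
#'
#' @param records data.frame with columns `fragment`, `activity`, `ec50_uM`
#'   (NA allowed) and `source`. Duplicate (fragment, activity) rows resolve
#'   last-wins with a warning.
#' @return A [MotifLibrary-class].
#' @export
motifLibrary <- function(records) {
  if (nrow(records)) {
    key <- paste(records$fragment, records$activity)
    if (anyDuplicated(key)) {
      warning("duplicate (fragment, activity) rows; keeping the last of each")
      records <- records[!duplicated(key, fromLast = TRUE), , drop = FALSE]
      rownames(records) <- NULL
    }
  }
  new("MotifLibrary", records = records)
}

#' Load a motif library from delimited text
#'
#' Expected columns: `fragment`, `activity`, `ec50_uM` (blank when
#' unquantified), `source`. TSV or CSV autodetected.
#'
#' @param path file path.
#' @return A [MotifLibrary-class].
#' @export
loadMotifLibrary <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  need <- c("fragment", "activity", "ec50_uM", "source")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("motif library schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0L)
    return(motifLibrary(data.frame(fragment = character(0),
                                   activity = character(0),
                                   ec50_uM = numeric(0),
                                   source = character(0))))
  ec <- trimws(raw$ec50_uM)
  ec[ec %in% c("", "NA")] <- NA
  bad <- !is.na(ec) & is.na(suppressWarnings(as.numeric(ec)))
  if (any(bad))
    stop(sprintf("row %d: malformed EC50 value '%s'", which(bad)[1],
                 ec[which(bad)[1]]))
  motifLibrary(data.frame(fragment = raw$fragment, activity = raw$activity,
                          ec50_uM = as.numeric(ec), source = raw$source,
                          stringsAsFactors = FALSE))
}

#' Bundled default motif library
#'
#' A small, fully referenced dictionary of short bioactive fragments
#' (ACE / DPP-IV / DPP-III / renin inhibitors and one opioid motif) with
#' published EC50 values where available. It is intentionally compact —
#' every record traces to a published potency or activity annotation — and
#' is meant to be extended (or replaced by a full BIOPEP export) via
#' [loadMotifLibrary()] and [mergeMotifLibraries()].
#'
#' @return A [MotifLibrary-class].
#' @export
defaultMotifLibrary <- function() {
  loadMotifLibrary(system.file("extdata", "motif_library.tsv",
                               package = "pepscreen", mustWork = TRUE))
}

#' @describeIn motifLibrary records data.frame accessor.
#' @param x a `MotifLibrary`.
#' @export
setMethod("motifRecords", "MotifLibrary", function(x) x@records)

#' @export
setMethod("length", "MotifLibrary", function(x) nrow(x@records))

setMethod("show", "MotifLibrary", function(object) {
  cat(sprintf("MotifLibrary: %d records, %d activity classes\n",
              nrow(object@records), length(unique(object@records$activity))))
  if (nrow(object@records))
    print(head(object@records, 5))
})

#' Merge motif libraries
#'
#' Later libraries win on duplicate (fragment, activity) pairs.
#'
#' @param ... [MotifLibrary-class] objects.
#' @return A merged [MotifLibrary-class].
#' @export
mergeMotifLibraries <- function(...) {
  libs <- list(...)
  recs <- do.call(rbind, lapply(libs, motifRecords))
  suppressWarnings(motifLibrary(recs))
}

#' Scan a peptide for bioactive motifs
#'
#' Finds every occurrence of every library fragment as a contiguous
#' substring of the peptide's bare (modification-stripped) sequence.
#' Overlapping occurrences are all reported.
#'
#' @param x a [Peptide-class].
#' @param library a [MotifLibrary-class].
#' @param activity restrict to one activity class, or `"all"` (default).
#' @return data.frame with columns `fragment`, `start` (1-based position),
#'   `activity`, `ec50_uM`, `source`, ordered by start then fragment.
#' @examples
#' \dontrun{
#' scanMotifs(parsePeptide("CCYSVY"), defaultMotifLibrary())
#' }
#' @export
setMethod("scanMotifs", "Peptide", function(x, library, activity = "all") {
  recs <- motifRecords(library)
  if (!identical(activity, "all"))
    recs <- recs[recs$activity %in% activity, , drop = FALSE]
  seq <- peptideSequence(x)
  hits <- lapply(seq_len(nrow(recs)), function(i) {
    frag <- recs$fragment[i]
    starts <- allSubstringStarts(seq, frag)
    if (!length(starts)) return(NULL)
    data.frame(fragment = frag, start = starts, activity = recs$activity[i],
               ec50_uM = recs$ec50_uM[i], source = recs$source[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(fragment = character(0), start = integer(0),
                      activity = character(0), ec50_uM = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$fragment, out$activity), , drop = FALSE]
  rownames(out) <- NULL
  out
})

## all (possibly overlapping) 1-based start positions of `pattern` in `subject`
allSubstringStarts <- function(subject, pattern) {
  np <- nchar(pattern)
  ns <- nchar(subject)
  if (np > ns) return(integer(0))
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(subject, from, ns), fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos)
    from <- pos + 1L   # step one residue to catch overlaps
    if (from + np - 1L > ns) break
  }
  starts
}
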