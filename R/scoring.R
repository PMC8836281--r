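## BIOPEP-style activity profile: frequency (A) and potency (B) parameters.

#' Frequency of bioactive fragments (parameter A)
#'
#' `A = a / N`: the number of fragments with a previously reported activity
#' divided by the peptide's residue count. Published tables print A to four
#' decimals; use `round(parameterA(a, n), 4)` for table comparison.
#'
#' @param a fragment count (>= 0).
#' @param n residue count (>= 1).
#' @return Frequency (unrounded).
#' @examples
#' round(parameterA(7, 9), 4)  # 0.7778
#' @export
parameterA <- function(a, n) {
  if (any(n < 1)) stop("residue count N must be >= 1")
  if (any(a < 0)) stop("fragment count must be non-negative")
  a / n
}

#' Potential biological activity (parameter B)
#'
#' `B = sum_i(1 / EC50_i) / N` in inverse micromolar: the summed reciprocal
#' potencies of the quantified fragments present in the peptide, per
#' residue. Fragments without a published EC50 contribute to A but not B.
#'
#' @param ec50 numeric vector of EC50 values in uM (all > 0); may be empty.
#' @param n residue count (>= 1).
#' @return Potency in uM^-1 (0 when no quantified fragments).
#' @export
parameterB <- function(ec50, n) {
  if (n < 1) stop("residue count N must be >= 1")
  ec50 <- ec50[!is.na(ec50)]
  if (any(ec50 <= 0)) stop("EC50 values must be positive")
  if (!length(ec50)) return(0)
  sum(1 / ec50) / n
}

#' Activity profile of a peptide against a motif library
#'
#' Scans the peptide (see [scanMotifs()]) and aggregates, per activity
#' class: the fragment count `a`, frequency `A = a/N`, and potency
#' `B = sum(1/EC50)/N` over the quantified fragments.
#'
#' Counting mode: `"site"` (default) counts every occurrence position, so a
#' motif found twice counts twice; `"distinct"` counts each (fragment,
#' activity) pair once regardless of multiplicity. Published profiles report
#' final counts only, so both conventions are exposed.
#'
#' @param peptide a [Peptide-class].
#' @param library a [MotifLibrary-class].
#' @param counting `"site"` or `"distinct"`.
#' @return data.frame with columns `activity`, `count`, `A`, `B`, one row
#'   per activity class found (zero rows for a motif-free peptide).
#' @export
activityProfile <- function(peptide, library, counting = c("site", "distinct")) {
  counting <- match.arg(counting)
  hits <- scanMotifs(peptide, library)
  n <- nResidues(peptide)
  if (counting == "distinct")
    hits <- hits[!duplicated(paste(hits$fragment, hits$activity)), , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(activity = character(0), count = integer(0),
                      A = numeric(0), B = numeric(0)))
  classes <- sort(unique(hits$activity))
  out <- do.call(rbind, lapply(classes, function(cl) {
    h <- hits[hits$activity == cl, , drop = FALSE]
    data.frame(activity = cl, count = nrow(h),
               A = parameterA(nrow(h), n),
               B = parameterB(h$ec50_uM, n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export activity profiles as a delimited table or JSON
#'
#' Table layout mirrors the published profile tables: sequence, activity,
#' count, A (4 decimals), B.
#'
#' @param profiles named list of profile data.frames from
#'   [activityProfile()] (names are the peptide sequences).
#' @param path output path; `.json` selects JSON, otherwise TSV.
#' @return Invisibly, the path.
#' @export
writeActivityProfiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    if (nrow(p) == 0L) return(NULL)
    cbind(data.frame(sequence = nm, stringsAsFactors = FALSE), p)
  }))
  if (is.null(tab))
    tab <- data.frame(sequence = character(0), activity = character(0),
                      count = integer(0), A = numeric(0), B = numeric(0))
  tab$A <- round(tab$A, 4)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
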