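## Multi-criterion candidate selection: turn profiles, digestion results and
## report metadata into per-criterion flags and a deterministic ranking.

#' Selection criteria for candidate bioactive peptides
#'
#' The screen evaluates, per peptide: a water-solubility proxy (hydrophobic
#' fraction at most `maxHydrophobicFraction`), predicted activity in every
#' class of `requireActivity`, survival of at least one annotated bioactive
#' fragment through some digestive enzyme, relative abundance (disabled
#' unless `minArea` is set), the C-terminal composition rule, and the
#' presence of cysteine. Criteria listed in `required` decide the overall
#' verdict; the rest are scored but advisory (cysteine by default, since
#' it matters for antioxidant but not ACE-inhibitory candidates).
#'
#' @param maxHydrophobicFraction solubility cut on the hydrophobic fraction
#'   (default 0.85).
#' @param requireActivity activity classes that must be predicted (default
#'   ACE inhibition; add `"antioxidant"` when the library quantifies it).
#' @param requireDigestionSurvival logical (default TRUE).
#' @param minArea abundance threshold, `NA` disables (default).
#' @param requireCtermRule logical (default TRUE).
#' @param requireCysteine logical (default FALSE: scored, not required).
#' @return A list of class `SelectionCriteria`.
#' @export
selectionCriteria <- function(maxHydrophobicFraction = 0.85,
                              requireActivity = "ACE_inhibitor",
                              requireDigestionSurvival = TRUE,
                              minArea = NA_real_,
                              requireCtermRule = TRUE,
                              requireCysteine = FALSE) {
  stopifnot(maxHydrophobicFraction >= 0, maxHydrophobicFraction <= 1)
  structure(list(maxHydrophobicFraction = maxHydrophobicFraction,
                 requireActivity = requireActivity,
                 requireDigestionSurvival = requireDigestionSurvival,
                 minArea = minArea,
                 requireCtermRule = requireCtermRule,
                 requireCysteine = requireCysteine),
            class = "SelectionCriteria")
}

#' Evaluate one peptide against the selection criteria
#'
#' Each criterion is evaluated independently to `"pass"`, `"fail"` or
#' `"absent"` (data not available — e.g. a missing area — which never
#' counts as a failure). The overall verdict is TRUE when every *required*
#' criterion passes.
#'
#' @param peptide a [Peptide-class].
#' @param profile data.frame from [activityProfile()] for this peptide.
#' @param digests named list of (annotated) [DigestResult-class] objects for
#'   this peptide, e.g. `lapply(digestMulti(p, defaultEnzymes()),
#'   annotateFragments, library = lib)`.
#' @param record optional single-row data.frame of report metadata (used
#'   for `area`); its sequence must match the peptide.
#' @param criteria a [selectionCriteria()].
#' @param config a [residueClassConfig()].
#' @return List of class `CandidateReport`: `sequence`, `flags` (named
#'   character vector), `nPass`, `area`, `overall`.
#' @export
evaluateCandidate <- function(peptide, profile, digests, record = NULL,
                              criteria = selectionCriteria(),
                              config = residueClassConfig()) {
  if (!is.null(record)) {
    if (stripMods(record$sequence[1]) != peptideSequence(peptide))
      stop("record sequence does not match the peptide being evaluated")
  }
  flags <- character(0)

  hf <- hydrophobicFraction(peptide, config)
  flags["solubility"] <- if (hf <= criteria$maxHydrophobicFraction)
    "pass" else "fail"

  if (length(criteria$requireActivity)) {
    found <- criteria$requireActivity %in%
      profile$activity[profile$count > 0]
    flags["predicted_activity"] <- if (all(found)) "pass" else "fail"
  }

  if (criteria$requireDigestionSurvival) {
    survived <- any(vapply(digests, function(d) nrow(annotations(d)) > 0,
                           logical(1)))
    flags["digestion_survival"] <- if (survived) "pass" else "fail"
  }

  area <- if (!is.null(record) && "area" %in% names(record))
    record$area[1] else NA_real_
  if (!is.na(criteria$minArea)) {
    flags["abundance"] <- if (is.na(area)) "absent"
      else if (area >= criteria$minArea) "pass" else "fail"
  }

  if (criteria$requireCtermRule)
    flags["cterm_rule"] <- if (ctermRule(peptide, config)) "pass" else "fail"

  flags["cysteine"] <- if ("C" %in% peptide@residues) "pass" else "fail"

  required <- setdiff(names(flags), if (!criteria$requireCysteine) "cysteine")
  overall <- all(flags[required] %in% c("pass", "absent"))
  structure(list(sequence = peptideSequence(peptide), flags = flags,
                 nPass = sum(flags == "pass"), area = area,
                 overall = overall),
            class = "CandidateReport")
}

#' Rank candidate reports
#'
#' Descending number of passed criteria; ties broken by higher area (absent
#' areas last), then lexicographic sequence. The order is total and
#' deterministic.
#'
#' @param reports list of `CandidateReport` objects from
#'   [evaluateCandidate()].
#' @return The reports, reordered.
#' @export
rankCandidates <- function(reports) {
  if (length(reports) < 1L) stop("at least one report is required")
  nPass <- vapply(reports, function(r) r$nPass, numeric(1))
  area <- vapply(reports, function(r) r$area, numeric(1))
  area[is.na(area)] <- -Inf
  seqs <- vapply(reports, function(r) r$sequence, character(1))
  reports[order(-nPass, -area, seqs)]
}

#' Tabulate candidate reports
#'
#' @param reports list of `CandidateReport` objects.
#' @return data.frame: one row per peptide, one column per criterion flag,
#'   plus `nPass`, `area` and `overall`.
#' @export
candidateTable <- function(reports) {
  all_flags <- unique(unlist(lapply(reports, function(r) names(r$flags))))
  rows <- lapply(reports, function(r) {
    f <- setNames(rep("absent", length(all_flags)), all_flags)
    f[names(r$flags)] <- r$flags
    cbind(data.frame(sequence = r$sequence, stringsAsFactors = FALSE),
          as.data.frame(as.list(f), stringsAsFactors = FALSE),
          data.frame(nPass = r$nPass, area = r$area, overall = r$overall))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
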