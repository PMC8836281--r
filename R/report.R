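## Identification-report I/O, acceptance filtering, protein roll-up.
##
## Reports are delimited text mirroring the export of a database-search
## ("db") or de-novo ("denovo") identification run: one row per peptide
## identification with score, mass, m/z, retention time, ppm error,
## label-free area and (de novo) per-residue local confidence.

## round-half-up to integer; report ALC values are printed this way
roundHalfUp <- function(x) floor(x + 0.5)

# canonical name -> accepted header spellings (lower-cased, trimmed)
REPORT_HEADER_MAP <- list(
  sequence         = c("sequence", "peptide", "peptide sequence"),
  neg10lgP         = c("neg10lgp", "-10lgp", "-10 lgp", "−10 lgp", "−10lgp"),
  alc              = c("alc", "alc (%)", "alc_percent", "alc%"),
  local_confidence = c("local_confidence", "local confidence", "local confidence (%)"),
  mz               = c("mz", "m/z"),
  mass             = c("mass"),
  rt               = c("rt", "retention time"),
  ppm              = c("ppm"),
  area             = c("area"),
  z                = c("z", "charge"),
  sample_id        = c("sample_id", "sample"),
  accessions       = c("accessions", "accession")
)

MANDATORY_COLS <- list(db = c("sequence", "neg10lgP"),
                       denovo = c("sequence", "local_confidence"))

stripMods <- function(seq) gsub("\\([+−-][0-9]+(\\.[0-9]+)?\\)", "", seq)

#' Read a peptide identification report
#'
#' Reads delimited text (TSV or CSV, autodetected) in either the
#' database-search flavour (`"db"`, score column `neg10lgP`) or the de-novo
#' flavour (`"denovo"`, per-residue `local_confidence` string such as
#' `"92 97 99 93 92 98"`, from which the ALC is recomputed). Header names
#' are matched case-insensitively against common spellings. Areas given as
#' `"ND"` or blank become `NA`.
#'
#' @param path file path.
#' @param flavour `"db"` or `"denovo"`.
#' @return data.frame with canonical columns (one row per identification);
#'   `local_confidence` is a list-column of numeric vectors; the flavour is
#'   stored in `attr(, "flavour")`.
#' @export
readPeaksReport <- function(path, flavour = c("db", "denovo")) {
  flavour <- match.arg(flavour)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  lc_names <- tolower(trimws(names(raw)))
  canon <- rep(NA_character_, length(lc_names))
  for (nm in names(REPORT_HEADER_MAP))
    canon[lc_names %in% REPORT_HEADER_MAP[[nm]]] <- nm
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  missing <- setdiff(MANDATORY_COLS[[flavour]], names(raw))
  if (flavour == "denovo" && "local_confidence" %in% missing && "alc" %in% names(raw))
    missing <- setdiff(missing, "local_confidence")
  if (length(missing))
    stop(sprintf("report schema error: missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))

  out <- data.frame(sequence = raw$sequence, stringsAsFactors = FALSE)
  num_cols <- intersect(c("neg10lgP", "alc", "mz", "mass", "rt", "ppm", "z"),
                        names(raw))
  for (nm in num_cols) out[[nm]] <- as.numeric(raw[[nm]])
  if ("area" %in% names(raw)) {
    a <- raw$area
    a[toupper(a) %in% c("ND", "NA", "")] <- NA
    out$area <- as.numeric(a)
  }
  if ("sample_id" %in% names(raw)) out$sample_id <- raw$sample_id
  if ("accessions" %in% names(raw)) out$accessions <- raw$accessions
  if ("local_confidence" %in% names(raw)) {
    lc <- lapply(strsplit(trimws(raw$local_confidence), "\\s+"), as.numeric)
    nres <- nchar(stripMods(out$sequence))
    len_ok <- lengths(lc) == nres | !nzchar(trimws(raw$local_confidence))
    if (any(!len_ok))
      stop(sprintf(
        "row %d: local-confidence length %d does not match sequence length %d",
        which(!len_ok)[1], lengths(lc)[which(!len_ok)[1]], nres[which(!len_ok)[1]]))
    bad_rng <- vapply(lc, function(v) any(v < 0 | v > 100), logical(1))
    if (any(bad_rng))
      stop(sprintf("row %d: local-confidence values outside [0, 100]",
                   which(bad_rng)[1]))
    out$local_confidence <- I(lc)
    if (!"alc" %in% names(out))
      out$alc <- vapply(lc, function(v) computeALC(v)$alc, numeric(1))
  }
  attr(out, "flavour") <- flavour
  out
}

#' Write a peptide identification report
#'
#' Inverse of [readPeaksReport()]: emits canonical headers, re-joins
#' local-confidence vectors with spaces and writes absent areas as `"ND"`.
#' Reading the written file back reproduces every parsed field.
#'
#' @param records data.frame as returned by [readPeaksReport()].
#' @param path output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return Invisibly, the path.
#' @export
writePeaksReport <- function(records, path) {
  out <- records
  if ("local_confidence" %in% names(out))
    out$local_confidence <- vapply(out$local_confidence, function(v)
      paste(format(v, trim = TRUE, scientific = FALSE), collapse = " "),
      character(1))
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- vapply(out[[nm]], function(v)
        if (is.na(v)) "ND" else format(v, digits = 15, trim = TRUE,
                                       scientific = FALSE), character(1))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average local confidence (ALC) of a de-novo identification
#'
#' Arithmetic mean of the per-residue local-confidence scores. Reports print
#' the ALC as an integer; the comparison value uses round-half-up.
#'
#' @param localConfidence numeric vector of per-residue percentages.
#' @return List with `alc` (nearest integer, half away from zero) and
#'   `mean` (unrounded).
#' @examples
#' computeALC(c(92, 97, 99, 93, 92, 98))$alc  # 95
#' @export
computeALC <- function(localConfidence) {
  if (length(localConfidence) == 0L || anyNA(localConfidence))
    stop("local confidence vector must be non-empty and complete")
  m <- mean(localConfidence)
  list(alc = roundHalfUp(m), mean = m)
}

#' Identification score from a p-value
#'
#' The database-search significance score is `-10 * log10(p)`: a score of 20
#' corresponds to p = 0.01 and the conventional high-confidence threshold of
#' 30 to p = 0.001.
#'
#' @param p p-value(s) in (0, 1].
#' @return Score(s).
#' @export
neg10lgP <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  -10 * log10(p)
}

#' Report acceptance-filter policy
#'
#' Defaults follow the conventional acceptance rules for endogenous-peptide
#' reports: database-search score >= 30 (p = 0.001), de-novo ALC >= 90,
#' precursor charge >= +2, and presence in at least two individual samples.
#'
#' @param minNeg10lgP minimum database-search score.
#' @param minAlc minimum ALC (percent, compared on the rounded value).
#' @param minSamples minimum number of distinct samples in which the
#'   (modification-stripped) sequence must appear.
#' @param minCharge minimum precursor charge state.
#' @return A list of class `FilterPolicy`.
#' @export
filterPolicy <- function(minNeg10lgP = 30, minAlc = 90, minSamples = 2L,
                         minCharge = 2L) {
  stopifnot(minNeg10lgP >= 0, minAlc >= 0, minSamples >= 0, minCharge >= 0)
  structure(list(minNeg10lgP = minNeg10lgP, minAlc = minAlc,
                 minSamples = as.integer(minSamples),
                 minCharge = as.integer(minCharge)),
            class = "FilterPolicy")
}

#' Apply acceptance filters to an identification report
#'
#' Retains records that meet the flavour's score threshold, the minimum
#' charge, and whose modification-stripped sequence occurs in at least
#' `minSamples` distinct samples. Row order is preserved, and the output is
#' always a subset of the input. Columns absent from the report (e.g. no
#' charge column) leave the corresponding rule inapplicable rather than
#' failing every record; sample replication falls back to counting rows per
#' sequence when no `sample_id` column exists.
#'
#' @param records data.frame from [readPeaksReport()] (or compatibly shaped).
#' @param policy a [filterPolicy()].
#' @return Filtered data.frame, flavour attribute preserved.
#' @export
applyFilters <- function(records, policy = filterPolicy()) {
  flavour <- attr(records, "flavour")
  if (is.null(flavour)) {
    has_db <- "neg10lgP" %in% names(records)
    has_dn <- any(c("alc", "local_confidence") %in% names(records))
    if (has_db && has_dn)
      stop("mixed-flavour records: both neg10lgP and ALC columns present")
    if (!has_db && !has_dn)
      stop("records carry neither a neg10lgP nor an ALC column")
    flavour <- if (has_db) "db" else "denovo"
  }
  n <- nrow(records)
  if (n == 0L) return(records)

  keep_score <- if (flavour == "db") {
    records$neg10lgP >= policy$minNeg10lgP
  } else {
    alc <- if ("alc" %in% names(records)) records$alc else
      vapply(records$local_confidence, function(v) computeALC(v)$alc, numeric(1))
    roundHalfUp(alc) >= policy$minAlc
  }
  keep_charge <- if ("z" %in% names(records))
    records$z >= policy$minCharge else rep(TRUE, n)
  key <- stripMods(records$sequence)
  n_samples <- if ("sample_id" %in% names(records)) {
    vapply(key, function(k)
      length(unique(records$sample_id[key == k])), integer(1))
  } else {
    as.integer(table(key)[key])
  }
  keep <- keep_score & keep_charge & (n_samples >= policy$minSamples)
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  attr(out, "flavour") <- flavour
  out
}

#' Roll peptide records up to their source proteins
#'
#' Protein relative abundance is the sum of the supporting peptides' areas
#' (absent areas count as zero); the protein score defaults to the plain sum
#' of supporting scores, with `scoreFun` as a hook for weighted schemes.
#' Records listing several accessions (separated by `:`, `;` or `,`)
#' contribute to each. Sequence coverage requires residue positions, which
#' identification reports do not carry, and is reported as `NA`; supplying
#' `proteinLengths` with unknown accessions triggers a warning.
#'
#' @param records data.frame with at least `sequence` and `accessions`
#'   columns (plus `area` and a score column where available).
#' @param proteinLengths optional named vector, accession -> residue count.
#' @param scoreFun aggregation for supporting-peptide scores (default `sum`).
#' @return data.frame with one row per accession: `accession`,
#'   `proteinScore`, `nSupporting`, `totalArea`, `coveragePercent`, and a
#'   `supporting` list-column of supporting sequences.
#' @export
rollupProteins <- function(records, proteinLengths = NULL, scoreFun = sum) {
  if (!"accessions" %in% names(records))
    stop("records must carry an 'accessions' column")
  acc_list <- strsplit(records$accessions, "[;:,]")
  accs <- sort(unique(unlist(acc_list)))
  if (!is.null(proteinLengths)) {
    unknown <- setdiff(accs, names(proteinLengths))
    if (length(unknown))
      warning("no protein length for accession(s): ",
              paste(unknown, collapse = ", "), "; coverage left absent")
  }
  score_col <- intersect(c("neg10lgP", "alc"), names(records))[1]
  rows <- lapply(accs, function(a) {
    idx <- which(vapply(acc_list, function(v) a %in% v, logical(1)))
    areas <- if ("area" %in% names(records)) records$area[idx] else
      rep(NA_real_, length(idx))
    areas[is.na(areas)] <- 0
    sc <- if (!is.na(score_col)) scoreFun(records[[score_col]][idx]) else NA_real_
    data.frame(accession = a, proteinScore = sc, nSupporting = length(idx),
               totalArea = sum(areas), coveragePercent = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$supporting <- I(lapply(accs, function(a)
    records$sequence[vapply(acc_list, function(v) a %in% v, logical(1))]))
  out
}

#' Export a protein roll-up as JSON
#'
#' @param rollup data.frame from [rollupProteins()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeRollupJson <- function(rollup, path) {
  jsonlite::write_json(rollup, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
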