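## Sequence model: parsing of the inline "(+x.xx)" modification dialect,
## mass/charge arithmetic, and physicochemical descriptors.

#' Parse a modification-annotated peptide sequence string
#'
#' Accepts one-letter amino-acid codes with optional inline residue
#' modifications written as a parenthesised signed delta immediately after
#' the modified residue, e.g. `"LLLGAGCM(+15.99)"` for a C-terminal oxidised
#' methionine. Both ASCII `-` and Unicode minus are accepted for negative
#' deltas. Formatting the result with [peptideString()] reproduces the
#' input string.
#'
#' @param text sequence string.
#' @return A [Peptide-class] object.
#' @examples
#' p <- parsePeptide("LLLGAGCM(+15.99)")
#' nResidues(p)      # 8
#' modifications(p)  # +15.99 at position 8
#' @export
parsePeptide <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("'text' must be a single non-empty string")
  chars <- strsplit(text, "")[[1]]
  residues <- character(0)
  mods <- numeric(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == ")") { close <- j; break }
      }
      if (is.na(close))
        stop(sprintf("unterminated modification starting at position %d", i))
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      body <- gsub("−", "-", body)   # Unicode minus
      if (!grepl("^[+-][0-9]+(\\.[0-9]+)?$", body))
        stop(sprintf("malformed modification '(%s)' at position %d", body, i))
      if (length(residues) == 0L)
        stop(sprintf("dangling modification at position %d: no preceding residue", i))
      idx <- as.character(length(residues))
      if (idx %in% names(mods))
        stop(sprintf(
          "dangling modification at position %d: residue %s already modified (no new preceding residue)",
          i, idx))
      mods[idx] <- as.numeric(body)
      i <- close + 1L
    } else {
      if (!ch %in% AA_CODES)
        stop(sprintf("unknown residue letter '%s' at position %d", ch, i))
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  new("Peptide", residues = residues, modifications = mods)
}

#' @describeIn parsePeptide bare (modification-stripped) sequence string.
#' @param x a `Peptide`.
#' @export
setMethod("peptideSequence", "Peptide", function(x)
  paste(x@residues, collapse = ""))

#' @describeIn parsePeptide annotated string reproducing the parsed input.
#' @export
setMethod("peptideString", "Peptide", function(x) {
  out <- x@residues
  if (length(x@modifications)) {
    idx <- as.integer(names(x@modifications))
    delta <- x@modifications
    lab <- sprintf("(%s%s)", ifelse(delta >= 0, "+", "-"),
                   format(abs(delta), trim = TRUE, scientific = FALSE))
    out[idx] <- paste0(out[idx], lab)
  }
  paste(out, collapse = "")
})

#' @describeIn parsePeptide number of residues (N).
#' @export
setMethod("nResidues", "Peptide", function(x) length(x@residues))

#' @describeIn parsePeptide named numeric vector of residue mass deltas (Da),
#'   names are 1-based positions.
#' @export
setMethod("modifications", "Peptide", function(x) x@modifications)

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide: %s (N = %d", peptideString(object), nResidues(object)))
  cat(sprintf(", %d modification%s", length(object@modifications),
              if (length(object@modifications) == 1L) "" else "s"))
  cat(")\n")
})

#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da) plus any residue modification deltas. By default, printed
#' nominal deltas that correspond to a canonical modification are replaced
#' by their exact monoisotopic value (+15.99 -> +15.994915, oxidised Met),
#' which is required for computed masses to agree with search-engine
#' precursor masses at the millidalton level.
#'
#' @param x a [Peptide-class].
#' @param canonicalMods replace known nominal deltas by exact values
#'   (default TRUE).
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parsePeptide("CPANGFY"))  # 770.3058
#' @export
setMethod("monoisotopicMass", "Peptide", function(x, canonicalMods = TRUE) {
  m <- sum(RESIDUE_MASS[x@residues]) + WATER_MASS
  if (length(x@modifications)) {
    delta <- x@modifications
    if (canonicalMods) {
      key <- format(abs(delta), trim = TRUE, scientific = FALSE)
      hit <- key %in% names(CANONICAL_MODS)
      delta[hit] <- sign(delta[hit]) * CANONICAL_MODS[key[hit]]
    }
    m <- m + sum(delta)
  }
  unname(m)
})

#' Theoretical mass-to-charge ratio
#'
#' `(M + z * 1.007276) / z` for a protonated precursor of charge `z`.
#'
#' @param x a [Peptide-class].
#' @param z positive integer charge state.
#' @param ... passed to [monoisotopicMass()].
#' @return m/z in Thomson.
#' @export
setMethod("theoreticalMz", "Peptide", function(x, z, ...) {
  if (length(z) != 1L || is.na(z) || z < 1)
    stop("charge z must be a positive integer")
  (monoisotopicMass(x, ...) + z * PROTON_MASS) / z
})

#' Signed precursor mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`, on the m/z scale.
#'
#' @param observedMz observed m/z (Th).
#' @param peptide a [Peptide-class].
#' @param z charge state used for the theoretical m/z.
#' @param ... passed to [theoreticalMz()].
#' @return Signed ppm error.
#' @export
ppmError <- function(observedMz, peptide, z, ...) {
  if (any(observedMz <= 0)) stop("observed m/z must be positive")
  theo <- theoreticalMz(peptide, z, ...)
  (observedMz - theo) / theo * 1e6
}

#' Residue classification configuration
#'
#' Defaults: hydrophobic = \{A, V, L, I, P, F, M, W\}, basic = \{K, R, H\},
#' antioxidant-prone = \{C, M, H, W, Y, K\}. All sets are configurable.
#'
#' @param hydrophobic,basic,antioxidantProne character vectors of one-letter
#'   codes.
#' @return A [ResidueClassConfig-class].
#' @export
residueClassConfig <- function(hydrophobic = c("A", "V", "L", "I", "P", "F", "M", "W"),
                               basic = c("K", "R", "H"),
                               antioxidantProne = c("C", "M", "H", "W", "Y", "K")) {
  new("ResidueClassConfig", hydrophobic = hydrophobic, basic = basic,
      antioxidantProne = antioxidantProne)
}

#' Fraction of hydrophobic residues
#'
#' Count of residues in the configured hydrophobic set divided by N. Used as
#' the water-solubility proxy in candidate selection (peptides above ~85%
#' hydrophobicity are poorly water soluble).
#'
#' @param x a [Peptide-class].
#' @param config a [ResidueClassConfig-class].
#' @return Fraction in \[0, 1\].
#' @export
setMethod("hydrophobicFraction", "Peptide", function(x, config = residueClassConfig()) {
  mean(x@residues %in% config@hydrophobic)
})

#' C-terminal composition rule
#'
#' TRUE when at least one of the last `window` residues (default 3) is
#' hydrophobic or basic. ACE-inhibitory peptides characteristically carry
#' hydrophobic or positively charged residues near the C-terminus.
#'
#' @param x a [Peptide-class].
#' @param config a [ResidueClassConfig-class].
#' @param window number of C-terminal residues inspected (>= 1).
#' @return Logical.
#' @export
setMethod("ctermRule", "Peptide", function(x, config = residueClassConfig(),
                                           window = 3L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(x@residues)
  tail_res <- x@residues[max(1L, n - window + 1L):n]
  any(tail_res %in% c(config@hydrophobic, config@basic))
})

#' Residue composition of a peptide
#'
#' @param x a [Peptide-class].
#' @return Named integer vector of counts (residues present only); counts
#'   sum to N.
#' @export
setMethod("residueCensus", "Peptide", function(x) {
  tab <- table(factor(x@residues, levels = AA_CODES))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
})
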