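# shared helpers: bundled fixture paths, random peptides, brute-force oracles

fixture <- function(name)
  system.file("extdata", name, package = "pepscreen", mustWork = TRUE)

dbReport <- function() readPeaksReport(fixture("voo_peaks_db.tsv"), "db")
denovoReport <- function() readPeaksReport(fixture("voo_denovo.tsv"), "denovo")

randomPeptide <- function(minLen = 4, maxLen = 25) {
  paste(sample(AA_CODES, sample(minLen:maxLen, 1), replace = TRUE),
        collapse = "")
}

# independent motif-scan oracle: enumerate every substring of length 1..10
# and test membership in the library
bruteForceScan <- function(seqstr, lib) {
  recs <- motifRecords(lib)
  hits <- list()
  n <- nchar(seqstr)
  for (start in seq_len(n)) {
    for (len in 1:min(10, n - start + 1)) {
      sub <- substr(seqstr, start, start + len - 1)
      m <- recs[recs$fragment == sub, , drop = FALSE]
      for (j in seq_len(nrow(m)))
        hits[[length(hits) + 1L]] <- data.frame(
          fragment = sub, start = start, activity = m$activity[j],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(fragment = character(0), start = integer(0),
               activity = character(0))
  out[order(out$start, out$fragment, out$activity), , drop = FALSE]
}

# independent cleavage oracle: position-by-position rule evaluation
bruteForceCutSites <- function(seqstr, p1, block) {
  ch <- strsplit(seqstr, "")[[1]]
  sites <- integer(0)
  for (i in seq_len(length(ch) - 1)) {
    if (ch[i] %in% p1 && !ch[i + 1] %in% block) sites <- c(sites, i)
  }
  sites
}
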