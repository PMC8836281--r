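## Ground-truthed synthetic data: identification reports with a truth
## manifest, and assay plates generated from known dose-response parameters.
## Every generator takes an explicit seed; no global random state is used.

#' Default true-peptide panels for report simulation
#'
#' The sequences of the bundled example reports (19 database-search and 8
#' de-novo endogenous olive-oil peptides).
#'
#' @param flavour `"db"` or `"denovo"`.
#' @return Character vector of sequences.
#' @export
defaultTruePeptides <- function(flavour = c("db", "denovo")) {
  flavour <- match.arg(flavour)
  f <- if (flavour == "db") "voo_peaks_db.tsv" else "voo_denovo.tsv"
  rep <- readPeaksReport(system.file("extdata", f, package = "pepscreen",
                                     mustWork = TRUE), flavour = flavour)
  rep$sequence
}

#' Configuration for report simulation
#'
#' Defaults emulate the statistical shape of real endogenous-peptide
#' reports: precursor mass errors of a few ppm (sigma 5 ppm, matching the
#' observed 0.5-9.6 ppm spread under a 10 ppm search tolerance),
#' per-residue local confidences Beta-shaped to give ALC around 90-96, and
#' log-normal label-free areas spanning roughly 1e4-1e7.
#'
#' @param truePeptides sequences to plant (default: the bundled panel for
#'   the flavour).
#' @param flavour `"db"` or `"denovo"`.
#' @param nSamples number of individual samples (default 2).
#' @param ppmSigma SD of the relative mass error, in ppm (default 5).
#' @param alcBeta shape pair of the Beta distribution scaled to \[0, 100\]
#'   for per-residue confidences (default c(28, 2), mean ~93).
#' @param areaLognormal `c(meanlog, sdlog)` of the area distribution
#'   (default c(12.5, 1.5)).
#' @param decoyFraction fraction of report rows that are constructed
#'   decoys, each violating exactly one acceptance rule (default 0.2).
#' @param seed integer seed.
#' @return A list of class `ReportSimConfig`.
#' @export
reportSimConfig <- function(truePeptides = NULL, flavour = c("db", "denovo"),
                            nSamples = 2L, ppmSigma = 5,
                            alcBeta = c(28, 2),
                            areaLognormal = c(12.5, 1.5),
                            decoyFraction = 0.2, seed = 1L) {
  flavour <- match.arg(flavour)
  if (is.null(truePeptides)) truePeptides <- defaultTruePeptides(flavour)
  stopifnot(ppmSigma > 0, all(alcBeta > 0), areaLognormal[2] > 0,
            decoyFraction >= 0, decoyFraction < 1, nSamples >= 1)
  structure(list(truePeptides = truePeptides, flavour = flavour,
                 nSamples = as.integer(nSamples), ppmSigma = ppmSigma,
                 alcBeta = alcBeta, areaLognormal = areaLognormal,
                 decoyFraction = decoyFraction, seed = as.integer(seed)),
            class = "ReportSimConfig")
}

randomSequence <- function(len) paste(sample(AA_CODES, len, replace = TRUE),
                                      collapse = "")

## confidences guaranteeing the target rounded-ALC condition, by rejection
simConfidences <- function(n, shape, above, threshold = 90, maxIter = 1000L) {
  for (i in seq_len(maxIter)) {
    v <- roundHalfUp(100 * rbeta(n, shape[1], shape[2]))
    v <- pmin(v, 99)   # engines cap the local confidence at 99
    ok <- roundHalfUp(mean(v)) >= threshold
    if (ok == above) return(v)
  }
  stop("could not generate a confidence vector meeting the ALC condition")
}

#' Simulate an identification report with known ground truth
#'
#' Each true peptide appears once per sample with an observed mass
#' `theoretical * (1 + eps)`, `eps ~ Normal(0, ppmSigma * 1e-6)`, m/z at a
#' charge of +2 or +3, a passing score (database-search score in 35-95, or
#' per-residue confidences whose rounded ALC is at least 90) and a
#' log-normal area. Decoy rows (constructed, below-threshold
#' identifications) each violate exactly one acceptance rule: a failing
#' score, charge +1, or presence in a single sample only. The truth
#' manifest records which rows must survive [applyFilters()].
#'
#' @param config a [reportSimConfig()].
#' @return List: `records` (report data.frame, flavour attribute set) and
#'   `truth` (data.frame `sequence`, `sample_id`, `decoy`, `decoy_type`,
#'   `must_survive`).
#' @export
simulateReport <- function(config) {
  stopifnot(inherits(config, "ReportSimConfig"))
  withr::with_seed(config$seed, {
    rows <- list()
    truth <- list()
    addRow <- function(seqstr, sample, score_ok, z, decoy_type = NA_character_) {
      p <- parsePeptide(seqstr)
      theo <- monoisotopicMass(p)
      eps <- rnorm(1, 0, config$ppmSigma * 1e-6)
      mass_obs <- theo * (1 + eps)
      rec <- data.frame(
        sequence = seqstr,
        mz = (mass_obs + z * PROTON_MASS) / z,
        mass = mass_obs,
        rt = runif(1, 10, 50),
        ppm = eps * 1e6,
        area = rlnorm(1, config$areaLognormal[1], config$areaLognormal[2]),
        z = z, sample_id = sample,
        stringsAsFactors = FALSE)
      if (config$flavour == "db") {
        rec$neg10lgP <- if (score_ok) runif(1, 35, 95) else runif(1, 10, 25)
      } else {
        lc <- simConfidences(nResidues(p), config$alcBeta, above = score_ok)
        rec$local_confidence <- I(list(lc))
        rec$alc <- computeALC(lc)$alc
      }
      rows[[length(rows) + 1L]] <<- rec
      truth[[length(truth) + 1L]] <<- data.frame(
        sequence = seqstr, sample_id = sample, decoy = !is.na(decoy_type),
        decoy_type = decoy_type, must_survive = is.na(decoy_type),
        stringsAsFactors = FALSE)
    }

    for (s in seq_len(config$nSamples))
      for (seqstr in config$truePeptides)
        addRow(seqstr, paste0("s", s), score_ok = TRUE, z = sample(2:3, 1))

    n_true <- length(rows)
    n_decoy <- round(config$decoyFraction / (1 - config$decoyFraction) * n_true)
    types <- rep_len(c("low_score", "charge1", "single_sample"),
                     max(n_decoy, 0L))
    for (k in seq_len(n_decoy)) {
      repeat {
        ds <- randomSequence(sample(6:15, 1))
        if (!ds %in% config$truePeptides) break
      }
      type <- types[k]
      n_copies <- if (type == "single_sample") 1L else min(2L, config$nSamples)
      for (s in seq_len(n_copies))
        addRow(ds, paste0("s", s),
               score_ok = type != "low_score",
               z = if (type == "charge1") 1L else sample(2:3, 1),
               decoy_type = type)
    }
    records <- do.call(rbind, rows)
    attr(records, "flavour") <- config$flavour
    list(records = records, truth = do.call(rbind, truth))
  })
}

#' Configuration for assay-plate simulation
#'
#' @param trueIc50 true IC50 in uM.
#' @param hill Hill slope (default 1).
#' @param noiseCv coefficient of variation of the multiplicative reading
#'   noise (default 0.02).
#' @param concentrations inhibitor concentrations (uM); default a half-log
#'   series centred on the true IC50 (which is itself a member), plus a
#'   zero well.
#' @param nReplicates wells per concentration within one experiment
#'   (default 3, i.e. triplicate).
#' @param nExperiments independent experiment repeats pooled in the ABTS
#'   simulation (default 3, mirroring assays run three times in triplicate).
#' @param trueTeac true slope-ratio TEAC for the ABTS simulation.
#' @param seed integer seed.
#' @return A list of class `AssaySimConfig`.
#' @export
assaySimConfig <- function(trueIc50, hill = 1, noiseCv = 0.02,
                           concentrations = NULL, nReplicates = 3L,
                           nExperiments = 3L, trueTeac = NA_real_, seed = 1L) {
  stopifnot(trueIc50 > 0, hill > 0, noiseCv >= 0, nReplicates >= 1,
            nExperiments >= 1)
  if (is.null(concentrations))
    concentrations <- c(0, trueIc50 * 10^seq(-1.5, 1.5, by = 0.5))
  structure(list(trueIc50 = trueIc50, hill = hill, noiseCv = noiseCv,
                 concentrations = concentrations,
                 nReplicates = as.integer(nReplicates),
                 nExperiments = as.integer(nExperiments),
                 trueTeac = trueTeac, seed = as.integer(seed)),
            class = "AssaySimConfig")
}

## log-logistic inhibition: 0% at c = 0, 50% at c = IC50
logLogisticInhibition <- function(conc, ic50, hill) {
  ifelse(conc == 0, 0, 100 / (1 + (ic50 / conc)^hill))
}

#' Simulate an ACE-inhibition assay plate
#'
#' Percent inhibition is generated from the log-logistic dose-response
#' `I(c) = 100 / (1 + (IC50/c)^h)` and converted to sample fluorescence
#' readings consistent with the inhibition formula under fixed control
#' (FC = 1000), blank (FB = 100) and sample-blank (FBs = 100) readings;
#' multiplicative Gaussian noise at `noiseCv` is applied to the sample
#' fluorescence.
#'
#' @param config an [assaySimConfig()].
#' @return An [AssayPlate-class].
#' @export
simulatePlate <- function(config) {
  stopifnot(inherits(config, "AssaySimConfig"))
  fc <- 1000; fb <- 100; fbs <- 100
  withr::with_seed(config$seed, {
    conc <- rep(config$concentrations, each = config$nReplicates)
    inh <- logLogisticInhibition(conc, config$trueIc50, config$hill)
    fs <- fbs + (fc - fb) * (1 - inh / 100)
    fs <- fs * (1 + rnorm(length(fs), 0, config$noiseCv))
    assayPlate(fc = fc, fb = fb, concentration = conc, fs = fs, fbs = fbs)
  })
}

#' Simulate an ABTS/TEAC experiment
#'
#' Generates a Trolox calibration (0-1 mM standards) and sample readings
#' whose true response slope is `trueTeac` times the Trolox slope, with
#' multiplicative noise at `noiseCv` on every response. Replication follows
#' the assay protocol: `nExperiments` independent repeats, each reading
#' every concentration in `nReplicates`-fold (triplicate by default);
#' sample concentrations are chosen so responses stay inside the
#' calibration's linear range.
#'
#' @param config an [assaySimConfig()] with `trueTeac` set.
#' @return List: `calibration` and `sample`, each a data.frame with
#'   `concentration` (mM), `response` and `experiment`.
#' @export
simulateAbts <- function(config) {
  stopifnot(inherits(config, "AssaySimConfig"), !is.na(config$trueTeac))
  trolox_slope <- 0.6
  intercept <- 0.02
  nrep <- config$nReplicates * config$nExperiments
  withr::with_seed(config$seed + 1L, {
    cal_conc <- rep(seq(0, 1, by = 0.125), each = nrep)
    cal_resp <- (intercept + trolox_slope * cal_conc) *
      (1 + rnorm(length(cal_conc), 0, config$noiseCv))
    smp_conc <- rep(seq(0.05, 0.3, by = 0.05), each = nrep)
    smp_resp <- (intercept + config$trueTeac * trolox_slope * smp_conc) *
      (1 + rnorm(length(smp_conc), 0, config$noiseCv))
    expt <- function(conc) rep_len(rep(seq_len(config$nExperiments),
                                       each = config$nReplicates),
                                   length(conc))
    list(calibration = data.frame(concentration = cal_conc,
                                  response = cal_resp,
                                  experiment = expt(cal_conc)),
         sample = data.frame(concentration = smp_conc, response = smp_resp,
                             experiment = expt(smp_conc)))
  })
}
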