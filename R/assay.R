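## Wet-assay calculators: ACE-inhibition percent and IC50 from fluorescence
## plates; ABTS antioxidant capacity as TEAC from Trolox calibration curves.

#' ACE-inhibition percentage
#'
#' `((FC - FB) - (FS - FBs)) / (FC - FB) * 100`, where FC is the control
#' fluorescence (enzyme, no inhibitor), FB the substrate blank, FS the
#' sample fluorescence and FBs the sample blank. Noisy data can produce
#' values outside \[0, 100\]; they are returned as-is with attribute
#' `out_of_range` flagging the affected entries.
#'
#' @param fc,fb,fs,fbs fluorescence readings (vectors recycle).
#' @return Percent inhibition.
#' @export
aceInhibition <- function(fc, fb, fs, fbs) {
  if (any(fc <= fb)) stop("invalid assay: control must exceed blank (FC > FB)")
  out <- ((fc - fb) - (fs - fbs)) / (fc - fb) * 100
  flag <- out < 0 | out > 100
  if (any(flag)) attr(out, "out_of_range") <- which(flag)
  out
}

#' Construct an assay plate
#'
#' @param fc control fluorescence reading(s).
#' @param fb blank fluorescence reading(s).
#' @param concentration inhibitor concentrations (uM), one per reading.
#' @param fs sample fluorescence readings.
#' @param fbs sample-blank readings (recycled if scalar).
#' @return An [AssayPlate-class].
#' @export
assayPlate <- function(fc, fb, concentration, fs, fbs) {
  readings <- data.frame(concentration = concentration, fs = fs,
                         fbs = rep_len(fbs, length(fs)))
  new("AssayPlate", fc = fc, fb = fb, readings = readings)
}

#' Per-concentration inhibition curve of a plate
#'
#' Replicate wells (rows sharing a concentration) are averaged; the SEM of
#' the replicate inhibition values is reported alongside.
#'
#' @param plate an [AssayPlate-class].
#' @return data.frame `concentration`, `inhibition`, `sem`, `n`, sorted by
#'   concentration.
#' @export
plateInhibition <- function(plate) {
  fc <- mean(plate@fc)
  fb <- mean(plate@fb)
  inh_all <- aceInhibition(fc, fb, plate@readings$fs, plate@readings$fbs)
  conc <- plate@readings$concentration
  lv <- sort(unique(conc))
  out <- do.call(rbind, lapply(lv, function(cc) {
    v <- inh_all[conc == cc]
    data.frame(concentration = cc, inhibition = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' IC50 from an assay plate
#'
#' Default method: linear interpolation of percent inhibition against
#' log10(concentration) between the pair of adjacent concentrations
#' bracketing 50% — assumption-free and reproducible. `method =
#' "logistic"` instead fits a two-parameter log-logistic curve
#' `I(c) = 100 / (1 + (IC50/c)^h)` by Levenberg-Marquardt least squares.
#'
#' @param plate an [AssayPlate-class].
#' @param method `"interpolation"` or `"logistic"`.
#' @return List: `ic50` (uM), `method`, `curve` (the averaged inhibition
#'   data used).
#' @export
ic50 <- function(plate, method = c("interpolation", "logistic")) {
  method <- match.arg(method)
  curve <- plateInhibition(plate)
  pos <- curve[curve$concentration > 0, , drop = FALSE]
  if (nrow(pos) < 2L)
    stop("IC50 needs at least two positive concentrations")
  est <- if (method == "interpolation") {
    exact <- which(pos$inhibition == 50)
    if (length(exact)) {
      pos$concentration[exact[1]]
    } else {
      above <- pos$inhibition >= 50
      cross <- which(above[-1] != above[-nrow(pos)])
      if (!length(cross))
        stop(sprintf(
          "IC50 not estimable: observed inhibition range [%.1f, %.1f]%% never brackets 50%%",
          min(pos$inhibition), max(pos$inhibition)))
      i <- cross[1]
      x <- log10(pos$concentration[c(i, i + 1L)])
      y <- pos$inhibition[c(i, i + 1L)]
      10^(x[1] + (50 - y[1]) * diff(x) / diff(y))
    }
  } else {
    if (max(pos$inhibition) < 50)
      stop("IC50 not estimable: inhibition never reaches 50%")
    start_ic50 <- pos$concentration[which.min(abs(pos$inhibition - 50))]
    fit <- minpack.lm::nlsLM(
      inhibition ~ 100 / (1 + (i50 / concentration)^h),
      data = pos, start = list(i50 = start_ic50, h = 1),
      lower = c(1e-9, 0.1), upper = c(Inf, 10))
    unname(coef(fit)[["i50"]])
  }
  list(ic50 = est, method = method, curve = curve)
}

#' Fit a Trolox calibration curve
#'
#' Ordinary least-squares line of assay response against Trolox
#' concentration (mM), typically over 0-1 mM.
#'
#' @param concentration Trolox concentrations (mM).
#' @param response assay responses.
#' @return A [TroloxCalibration-class].
#' @export
troloxCalibration <- function(concentration, response) {
  fit <- lm(response ~ concentration)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  new("TroloxCalibration",
      points = data.frame(concentration = concentration, response = response),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

setMethod("show", "TroloxCalibration", function(object) {
  cat(sprintf("TroloxCalibration: %d points, slope %.4g, intercept %.4g, R2 %.4f\n",
              nrow(object@points), object@slope, object@intercept, object@r2))
})

#' Trolox-equivalent antioxidant capacity (TEAC)
#'
#' TEAC is the millimolar Trolox concentration with the same radical
#' scavenging as 1 mM of the compound. Default method: ratio of the
#' compound's least-squares response slope to the Trolox calibration slope.
#' `method = "single_point"` instead converts each sample response to its
#' Trolox equivalent through the calibration line and averages the
#' equivalents per mM of compound.
#'
#' @param calibration a [TroloxCalibration-class].
#' @param concentration compound concentrations (mM).
#' @param response assay responses at those concentrations.
#' @param method `"slope_ratio"` (default) or `"single_point"`.
#' @return TEAC (dimensionless, mM Trolox per mM compound).
#' @export
teac <- function(calibration, concentration, response,
                 method = c("slope_ratio", "single_point")) {
  method <- match.arg(method)
  rng <- range(calibration@points$concentration)
  resp_rng <- range(calibration@points$response)
  if (method == "slope_ratio") {
    if (length(unique(concentration)) < 2L)
      stop("slope-ratio TEAC needs at least two distinct sample concentrations")
    s <- unname(coef(lm(response ~ concentration))[2])
    out <- s / calibration@slope
  } else {
    equiv <- (response - calibration@intercept) / calibration@slope
    out <- mean(equiv / concentration)
  }
  if (any(response < min(resp_rng) - abs(diff(resp_rng)) * 0.05 |
          response > max(resp_rng) + abs(diff(resp_rng)) * 0.05))
    warning("sample responses fall outside the calibration range; ",
            "TEAC involves extrapolation")
  out
}

#' Read a long-format plate CSV
#'
#' Expected columns: `well`, `role` (one of control, blank, sample,
#' sample_blank), `concentration` (blank for control/blank rows), `reading`.
#'
#' @param path CSV path.
#' @return An [AssayPlate-class].
#' @export
readPlateCsv <- function(path) {
  tab <- read.delim(path, sep = ",", strip.white = TRUE)
  need <- c("role", "concentration", "reading")
  if (!all(need %in% names(tab)))
    stop("plate schema error: need columns ", paste(need, collapse = ", "))
  samp <- tab[tab$role == "sample", ]
  sb <- tab[tab$role == "sample_blank", ]
  fbs <- sb$reading[match(samp$concentration, sb$concentration)]
  assayPlate(fc = tab$reading[tab$role == "control"],
             fb = tab$reading[tab$role == "blank"],
             concentration = samp$concentration,
             fs = samp$reading, fbs = fbs)
}

#' Write an assay plate as long-format CSV
#'
#' @param plate an [AssayPlate-class].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writePlateCsv <- function(plate, path) {
  r <- plate@readings
  tab <- rbind(
    data.frame(well = paste0("C", seq_along(plate@fc)), role = "control",
               concentration = NA_real_, reading = plate@fc),
    data.frame(well = paste0("B", seq_along(plate@fb)), role = "blank",
               concentration = NA_real_, reading = plate@fb),
    data.frame(well = paste0("S", seq_len(nrow(r))), role = "sample",
               concentration = r$concentration, reading = r$fs),
    data.frame(well = paste0("SB", seq_len(nrow(r))), role = "sample_blank",
               concentration = r$concentration, reading = r$fbs))
  write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
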