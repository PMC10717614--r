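# Microplate assay arithmetic: standard-curve inverse regression, metabolite
# consumption/secretion deltas, exogenous-lactate correction, DNA
# quantification and alizarin-red-per-DNA normalisation. Unit policy:
# glucose in mg/L (standards are prepared in mg/dL and converted explicitly
# by the caller), lactate and glutamine in mM.

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `reading ~ concentration` for a set of
#' assay standards. The calibrated range is `[min(conc), max(conc)]`; a
#' warning is raised when R-squared falls below 0.99, the usual plate-assay
#' linearity expectation.
#'
#' @param conc Standard concentrations (>= 3 distinct values).
#' @param reading Corresponding instrument readings (absorbance or
#'   fluorescence).
#' @param analyte Analyte label.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `range`, `analyte`, and the underlying `lm` fit.
#' @examples
#' sc <- fit_standard_curve(c(0, 100, 200, 300), 0.01 + 0.002 * c(0, 100, 200, 300))
#' sc$slope  # 0.002
#' @export
fit_standard_curve <- function(conc, reading, analyte = "analyte") {
  if (length(conc) != length(reading)) {
    stop("`conc` and `reading` lengths differ", call. = FALSE)
  }
  if (length(unique(conc)) < 3) {
    stop("at least 3 distinct standard concentrations are required",
         call. = FALSE)
  }
  fit <- stats::lm(reading ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((reading - mean(reading))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (r2 < 0.99) {
    warning(sprintf("standard curve R-squared %.4f below 0.99 for %s",
                    r2, analyte), call. = FALSE)
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, range = range(conc), analyte = analyte, fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve (%s): reading = %.5g + %.5g * conc, R2 = %.4f, range [%g, %g]\n",
    x$analyte, x$intercept, x$slope, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Convert a plate reading to a concentration
#'
#' Inverse regression through a fitted standard curve,
#' `((reading - intercept) / slope) * dilution`. Readings outside the
#' calibrated response range are still inverted but carry an out-of-range
#' flag (attribute `"out_of_range"`) rather than being silently
#' extrapolated.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param reading Instrument reading(s).
#' @param dilution Dilution factor(s) applied to the sample before reading.
#' @return Concentration(s) in the standards' units times the dilution, with
#'   a logical `"out_of_range"` attribute.
#' @export
reading_to_concentration <- function(curve, reading, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) {
    stop("standard curve slope is zero; inverse regression undefined",
         call. = FALSE)
  }
  undiluted <- (reading - curve$intercept) / curve$slope
  calibrated <- curve$intercept + curve$slope * curve$range
  oor <- reading < min(calibrated) | reading > max(calibrated)
  structure(undiluted * dilution, out_of_range = oor)
}

#' Analyse a plate table against its own standards
#'
#' Convenience wrapper: fits the standard curve from the `role == "standard"`
#' rows of a plate table (the layout written by [simulate_assay_plate()])
#' and inverts every `role == "sample"` row with its recorded dilution.
#'
#' @param plate Data frame with columns `role`, `reading`, `dilution`, and
#'   `true_conc` for standard rows.
#' @param analyte Analyte label for the curve.
#' @return The sample rows with a `conc` column appended, plus the fitted
#'   curve as attribute `"curve"`.
#' @export
analyse_plate <- function(plate, analyte = plate$analyte[1]) {
  std <- plate[plate$role == "standard", ]
  smp <- plate[plate$role == "sample", ]
  curve <- fit_standard_curve(std$true_conc, std$reading, analyte = analyte)
  smp$conc <- as.numeric(
    reading_to_concentration(curve, smp$reading, smp$dilution))
  attr(smp, "curve") <- curve
  smp
}

#' Metabolite consumption from initial and final concentrations
#'
#' `delta = initial - final`: positive values are net consumption, negative
#' values net secretion (allowed, and flagged through the `"net_secretion"`
#' attribute). Defaults used in the osteogenesis study: glucose initial
#' 1000 mg/L and glutamine initial 2.0 mM per the medium formulation;
#' lactate is reported directly as secretion without this subtraction.
#'
#' @param initial,final Non-negative concentrations in the same units.
#' @return `initial - final`, with logical attribute `"net_secretion"`.
#' @examples
#' metabolite_delta(2.0, 0.583)  # 1.417 mM glutamine consumed
#' @export
metabolite_delta <- function(initial, final) {
  if (any(initial < 0) || any(final < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  delta <- initial - final
  structure(delta, net_secretion = delta < 0)
}

#' Correct measured lactate for the exogenous supplement
#'
#' In lactate-supplemented medium the measured extracellular lactate includes
#' the amount added exogenously; secreted lactate is the measured total minus
#' the supplement (default 7.5 mM, the sodium-lactate dose). Negative results
#' indicate net lactate uptake and are flagged.
#'
#' @param measured_total Measured lactate concentration (mM, >= 0).
#' @param supplement Exogenous lactate concentration (mM, default 7.5).
#' @return Secreted lactate (mM) with logical attribute `"net_uptake"`.
#' @export
correct_exogenous_lactate <- function(measured_total, supplement = 7.5) {
  if (any(measured_total < 0)) {
    stop("measured lactate must be non-negative", call. = FALSE)
  }
  secreted <- measured_total - supplement
  structure(secreted, net_uptake = secreted < 0)
}

#' Alizarin red staining normalised per DNA
#'
#' Mineral deposition (alizarin red absorbance) divided by the DNA
#' concentration of the same culture, removing cell-number differences
#' between conditions.
#'
#' @param ars_absorbance Alizarin red quantification (absorbance units).
#' @param dna_conc DNA concentration (ng/mL, > 0).
#' @return Normalised mineralization (absorbance per ng/mL DNA).
#' @export
ars_per_dna <- function(ars_absorbance, dna_conc) {
  if (any(dna_conc <= 0)) {
    stop("DNA concentration must be positive", call. = FALSE)
  }
  ars_absorbance / dna_conc
}
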