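# Signal transduction and assay statistics: affine species-to-signal mapping,
# delta-F and F/F0 metrics, log-linear calibration, and the 3*sigma/S limit
# of detection.

#' Map species concentrations to an optical signal
#'
#' Affine transduction: `gain * (per_duplex_g4 * duplex + leak_weight *
#' hairpin) + background`. The CHA product duplex carries a
#' quadruplex-forming tail at both ends, hence the default of 2 signaling
#' quadruplexes per duplex; free hairpins contribute through `leak_weight`
#' (their single sequestered tail is mostly dark, default 0). The same form
#' serves the fluorescence (quadruplex dye) and colorimetric (DNAzyme
#' absorbance) channels with channel-specific gain/background; no enzyme
#' kinetics are modeled.
#'
#' @param duplex_conc,hairpin_conc Concentrations in nM (non-negative).
#' @param gain Signal per nM of signaling quadruplex (>= 0).
#' @param per_duplex_g4 Signaling quadruplexes per product duplex (default 2).
#' @param background Signal offset (blank level).
#' @param leak_weight Quadruplexes per free hairpin (default 0).
#' @return Signal in arbitrary units.
#' @export
signal_from_species <- function(duplex_conc, hairpin_conc = 0, gain = 1,
                                per_duplex_g4 = 2, background = 0,
                                leak_weight = 0) {
  if (!is.numeric(gain) || any(gain < 0)) stop("gain must be >= 0", call. = FALSE)
  if (any(duplex_conc < 0) || any(hairpin_conc < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  gain * (per_duplex_g4 * duplex_conc + leak_weight * hairpin_conc) + background
}

#' Signal change and signal-to-noise metrics
#'
#' `delta_f` is the fluorescence change `F - F0`; `f_over_f0` the
#' signal-to-noise ratio `F / F0` (requires `F0 > 0`).
#'
#' @param F Measured signal.
#' @param F0 Blank signal.
#' @return Numeric.
#' @export
delta_f <- function(F, F0) F - F0

#' @rdname delta_f
#' @export
f_over_f0 <- function(F, F0) {
  if (any(F0 <= 0)) stop("F0 must be > 0 for the ratio", call. = FALSE)
  F / F0
}

#' Assemble a readout table
#'
#' @param concentration_nM Concentrations (0 marks blanks).
#' @param replicate Replicate ids.
#' @param signal Signal values.
#' @param channel `"fluorescence"` or `"absorbance"` (uniform within a fit).
#' @return Tibble of class `readout_table`.
#' @export
readout_table <- function(concentration_nM, replicate, signal,
                          channel = "fluorescence") {
  stopifnot(all(concentration_nM >= 0), length(replicate) == length(concentration_nM),
            length(signal) == length(concentration_nM))
  channel <- match.arg(channel, c("fluorescence", "absorbance"))
  out <- tibble::tibble(concentration_nM = as.numeric(concentration_nM),
                        replicate = replicate,
                        signal = as.numeric(signal),
                        channel = channel)
  class(out) <- c("readout_table", class(out))
  out
}

#' Summary statistics of blank readings
#'
#' @param values Blank signal readings (n >= 2 for a standard deviation).
#' @return List `mean` (F0), `sd` (sigma), `n` of class `blank_stats`.
#' @export
blank_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 blank readings", call. = FALSE)
  structure(list(mean = mean(values), sd = sd(values), n = length(values)),
            class = "blank_stats")
}

#' Fit the log-linear calibration
#'
#' Ordinary least squares of the per-concentration replicate-mean signal on
#' `log10(concentration)` over the positive concentrations in `range`:
#' `Y = a * lg X + b`. Blanks (X = 0) are excluded. With `per_replicate =
#' TRUE` the regression uses individual replicates instead of means.
#'
#' @param readouts A [readout_table()] (or data frame with the same columns).
#' @param range Optional `c(lo, hi)` concentration window in nM (inclusive).
#' @param per_replicate Fit on raw replicates instead of replicate means.
#' @return Object of class `calibration_fit`: `slope` (signal per decade),
#'   `intercept`, `r` (Pearson correlation of lg X with the fitted signals'
#'   observations), `r_squared`, `residual_sd`, `slope_se`, `intercept_se`,
#'   `n_levels`, `range`.
#' @export
fit_log_linear <- function(readouts, range = NULL, per_replicate = FALSE) {
  stopifnot(is.data.frame(readouts),
            all(c("concentration_nM", "signal") %in% names(readouts)))
  d <- readouts[readouts$concentration_nM > 0, , drop = FALSE]
  if (!is.null(range)) {
    d <- d[d$concentration_nM >= range[1] & d$concentration_nM <= range[2], ,
           drop = FALSE]
  }
  if (!nrow(d)) stop("no positive concentrations in range", call. = FALSE)
  if (!per_replicate) {
    agg <- stats::aggregate(signal ~ concentration_nM, data = d, FUN = mean)
    x <- log10(agg$concentration_nM)
    y <- agg$signal
  } else {
    x <- log10(d$concentration_nM)
    y <- d$signal
  }
  if (length(unique(x)) < 2L) {
    stop("need >= 2 distinct positive concentrations to fit", call. = FALSE)
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noise-free tables fit exactly
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = unname(stats::cor(x, y)),
    r_squared = unname(sm$r.squared),
    residual_sd = sm$sigma,
    slope_se = sm$coefficients[2, 2],
    intercept_se = sm$coefficients[1, 2],
    n_levels = length(unique(x)),
    range = range %||% base::range(d$concentration_nM)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Y = %.2f lg[X] + %.2f  (r = %.4f, residual sd = %.3g, %d levels)\n",
              x$slope, x$intercept, x$r, x$residual_sd, x$n_levels))
  invisible(x)
}

#' Predict signal from a calibration fit
#'
#' `Y = a * lg X + b`; defined for X > 0 only.
#'
#' @param fit A [calibration_fit][fit_log_linear()] (or list with `slope`,
#'   `intercept`).
#' @param X Concentration(s), nM, > 0.
#' @return Predicted signal(s).
#' @export
predict_signal <- function(fit, X) {
  if (any(X <= 0)) stop("X must be > 0 (lg X undefined otherwise)", call. = FALSE)
  fit$slope * log10(X) + fit$intercept
}

#' 3-sigma/slope limit of detection
#'
#' The literal rule `LOD = 3 * sigma / |S|` with `sigma` the blank standard
#' deviation and `S` the calibration slope. Because the slope of a
#' log-linear calibration is signal per decade, the literal quotient is in
#' decades of concentration; the calibration-inverted concentration form
#' `10^(lg X at F0 + 3 sigma)` is reported alongside (it needs the blank mean
#' and the intercept).
#'
#' @param blanks A [blank_stats()] (or list with `mean`, `sd`).
#' @param fit A calibration fit with nonzero `slope` (and `intercept` for the
#'   concentration form).
#' @return List: `lod` (the literal 3 sigma / S), `lod_conc_nM` (the inverted
#'   concentration, `NA` if no intercept/mean available), `sigma`, `slope`.
#' @export
lod_3sigma <- function(blanks, fit) {
  sigma <- blanks$sd
  if (is.null(sigma) || is.na(sigma) || sigma < 0) stop("blank sd unavailable", call. = FALSE)
  S <- fit$slope
  if (!is.numeric(S) || S == 0) stop("degenerate fit: slope is zero", call. = FALSE)
  lod <- 3 * sigma / abs(S)
  lod_conc <- NA_real_
  if (!is.null(fit$intercept) && !is.null(blanks$mean)) {
    lod_conc <- 10^((blanks$mean + 3 * sigma - fit$intercept) / S)
  }
  list(lod = lod, lod_conc_nM = lod_conc, sigma = sigma, slope = S)
}
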