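# Seeded generators emulating the assay's readout statistics, so the
# calibration/LOD path is testable without measured data. All generators are
# pure functions of their parameters and seed.

#' Calibration experiment design
#'
#' Defaults reproduce the assay's standard series — thrombin at 0, 0.01,
#' 0.05, 0.1, 0.5, 1, 10, 50 nM with 3 replicates — with signals drawn from
#' the published calibration line `Y = 721.64 lg X + 3432.27` plus
#' homoscedastic Gaussian replicate noise. The replicate noise magnitude is
#' not published; `sigma = 50` signal units is the documented default (a few
#' percent of the dynamic range, consistent with the size of the reported
#' replicate error bars). Blanks (X = 0) are drawn around `blank_mean`, a
#' sub-calibration background level.
#'
#' @param concentrations_nM Concentration series (0 rows are blanks).
#' @param replicates Replicates per level (>= 1).
#' @param slope,intercept Generator line (signal per decade; signal).
#' @param sigma Replicate noise sd (>= 0), signal units.
#' @param blank_mean Mean blank signal.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Object of class `calibration_design`.
#' @export
calibration_design <- function(concentrations_nM = c(0, 0.01, 0.05, 0.1, 0.5, 1, 10, 50),
                               replicates = 3L,
                               slope = 721.64, intercept = 3432.27,
                               sigma = 50, blank_mean = 1800,
                               seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(concentrations_nM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(concentrations_nM = concentrations_nM,
                 replicates = as.integer(replicates),
                 slope = slope, intercept = intercept, sigma = sigma,
                 blank_mean = blank_mean, seed = as.integer(seed)),
            class = "calibration_design")
}

#' Generate synthetic calibration readouts
#'
#' `Y = slope * lg X + intercept + N(0, sigma^2)` for X > 0;
#' `Y = blank_mean + N(0, sigma^2)` for blanks.
#'
#' @param design A [calibration_design()].
#' @return A [readout_table()].
#' @export
generate_calibration_readouts <- function(design = calibration_design()) {
  stopifnot(inherits(design, "calibration_design"))
  conc <- rep(design$concentrations_nM, each = design$replicates)
  repl <- rep(seq_len(design$replicates), times = length(design$concentrations_nM))
  mu <- ifelse(conc > 0, design$slope * log10(pmax(conc, .Machine$double.xmin)) +
                 design$intercept, design$blank_mean)
  y <- withr::with_seed(design$seed, mu + rnorm(length(mu), 0, design$sigma))
  readout_table(conc, repl, y)
}

#' Generate synthetic blank readings
#'
#' `n` Gaussian draws around `mean`; `serum_offset` raises the background
#' (serum matrices show elevated background from potassium-induced
#' quadruplex formation) without changing the spread.
#'
#' @param mean Blank mean signal.
#' @param sigma Blank sd (>= 0).
#' @param n Number of readings (>= 2).
#' @param seed Integer seed.
#' @param serum_offset Additive background shift (default 0).
#' @return Numeric vector of readings (pass to [blank_stats()]).
#' @export
generate_blank_readouts <- function(mean = 1800, sigma = 20, n = 3L, seed = 1L,
                                    serum_offset = 0) {
  if (n < 2) stop("need n >= 2 blank readings", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   mean + serum_offset + rnorm(n, 0, sigma))
}

#' Random hairpin panel
#'
#' Strands of the form `stem + loop + reverse_complement(stem)`, the designed
#' fold of the sensor hairpins, used as a seeded test corpus for the
#' thermodynamics engine. Stems are drawn from G/C and loops from A/C/T: the
#' strand then has exactly `stem_len` Watson-Crick pairs available, all used
#' by the designed contiguous stem, so for `stem_len >= 3` the designed
#' hairpin is a minimum-free-energy structure by construction.
#'
#' @param stem_len Stem length (>= 1).
#' @param loop_len Loop length (>= 3, the minimum hairpin loop).
#' @param count Number of strands.
#' @param seed Integer seed.
#' @return An [oligo_panel] with strands `hp1..hpN`.
#' @export
random_hairpin_panel <- function(stem_len = 4L, loop_len = 4L, count = 5L, seed = 1L) {
  if (stem_len < 1) stop("stem_len must be >= 1", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  strands <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(count), function(i) {
      stem <- paste(sample(c("G", "C"), stem_len, replace = TRUE),
                    collapse = "")
      loop <- paste(sample(c("A", "C", "T"), loop_len, replace = TRUE),
                    collapse = "")
      dna_strand(paste0("hp", i), paste0(stem, loop, rc_chr(stem)))
    })
  })
  oligo_panel(strands)
}
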