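# Dynamic-programming route to the ensemble quantities: partition function Q,
# equilibrium structure probabilities p(s) = exp(-dG(s)/kT)/Q, and MFE.

# Parameter block handed to the compiled engine. scale_g is a per-base
# free-energy rescaling used purely for floating-point range; it cancels
# exactly in the returned log partition functions.
engine_params <- function(model, scale_g = -0.75) {
  list(
    kT = model$kT,
    stack = unname(model$stack),
    hairpin = as.numeric(model$hairpin),
    bulge = as.numeric(model$bulge),
    interior = as.numeric(model$interior),
    js_coef = model$js_coef,
    ml_a = unname(model$multiloop["a"]),
    ml_b = unname(model$multiloop["b"]),
    ml_c = unname(model$multiloop["c"]),
    min_hairpin = as.integer(model$min_hairpin),
    max_twoloop = as.integer(model$max_twoloop),
    scale_g = scale_g
  )
}

.strand_chr <- function(sequence) {
  if (inherits(sequence, "dna_strand")) return(sequence$bases)
  dna_strand("x", sequence)$bases
}

#' Partition function of a single strand
#'
#' `Q = sum(exp(-dG(s)/kT))` over every admissible pseudoknot-free structure
#' of the strand, computed by interval dynamic programming. Depends only on
#' the bases and the model, never on the strand name. `Q >= 1` always (the
#' empty structure contributes `exp(0)`).
#'
#' @param sequence A [dna_strand] or sequence string (single strand; use
#'   [complex_partition_function()] for multi-strand complexes).
#' @param model An [energy_model].
#' @param log Return `log(Q)` instead of `Q` (the log is the numerically safe
#'   form for long, stable sequences).
#' @return `Q` (or `log Q`).
#' @export
partition_function <- function(sequence, model = energy_model(), log = FALSE) {
  bases <- .strand_chr(sequence)
  if (grepl("+", bases, fixed = TRUE)) {
    stop("partition_function is defined on a single strand; use complex_partition_function",
         call. = FALSE)
  }
  codes <- .base_code(strsplit(bases, "", fixed = TRUE)[[1]])
  lq <- .dp_partition_ranges(list(codes), engine_params(model))[1, 1]
  if (log) lq else exp(lq)
}

#' Equilibrium probability of a secondary structure
#'
#' `p(s) = exp(-dG(s)/kT) / Q` over the ensemble of the structure's sequence
#' context. Probabilities over the full enumerated ensemble sum to 1.
#'
#' @param structure A [secondary_structure].
#' @param sequence Optional sequence context; defaults to the structure's own
#'   strands, and must match them when supplied.
#' @param model An [energy_model].
#' @return Probability in (0, 1].
#' @export
structure_probability <- function(structure, sequence = NULL, model = energy_model()) {
  stopifnot(inherits(structure, "secondary_structure"))
  if (!is.null(sequence)) {
    ctx <- if (length(sequence) > 1L) paste(sequence, collapse = "+") else sequence
    ctx_strands <- strsplit(ctx, "+", fixed = TRUE)[[1]]
    ctx_strands <- vapply(ctx_strands, function(s) dna_strand("x", s)$bases,
                          character(1), USE.NAMES = FALSE)
    if (!identical(ctx_strands, structure$strands)) {
      stop("structure is not compatible with the supplied sequence", call. = FALSE)
    }
  }
  codes <- lapply(structure$strands, function(s) {
    .base_code(strsplit(s, "", fixed = TRUE)[[1]])
  })
  ns <- length(codes)
  lq <- .dp_partition_ranges(codes, engine_params(model))[1, ns]
  # structure energies carry the association penalty; fold it into log Q so
  # that the constant cancels in p(s)
  lq <- lq - (ns - 1) * model$assoc_penalty / model$kT
  g <- structure_free_energy(structure, model)
  exp(-g / model$kT - lq)
}

#' Minimum free energy structure of a strand
#'
#' Interval dynamic programming over the same ensemble as
#' [partition_function()]; the reported energy equals the minimum of the
#' enumerated ensemble. Ties are resolved by a deterministic traceback
#' (unpaired before paired, then smallest partner index; hairpin before
#' two-loop before multiloop closures).
#'
#' @inheritParams partition_function
#' @return List with `structure` (a [secondary_structure]), `energy`
#'   (kcal/mol) and `dotbracket`.
#' @export
mfe <- function(sequence, model = energy_model()) {
  bases <- .strand_chr(sequence)
  if (grepl("+", bases, fixed = TRUE)) {
    stop("mfe is defined on a single strand", call. = FALSE)
  }
  codes <- .base_code(strsplit(bases, "", fixed = TRUE)[[1]])
  res <- .dp_mfe_single(codes, engine_params(model))
  st <- secondary_structure(bases, res$pairs)
  list(structure = st, energy = res$energy, dotbracket = format_dotbracket(st))
}
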