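# Exhaustive realization of the structural ensemble for short sequences.
# This is the independent route against which the dynamic-programming
# partition function and MFE are verified; it lists every admissible
# pseudoknot-free structure and scores each via loop decomposition.

.base_code <- function(bases) {
  code <- match(bases, c("A", "C", "G", "T")) - 1L
  if (anyNA(code)) stop("alphabet error", call. = FALSE)
  code
}

.wc_ok <- function(a, b) a + b == 3L  # codes: A=0, C=1, G=2, T=3

#' Enumerate every admissible secondary structure
#'
#' Lists all pseudoknot-free structures over the given strand(s): strict
#' Watson-Crick pairs only, nick-free hairpin loops with at least
#' `model$min_hairpin` unpaired bases, bulge/interior loops within the
#' ensemble cap. The empty structure is always included. Guarded to a total
#' length of 22 nt; longer inputs must use the dynamic-programming route
#' ([partition_function()], [mfe()]).
#'
#' @param sequence Strand string(s); `+` separates strands of an ordered
#'   complex.
#' @param model An [energy_model].
#' @return A list with one element per structure: `structure`
#'   (a [secondary_structure]) and `energy` (kcal/mol, includes the
#'   association penalty for multi-strand input).
#' @export
enumerate_structures <- function(sequence, model = energy_model()) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "+")
  strands <- strsplit(sequence, "+", fixed = TRUE)[[1]]
  strands <- vapply(strands, function(s) dna_strand("x", s)$bases, character(1),
                    USE.NAMES = FALSE)
  n <- sum(nchar(strands))
  if (n > 22L) {
    stop("enumeration is guarded to 22 nt total (got ", n,
         "); use the dynamic-programming route", call. = FALSE)
  }
  code <- .base_code(strsplit(paste(strands, collapse = ""), "", fixed = TRUE)[[1]])
  nicks <- if (length(strands) > 1L) cumsum(nchar(strands))[-length(strands)] else integer(0)
  pair_sets <- .enumerate_pairsets(code, nicks, model$min_hairpin)
  lapply(pair_sets, function(ps) {
    st <- secondary_structure(strands, ps)
    list(structure = st, energy = structure_free_energy(st, model))
  })
}

# All non-crossing Watson-Crick pairings. Local admissibility rule: a pair
# (i, j) is allowed iff j - i - 1 >= min_hairpin or a nick lies inside (i, j)
# (a nick-containing loop is exterior and exempt from the hairpin minimum).
# This local rule is exact: an inner region shorter than min_hairpin with no
# nick cannot host pairs of its own, so (i, j) would close an undersized
# hairpin.
.enumerate_pairsets <- function(code, nicks, min_hairpin) {
  n <- length(code)
  has_nick <- function(i, j) any(nicks >= i & nicks <= j - 1L)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(NULL))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)  # i unpaired
    for (l in (i + 1L):j) {
      if (!.wc_ok(code[i], code[l])) next
      if ((l - i - 1L) < min_hairpin && !has_nick(i, l)) next
      inner <- rec(i + 1L, l - 1L)
      outer <- rec(l + 1L, j)
      for (ps_in in inner) for (ps_out in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, l), ps_in, ps_out)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Partition function of the enumerated ensemble
#'
#' Direct evaluation of `sum(exp(-dG(s)/kT))` over [enumerate_structures()].
#' Used as the oracle for the dynamic-programming [partition_function()].
#'
#' @inheritParams enumerate_structures
#' @param connected_only Keep only structures in which every strand nick is
#'   spanned by at least one base pair (the connected-complex convention used
#'   by tube analysis). No effect on single strands.
#' @return List with `Q`, `logQ`, `n_structures`, and `energies`.
#' @export
enumeration_partition_function <- function(sequence, model = energy_model(),
                                           connected_only = FALSE) {
  ens <- enumerate_structures(sequence, model)
  if (connected_only) {
    keep <- vapply(ens, function(e) .is_connected(e$structure), logical(1))
    ens <- ens[keep]
  }
  energies <- vapply(ens, `[[`, numeric(1), "energy")
  w <- exp(-energies / model$kT)
  list(Q = sum(w), logQ = log(sum(w)), n_structures = length(ens), energies = energies)
}

.is_connected <- function(structure) {
  nicks <- structure$nicks
  if (!length(nicks)) return(TRUE)
  p <- structure$pairs
  all(vapply(nicks, function(d) {
    nrow(p) > 0L && any(p[, 1] <= d & p[, 2] >= d + 1L)
  }, logical(1)))
}
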