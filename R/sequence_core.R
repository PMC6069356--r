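# Strand representation, FASTA I/O, complementarity search and G-tract
# scanning. Coordinates in every user-facing report are 1-based inclusive.

#' Create a DNA strand
#'
#' A named single DNA strand written 5'->3' over the strict alphabet
#' \{A, C, G, T\}. U, IUPAC ambiguity codes and other characters are rejected
#' with an error naming the first offending position.
#'
#' @param name Short identifier (non-empty string).
#' @param bases Sequence 5'->3'; whitespace is stripped (printed tables often
#'   space-group bases), then validated against A/C/G/T.
#' @param note Optional free-text annotation.
#' @return An object of class `dna_strand` with fields `name`, `bases`, `note`.
#' @examples
#' dna_strand("S", "AGT CAC ACG GAC TAT TCC AAC C")
#' @export
dna_strand <- function(name, bases, note = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("strand name must be a non-empty string", call. = FALSE)
  }
  if (!is.character(bases) || length(bases) != 1L) {
    stop("bases must be a single string", call. = FALSE)
  }
  bases <- toupper(gsub("[[:space:]]", "", bases))
  if (!nzchar(bases)) stop("strand '", name, "': bases must be non-empty", call. = FALSE)
  bad <- regexpr("[^ACGT]", bases)
  if (bad > 0L) {
    stop(sprintf("strand '%s': invalid character '%s' at position %d (alphabet is ACGT)",
                 name, substr(bases, bad, bad), bad), call. = FALSE)
  }
  structure(list(name = name, bases = bases, note = note), class = "dna_strand")
}

#' @export
print.dna_strand <- function(x, ...) {
  cat(sprintf(">%s (%d nt)\n%s\n", x$name, nchar(x$bases), x$bases))
  invisible(x)
}

as_dna_strand <- function(x, name = NULL) {
  if (inherits(x, "dna_strand")) return(x)
  dna_strand(name %||% "strand", as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an oligo panel
#'
#' An ordered, name-unique collection of [dna_strand] objects. Panels
#' round-trip losslessly through FASTA via [write_fasta()] / [load_panel()].
#'
#' @param ... `dna_strand` objects (or a single list of them).
#' @return An object of class `oligo_panel` (named list of strands).
#' @export
oligo_panel <- function(...) {
  strands <- list(...)
  if (length(strands) == 1L && is.list(strands[[1]]) && !inherits(strands[[1]], "dna_strand")) {
    strands <- strands[[1]]
  }
  if (length(strands) == 0L) stop("panel must contain at least one strand", call. = FALSE)
  if (!all(vapply(strands, inherits, logical(1), "dna_strand"))) {
    stop("all panel members must be dna_strand objects", call. = FALSE)
  }
  nms <- vapply(strands, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate strand name(s): ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  names(strands) <- nms
  structure(strands, class = "oligo_panel")
}

#' @export
print.oligo_panel <- function(x, ...) {
  cat(sprintf("oligo_panel with %d strand(s)\n", length(x)))
  for (s in x) cat(sprintf("  %-10s %3d nt  %s\n", s$name, nchar(s$bases), s$bases))
  invisible(x)
}

#' @export
`[.oligo_panel` <- function(x, i) {
  oligo_panel(unclass(x)[i])
}

# The four printed oligos of the thrombin sensor (whitespace in the printed
# table is formatting only and is stripped on ingestion).
builtin_oligos <- function() {
  oligo_panel(
    dna_strand("Aptamer", "GGTTGGTGTGGTTGGAATAGTC",
               note = "thrombin-binding aptamer extended with an S-capture tail"),
    dna_strand("S", "AGTCACACGGACTATTCCAACC",
               note = "initiator strand released on target binding"),
    dna_strand("H1", "GGGTAATAGTCCGTGTGACTATGGACTATAGGAGTCACACGGGCGGGTAGGG",
               note = "metastable hairpin; stem sequesters the S-recognition segment"),
    dna_strand("H2", "GGGTTGTATGACTCCTATAGTCCATAGTCACACGGACTATTGGGCGGGTAGGG",
               note = "metastable hairpin; completes the G-quadruplex-tailed duplex")
  )
}

#' Load an oligo panel from FASTA or the built-in sensor panel
#'
#' @param source Path to a FASTA file, or the token `"builtin"` for the
#'   shipped four-strand thrombin-sensor panel (Aptamer, S, H1, H2).
#' @return An [oligo_panel].
#' @examples
#' load_panel("builtin")
#' @export
load_panel <- function(source = "builtin") {
  if (identical(source, "builtin")) return(builtin_oligos())
  if (!file.exists(source)) stop("FASTA file not found: ", source, call. = FALSE)
  set <- Biostrings::readDNAStringSet(source)
  if (length(set) == 0L) stop("FASTA contains no records: ", source, call. = FALSE)
  nms <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nms))) stop("FASTA contains an empty record name", call. = FALSE)
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA header(s): ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) stop("FASTA contains an empty record", call. = FALSE)
  oligo_panel(mapply(dna_strand, nms, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

#' Write an oligo panel to FASTA
#'
#' Standard FASTA, one record per strand, 60-column wrapped.
#'
#' @param panel An [oligo_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "oligo_panel"))
  if (length(panel) == 0L) stop("cannot write an empty panel", call. = FALSE)
  set <- Biostrings::DNAStringSet(vapply(panel, function(s) s$bases, character(1)))
  names(set) <- names(panel)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse complement of a strand
#'
#' Antiparallel Watson-Crick complement, 5'->3'. Applying it twice returns the
#' input (involution).
#'
#' @param strand A [dna_strand] or a bare sequence string.
#' @return A `dna_strand` (name suffixed `_rc` when a strand is supplied);
#'   a bare string in, bare string out.
#' @examples
#' reverse_complement("AGTCACACGGACTATTCCAACC")
#' @export
reverse_complement <- function(strand) {
  if (is.character(strand) && length(strand) == 1L) {
    s <- dna_strand("x", strand)
    return(rc_chr(s$bases))
  }
  stopifnot(inherits(strand, "dna_strand"))
  dna_strand(paste0(strand$name, "_rc"), rc_chr(strand$bases), note = strand$note)
}

rc_chr <- function(bases) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", bases), "", fixed = TRUE)[[1]]), collapse = "")
}

#' Longest contiguous Watson-Crick duplex between two strands
#'
#' Scans every register of `a` (read 5'->3') against `b` (read 3'->5') and
#' returns the longest contiguous perfectly complementary segment. Only strict
#' Watson-Crick pairs (A:T, G:C) count; no wobble. Ties are broken by the
#' smallest `start_a`, then the smallest `start_b`.
#'
#' @param a,b [dna_strand] objects or sequence strings.
#' @return A list with `start_a`, `start_b` (1-based 5' indices of the matched
#'   segments on `a` and `b`) and `length` (bp; 0 when no pair exists, in which
#'   case the starts are `NA`).
#' @examples
#' p <- load_panel("builtin")
#' longest_complementary_duplex(p$Aptamer, p$S)  # the designed 13-bp toehold
#' @export
longest_complementary_duplex <- function(a, b) {
  a <- as_dna_strand(a, "a"); b <- as_dna_strand(b, "b")
  av <- utf8ToInt(a$bases); bv <- utf8ToInt(b$bases)
  # ASCII sum trick: A+T = 149 and C+G = 138 are the only Watson-Crick sums
  n <- length(av); m <- length(bv)
  best <- list(start_a = NA_integer_, start_b = NA_integer_, length = 0L)
  # Antiparallel register: partner index in b decreases as i advances, so
  # contiguous duplexes are runs along anti-diagonals i + partner = c.
  for (c in 2L:(n + m)) {
    i0 <- max(1L, c - m); i1 <- min(n, c - 1L)
    run <- 0L
    for (i in i0:i1) {
      s <- av[i] + bv[c - i]
      run <- if (s == 149L || s == 138L) run + 1L else 0L
      if (run >= best$length && run > 0L) {
        cand <- list(start_a = i - run + 1L, start_b = c - i, length = run)
        if (run > best$length ||
            cand$start_a < best$start_a ||
            (cand$start_a == best$start_a && cand$start_b < best$start_b)) {
          best <- cand
        }
      }
    }
  }
  best
}

#' Find maximal guanine tracts
#'
#' Maximal runs of G of at least `min_len`, reported 5'->3'. Four or more
#' tracts of three or more guanines mark G-quadruplex-forming capability (the
#' motif-level proxy used throughout this package; quadruplexes lie outside
#' the pseudoknot-free thermodynamic ensemble).
#'
#' @param strand A [dna_strand] or sequence string.
#' @param min_len Minimum run length (integer >= 2).
#' @return A tibble with columns `start` (1-based) and `length`; zero rows if
#'   no tract qualifies.
#' @examples
#' find_g_tracts(load_panel("builtin")$H1, 3)
#' @export
find_g_tracts <- function(strand, min_len = 3L) {
  s <- as_dna_strand(strand)
  if (!is.numeric(min_len) || length(min_len) != 1L || min_len < 2) {
    stop("min_len must be a single integer >= 2", call. = FALSE)
  }
  v <- strsplit(s$bases, "", fixed = TRUE)[[1]] == "G"
  r <- rle(v)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = as.integer(ends - r$lengths + 1L)[keep],
                 length = as.integer(r$lengths)[keep])
}

#' Does a strand have G-quadruplex-forming capability?
#'
#' Motif rule: at least `min_tracts` maximal G-runs of length >= `min_len`.
#'
#' @inheritParams find_g_tracts
#' @param min_tracts Required number of tracts (default 4, one per tetrad
#'   column).
#' @return Logical scalar.
#' @export
has_g_quadruplex_motif <- function(strand, min_len = 3L, min_tracts = 4L) {
  nrow(find_g_tracts(strand, min_len)) >= min_tracts
}
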