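# Pseudoknot-free secondary structures over one or more ordered strands,
# dot-bracket parsing/rendering (multi-strand separator '+'), validation and
# loop decomposition.

#' Construct a secondary structure
#'
#' A set of non-crossing base pairs over one or more ordered strands. Indices
#' are global 1-based positions along the concatenation of the strands in
#' order; `nicks` (gaps between consecutive strands) are derived from the
#' strand lengths.
#'
#' @param strands Character vector of strand sequences (5'->3'), or a single
#'   string using `+` as the strand separator.
#' @param pairs Two-column integer matrix of paired positions `(i, j)` with
#'   `i < j` (a 0-row matrix or `NULL` for the empty structure).
#' @return An object of class `secondary_structure` with fields `strands`,
#'   `pairs` (ordered by `i`), `nicks` (gap indices d: a strand break lies
#'   between global positions d and d+1) and `length`.
#' @details Validation rejects out-of-bounds indices, bases in more than one
#'   pair and crossing (pseudoknotted) pairs. The minimum-hairpin-loop rule is
#'   enforced at loop decomposition, where loop identity is known.
#' @export
secondary_structure <- function(strands, pairs = NULL) {
  if (length(strands) == 1L && grepl("+", strands, fixed = TRUE)) {
    strands <- strsplit(strands, "+", fixed = TRUE)[[1]]
  }
  strands <- vapply(strands, function(s) dna_strand("x", s)$bases, character(1),
                    USE.NAMES = FALSE)
  n <- sum(nchar(strands))
  nicks <- if (length(strands) > 1L) cumsum(nchar(strands))[-length(strands)] else integer(0)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs)) {
    if (any(pairs < 1L) || any(pairs > n)) stop("pair index out of bounds", call. = FALSE)
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j", call. = FALSE)
    idx <- as.vector(pairs)
    if (anyDuplicated(idx)) stop("a base may belong to at most one pair", call. = FALSE)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    # non-crossing check via stack scan
    partner <- integer(n)
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- -pairs[, 1]
    open <- integer(0)
    for (k in seq_len(n)) {
      if (partner[k] > 0L) open <- c(open, partner[k])
      else if (partner[k] < 0L) {
        if (!length(open) || open[length(open)] != k) {
          stop("crossing (pseudoknotted) pairs are not representable", call. = FALSE)
        }
        open <- open[-length(open)]
      }
    }
  }
  structure(list(strands = strands, pairs = pairs, nicks = as.integer(nicks),
                 length = as.integer(n)),
            class = "secondary_structure")
}

#' Parse a dot-bracket string
#'
#' @param sequence Strand sequence(s): character vector or `+`-separated string.
#' @param dotbracket Matched `()` string of the same total length, `+`-separated
#'   consistently with `sequence`.
#' @return A [secondary_structure].
#' @export
parse_dotbracket <- function(sequence, dotbracket) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "+")
  seq_parts <- strsplit(sequence, "+", fixed = TRUE)[[1]]
  db_parts <- strsplit(dotbracket, "+", fixed = TRUE)[[1]]
  if (length(seq_parts) != length(db_parts) ||
      !all(nchar(seq_parts) == nchar(db_parts))) {
    stop("dot-bracket does not match the sequence layout", call. = FALSE)
  }
  db <- strsplit(paste(db_parts, collapse = ""), "", fixed = TRUE)[[1]]
  if (!all(db %in% c("(", ")", "."))) stop("dot-bracket may contain only ( ) . +", call. = FALSE)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  pl <- vector("list", sum(db == ")"))
  k <- 0L
  for (p in seq_along(db)) {
    if (db[p] == "(") open <- c(open, p)
    else if (db[p] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket", call. = FALSE)
      k <- k + 1L
      pl[[k]] <- c(open[length(open)], p)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket", call. = FALSE)
  if (k) pairs <- do.call(rbind, pl)
  secondary_structure(seq_parts, pairs)
}

#' Render a structure as a dot-bracket string
#'
#' @param structure A [secondary_structure].
#' @return Dot-bracket string with `+` between strands. Round-trips losslessly
#'   with [parse_dotbracket()].
#' @export
format_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  db <- rep(".", structure$length)
  db[structure$pairs[, 1]] <- "("
  db[structure$pairs[, 2]] <- ")"
  lens <- nchar(structure$strands)
  off <- c(0L, cumsum(lens))
  parts <- vapply(seq_along(lens), function(s) {
    paste(db[(off[s] + 1L):(off[s] + lens[s])], collapse = "")
  }, character(1))
  paste(parts, collapse = "+")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(paste(x$strands, collapse = "+"), "\n", format_dotbracket(x), "\n", sep = "")
  invisible(x)
}

structure_bases <- function(structure) {
  strsplit(paste(structure$strands, collapse = ""), "", fixed = TRUE)[[1]]
}

# nick gaps strictly inside the region spanned by (i, j): gaps d with
# i <= d <= j - 1 (gap d lies between global positions d and d+1)
nicks_between <- function(nicks, i, j) nicks[nicks >= i & nicks <= j - 1L]

#' Decompose a structure into loops
#'
#' Partitions every base into exactly one loop. Each pair is assigned to the
#' loop it closes; unpaired bases belong to their exposed loop; the exterior
#' loop (possibly base-less) is always present. Kinds follow the standard
#' definitions: `stack` (adjacent pairs, no unpaired between), `bulge`
#' (unpaired on exactly one side), `interior` (both sides), `hairpin` (no
#' inner pair), `multiloop` (>= 3 bordering pairs including the closing one),
#' and `exterior`. Any loop whose span contains a strand nick is classified
#' `exterior` (it is an open, zero-energy loop), which is how multi-strand
#' complexes are scored.
#'
#' @param structure A [secondary_structure].
#' @return List of loops; each a list with `kind`, `closing` (the closing pair
#'   `c(i, j)` or `NULL` for the outermost exterior loop), `children` (matrix of
#'   directly nested pairs), `members` (base indices owned by the loop) and
#'   `unpaired` (count of unpaired members).
#' @export
decompose_loops <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  n <- structure$length
  pairs <- structure$pairs
  nicks <- structure$nicks
  # children of each pair (and of the virtual exterior root)
  loops <- list()
  kids_of <- function(lo, hi) {
    # direct (outermost) pairs fully contained in [lo, hi]
    if (!nrow(pairs)) return(matrix(integer(0), ncol = 2L))
    inside <- pairs[, 1] >= lo & pairs[, 2] <= hi
    cand <- pairs[inside, , drop = FALSE]
    if (!nrow(cand)) return(cand)
    top <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      top[k] <- !any(cand[, 1] < cand[k, 1] & cand[, 2] > cand[k, 2])
    }
    cand[top, , drop = FALSE]
  }
  classify <- function(i, j, children, members_unpaired, has_nick) {
    if (has_nick) return("exterior")
    nc <- nrow(children)
    if (nc == 0L) return("hairpin")
    if (nc >= 2L) return("multiloop")
    u5 <- children[1, 1] - i - 1L
    u3 <- j - children[1, 2] - 1L
    if (u5 == 0L && u3 == 0L) return("stack")
    if (u5 == 0L || u3 == 0L) return("bulge")
    "interior"
  }
  walk <- function(lo, hi, closing) {
    children <- kids_of(lo, hi)
    covered <- rep(FALSE, n)
    if (nrow(children)) {
      for (k in seq_len(nrow(children))) covered[children[k, 1]:children[k, 2]] <- TRUE
    }
    span <- if (lo <= hi) lo:hi else integer(0)
    unpaired <- span[!covered[span]]
    # nick exposed in this loop: inside the closing span but not inside a child
    gap_lo <- if (is.null(closing)) 0L else closing[1]
    gap_hi <- if (is.null(closing)) n else closing[2] - 1L
    g <- nicks[nicks >= gap_lo & nicks <= gap_hi]
    exposed <- g
    if (nrow(children) && length(g)) {
      inside_child <- vapply(g, function(d) {
        any(children[, 1] <= d & d <= children[, 2] - 1L)
      }, logical(1))
      exposed <- g[!inside_child]
    }
    has_nick <- length(exposed) > 0L
    if (is.null(closing)) {
      kind <- "exterior"
      members <- unpaired
    } else {
      kind <- classify(closing[1], closing[2], children, length(unpaired), has_nick)
      if (kind == "hairpin" && length(unpaired) < 3L) {
        stop(sprintf("hairpin loop closed by (%d,%d) has %d unpaired bases (minimum 3)",
                     closing[1], closing[2], length(unpaired)), call. = FALSE)
      }
      members <- unname(c(closing, unpaired))
    }
    loops[[length(loops) + 1L]] <<- list(
      kind = kind, closing = unname(closing), children = children,
      members = sort(members), unpaired = length(unpaired)
    )
    if (nrow(children)) {
      for (k in seq_len(nrow(children))) {
        walk(children[k, 1] + 1L, children[k, 2] - 1L, children[k, , drop = TRUE])
      }
    }
  }
  walk(1L, n, NULL)
  loops
}
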