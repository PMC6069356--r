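# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# O(n*m*L) duplex search: every start pair, every length, antiparallel
# Watson-Crick check base by base.
oracle_duplex <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(start_a = NA_integer_, start_b = NA_integer_, length = 0L)
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    maxL <- min(length(av) - i + 1L, length(bv) - j + 1L)
    for (L in seq_len(maxL)) {
      ok <- all(vapply(0:(L - 1L), function(t) {
        comp[[av[i + t]]] == bv[j + L - 1L - t]
      }, logical(1)))
      if (ok && L > best$length) best <- list(start_a = i, start_b = j, length = L)
    }
  }
  best
}

# Count admissible pseudoknot-free structures by a simple interval recursion
# (no structure listing, no energies) - the independent counter for the
# enumeration route.
oracle_structure_count <- function(seq, min_hairpin = 3L) {
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(code)
  memo <- array(NA_real_, dim = c(n + 1L, n + 1L))
  rec <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    tot <- rec(i + 1L, j)
    for (l in (i + 1L):j) {
      if (code[i] + code[l] != 3L) next
      if (l - i - 1L < min_hairpin) next
      tot <- tot + rec(i + 1L, l - 1L) * rec(l + 1L, j)
    }
    memo[i, j] <<- tot
    tot
  }
  rec(1L, n)
}

# Closed-form dimer equilibrium A + B <=> AB with K = Q_AB / (Q_A Q_B) (1 M
# reference): free-A satisfies a quadratic in xAB.
oracle_dimer <- function(a0, b0, K) {
  s <- a0 + b0 + 1 / K
  # stable smaller root: 2ab / (s + sqrt(s^2 - 4ab))
  xab <- 2 * a0 * b0 / (s + sqrt(s^2 - 4 * a0 * b0))
  c(A = a0 - xab, B = b0 - xab, AB = xab)
}

# The assay's standard concentration series and published calibration line
# (the synthetic-data defaults).
assay_series_nM <- c(0, 0.01, 0.05, 0.1, 0.5, 1, 10, 50)
assay_slope <- 721.64
assay_intercept <- 3432.27
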