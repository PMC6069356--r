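# Test-tube analysis: enumerate the complexes a strand set can form up to a
# maximum size, compute each complex's (connected) partition function, and
# solve the convex equilibrium-concentration program under mass conservation.

#' Enumerate complexes up to a maximum size
#'
#' All rotation-distinct ordered multisets (necklaces) of the given strand
#' names up to size `max_size`; circular rotations of a strand ordering
#' describe the same complex. Monomers are always included. Output order is
#' deterministic: by size, then lexicographically by the canonical (minimal)
#' rotation.
#'
#' @param strand_names Character vector of distinct strand names.
#' @param max_size Largest complex size L (>= 1).
#' @return Tibble with `complex` (dot-joined name), `strands` (list column of
#'   ordered names), `size`, and `symmetry` (rotational symmetry order of the
#'   ordering, used for the indistinguishability correction of Q).
#' @examples
#' enumerate_complexes(c("S", "H1", "H2"), 2)  # 3 monomers + 6 dimers
#' @export
enumerate_complexes <- function(strand_names, max_size = 4L) {
  if (!is.numeric(max_size) || max_size < 1) stop("max_size must be >= 1", call. = FALSE)
  stopifnot(is.character(strand_names), length(strand_names) >= 1L,
            !anyDuplicated(strand_names))
  canon <- function(v) {
    rots <- vapply(seq_along(v), function(r) {
      paste(v[c(r:length(v), seq_len(r - 1L))[seq_along(v)]], collapse = "\r")
    }, character(1))
    min(rots)
  }
  out <- list()
  for (size in seq_len(max_size)) {
    grid <- do.call(expand.grid, c(rep(list(strand_names), size),
                                   stringsAsFactors = FALSE))
    keys <- apply(as.matrix(grid), 1L, function(v) canon(v))
    keep <- !duplicated(keys)
    ord <- order(keys[keep])
    rows <- which(keep)[ord]
    for (r in rows) {
      v <- strsplit(keys[r], "\r", fixed = TRUE)[[1]]
      sym <- sum(vapply(seq_along(v), function(s) {
        identical(v[c(s:length(v), seq_len(s - 1L))[seq_along(v)]], v)
      }, logical(1)))
      out[[length(out) + 1L]] <- list(complex = paste(v, collapse = "."),
                                      strands = v, size = size, symmetry = sym)
    }
  }
  tibble::tibble(
    complex = vapply(out, `[[`, character(1), "complex"),
    strands = lapply(out, `[[`, "strands"),
    size = vapply(out, `[[`, integer(1), "size"),
    symmetry = vapply(out, function(x) as.integer(x$symmetry), integer(1))
  )
}

#' Partition function of an ordered multi-strand complex
#'
#' Boltzmann sum over connected, pseudoknot-free structures of the given
#' strand ordering: every strand nick must be spanned by at least one base
#' pair (a structure that falls apart at a nick belongs to smaller complexes).
#' Loops containing a nick are exterior (zero energy). The result carries the
#' association penalty per strand beyond the first and is divided by the
#' rotational symmetry order of the ordering (indistinguishability
#' correction). A single strand reduces exactly to [partition_function()].
#'
#' @param strands Ordered character vector of strand names (a row of
#'   [enumerate_complexes()]) or of bare sequences.
#' @param panel An [oligo_panel] resolving names to sequences (ignored if
#'   `strands` are bare sequences).
#' @param model An [energy_model].
#' @param log Return `log(Q)`; `-Inf` marks a complex with no connected
#'   structure (e.g. two strands with no cross pairs).
#' @return `Q_j` (or its log).
#' @export
complex_partition_function <- function(strands, panel = NULL, model = energy_model(),
                                       log = FALSE) {
  seqs <- resolve_strands(strands, panel)
  ns <- length(seqs)
  codes <- lapply(seqs, function(s) .base_code(strsplit(s, "", fixed = TRUE)[[1]]))
  M <- .dp_partition_ranges(codes, engine_params(model))
  # connected Q by first-unspanned-nick subtraction, in log space:
  # Q_all(1..q) = sum_k Q_conn(1..k) * Q_all(k+1..q)
  logQc <- numeric(ns)
  for (q in seq_len(ns)) {
    terms <- if (q > 1L) {
      vapply(seq_len(q - 1L), function(k) logQc[k] + M[k + 1L, q], numeric(1))
    } else numeric(0)
    logQc[q] <- logspace_sub(M[1L, q], logspace_sum(terms))
  }
  sym <- rotational_symmetry(strands)
  lq <- logQc[ns] - (ns - 1) * model$assoc_penalty / model$kT - base::log(sym)
  if (log) lq else exp(lq)
}

resolve_strands <- function(strands, panel) {
  if (inherits(strands, "oligo_panel")) {
    return(vapply(strands, function(s) s$bases, character(1)))
  }
  stopifnot(is.character(strands), length(strands) >= 1L)
  if (!is.null(panel)) {
    missing <- setdiff(strands, names(panel))
    if (length(missing) && all(grepl("^[ACGTacgt]+$", strands))) {
      # bare sequences
      return(vapply(strands, function(s) dna_strand("x", s)$bases, character(1),
                    USE.NAMES = FALSE))
    }
    if (length(missing)) stop("strand(s) not in panel: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    return(vapply(strands, function(nm) panel[[nm]]$bases, character(1),
                  USE.NAMES = FALSE))
  }
  if (!all(grepl("^[ACGTacgt]+$", strands))) {
    stop("supply a panel to resolve strand names", call. = FALSE)
  }
  vapply(strands, function(s) dna_strand("x", s)$bases, character(1), USE.NAMES = FALSE)
}

rotational_symmetry <- function(v) {
  v <- as.character(v)
  sum(vapply(seq_along(v), function(s) {
    identical(v[c(s:length(v), seq_len(s - 1L))[seq_along(v)]], v)
  }, logical(1)))
}

# log(sum(exp(x))) and log(exp(a) - exp(b)), stable
logspace_sum <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (!length(x)) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + base::log(sum(exp(x - mx)))
}

logspace_sub <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) {
    # numerically, the connected part vanished
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

#' Specify a test tube
#'
#' @param totals_nM Named numeric vector: total strand concentrations in nM.
#' @param max_size Largest complex size L considered (default 4; tetramer
#'   by-products are the largest species the CHA analysis tracks).
#' @param temperature Kelvin.
#' @return Object of class `tube_spec`.
#' @export
tube <- function(totals_nM, max_size = 4L, temperature = 310.15) {
  stopifnot(is.numeric(totals_nM), !is.null(names(totals_nM)),
            all(nzchar(names(totals_nM))), all(totals_nM >= 0), max_size >= 1)
  structure(list(totals_nM = totals_nM, max_size = as.integer(max_size),
                 temperature = temperature), class = "tube_spec")
}

#' Solve equilibrium concentrations for a tube
#'
#' Minimizes `sum_j x_j (log x_j - log Q_j - 1)` subject to mass conservation
#' `A x = x0`, `x >= 0` (concentrations in molar, 1 M standard state). Solved
#' by damped Newton iterations on the dual variables (one chemical potential
#' per strand), so every iterate satisfies the law of mass action
#' `log x_j = log Q_j + sum_i A_ij lambda_i` exactly; convergence is declared
#' on the mass-balance residual.
#'
#' @param tube A [tube()] specification.
#' @param complexes Tibble from [enumerate_complexes()] with an added `logQ`
#'   column (see [analyze_tube()] for the one-call route).
#' @param tol Relative mass-balance residual required (default 1e-10).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `equilibrium_state`: tibble `species` (complex,
#'   size, logQ, x_M, x_nM), strand potentials `lambda`, and diagnostics
#'   (`iterations`, `converged`, `residual`, `kkt`, `objective`,
#'   `objective_trace`).
#' @export
solve_equilibrium <- function(tube, complexes, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(tube, "tube_spec"), is.data.frame(complexes),
            all(c("complex", "strands", "logQ") %in% names(complexes)))
  strands <- names(tube$totals_nM)
  x0 <- tube$totals_nM * 1e-9  # molar
  active_strands <- strands[x0 > 0]
  if (!length(active_strands)) stop("all strand totals are zero", call. = FALSE)
  # drop complexes with zero Q or containing an absent strand
  keep <- vapply(seq_len(nrow(complexes)), function(r) {
    v <- complexes$strands[[r]]
    is.finite(complexes$logQ[r]) && all(v %in% active_strands)
  }, logical(1))
  cx <- complexes[keep, , drop = FALSE]
  if (!nrow(cx)) stop("no complexes with positive Q", call. = FALSE)
  A <- vapply(cx$strands, function(v) {
    vapply(active_strands, function(s) sum(v == s), numeric(1))
  }, numeric(length(active_strands)))
  A <- matrix(A, nrow = length(active_strands),
              dimnames = list(active_strands, cx$complex))
  mono <- match(active_strands, cx$complex)
  if (anyNA(mono)) stop("every strand needs its monomer complex", call. = FALSE)
  logQ <- cx$logQ
  x0a <- x0[active_strands]
  if (any(!is.finite(logQ[mono]))) stop("monomer partition functions must be positive",
                                        call. = FALSE)

  lambda <- log(x0a) - logQ[mono]
  logx <- function(lam) logQ + drop(crossprod(A, lam))
  # keep the largest complex below the total mass scale at the start
  cap <- log(sum(x0a))
  for (it in 1:200) {
    if (max(logx(lambda)) <= cap + 1) break
    lambda <- lambda - 1
  }
  dual_obj <- function(lam) {
    lx <- logx(lam)
    if (max(lx) > 500) return(Inf)
    sum(exp(lx)) - sum(lam * x0a)
  }
  obj_trace <- numeric(0)
  residual <- Inf
  converged <- FALSE
  iter <- 0L
  g_cur <- dual_obj(lambda)
  while (iter < max_iter) {
    iter <- iter + 1L
    x <- exp(logx(lambda))
    grad <- drop(A %*% x) - x0a
    residual <- max(abs(grad) / x0a)
    obj_trace <- c(obj_trace, g_cur)
    if (residual <= tol) { converged <- TRUE; break }
    H <- A %*% (x * t(A))
    # Jacobi-preconditioned Newton direction (H is SPD; x spans many decades)
    d <- 1 / sqrt(diag(H))
    Hn <- t(t(H * d) * d)
    step <- d * tryCatch(solve(Hn, -(d * grad)), error = function(e) -(d * grad))
    slope <- sum(grad * step)  # < 0: Newton direction is a descent direction
    if (!is.finite(slope) || slope >= 0) step <- -grad / diag(H)
    slope <- sum(grad * step)
    t_ls <- 1
    # Armijo decrease, relaxed to ulp resolution of the objective: near the
    # optimum the true decrease per Newton step falls below eps * |g|
    slack <- 8 * .Machine$double.eps * abs(g_cur)
    repeat {
      g_new <- dual_obj(lambda + t_ls * step)
      if (g_new <= g_cur + max(1e-4 * t_ls * slope, slack) || t_ls < 1e-14) break
      t_ls <- t_ls / 2
    }
    if (t_ls < 1e-14) break  # no further numerical progress
    lambda <- lambda + t_ls * step
    g_cur <- g_new
  }
  if (!converged && residual > 1e-6) {
    stop(sprintf("equilibrium solver did not converge: residual %.3e after %d iterations",
                 residual, iter), call. = FALSE)
  }
  x <- exp(logx(lambda))
  kkt <- max(abs(log(x) - logQ - drop(crossprod(A, lambda))))
  primal <- sum(x * (log(x) - logQ - 1))
  species <- tibble::tibble(
    complex = cx$complex,
    strands = cx$strands,
    size = cx$size,
    symmetry = cx$symmetry,
    logQ = logQ,
    x_M = unname(x),
    x_nM = unname(x) * 1e9
  )
  structure(list(
    species = species,
    lambda = setNames(lambda, active_strands),
    diagnostics = list(iterations = iter, converged = converged,
                       residual = residual, kkt = kkt,
                       objective = primal, objective_trace = obj_trace)
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("equilibrium_state: %d complexes, %d iterations, residual %.2e, kkt %.2e\n",
              nrow(x$species), d$iterations, d$residual, d$kkt))
  top <- x$species[order(-x$species$x_nM), c("complex", "size", "x_nM")]
  print(utils::head(as.data.frame(top), 10))
  invisible(x)
}

#' One-call tube analysis
#'
#' Enumerates complexes up to the tube's `max_size`, computes every complex
#' partition function from the panel sequences, and solves the equilibrium.
#'
#' @param panel An [oligo_panel].
#' @param tube A [tube()] whose strand names exist in the panel.
#' @param model An [energy_model] (its temperature is taken from the tube).
#' @return An `equilibrium_state` (see [solve_equilibrium()]); the `species`
#'   tibble carries the complex `logQ` values.
#' @export
analyze_tube <- function(panel, tube, model = NULL) {
  stopifnot(inherits(panel, "oligo_panel"), inherits(tube, "tube_spec"))
  if (is.null(model)) model <- energy_model(temperature = tube$temperature)
  strands <- names(tube$totals_nM)
  missing <- setdiff(strands, names(panel))
  if (length(missing)) stop("strand(s) not in panel: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  cx <- enumerate_complexes(strands, tube$max_size)
  cx$logQ <- vapply(cx$strands, function(v) {
    complex_partition_function(v, panel, model, log = TRUE)
  }, numeric(1))
  solve_equilibrium(tube, cx)
}
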