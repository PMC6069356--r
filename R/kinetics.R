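# Domain-level mass-action model of the target-triggered CHA circuit.
# The target protein is modeled as a single strand fully complementary to the
# aptamer (the same abstraction the strand-displacement simulation of the
# circuit uses); protein-aptamer binding biophysics is out of scope.
#
# Species: Thrombin, AptamerS (aptamer:S probe duplex), AptamerThrombin, S,
# H1, H2, S_H1 (opened-hairpin intermediate), DuplexH1H2 (the CHA product).
# Reactions:
#   R1  Thrombin + AptamerS -> AptamerThrombin + S      (k_trigger)
#   R2f S + H1 -> S_H1                                  (k_open)
#   R2r S_H1 -> S + H1                                  (k_open_rev)
#   R3  S_H1 + H2 -> DuplexH1H2 + S                     (k_cat, catalytic turnover)
#   R4  H1 + H2 -> DuplexH1H2                           (k_leak, target-independent)

CHA_SPECIES <- c("Thrombin", "AptamerS", "AptamerThrombin", "S",
                 "H1", "H2", "S_H1", "DuplexH1H2")

#' Rate configuration for the CHA network
#'
#' Bimolecular rates in /nM/s, unimolecular in /s. Defaults place the circuit
#' in the designed regime: fast toehold-mediated displacement for the
#' triggered path (1e-3 /nM/s, i.e. ~1e6 /M/s, typical of a long toehold) and
#' a slow hairpin-hairpin leak. They are a configuration surface, not a
#' correctness surface.
#'
#' @param k_trigger Target strand displaces S from the aptamer:S probe.
#' @param k_open S opens H1 (forward), `k_open_rev` the reverse (/s).
#' @param k_cat S:H1 recruits H2, releasing S.
#' @param k_leak Direct H1 + H2 leak.
#' @return Object of class `rate_config`.
#' @export
rate_config <- function(k_trigger = 1e-3, k_open = 1e-3, k_open_rev = 1e-3,
                        k_cat = 1e-3, k_leak = 1e-8) {
  r <- c(k_trigger = k_trigger, k_open = k_open, k_open_rev = k_open_rev,
         k_cat = k_cat, k_leak = k_leak)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0", call. = FALSE)
  structure(as.list(r), class = "rate_config")
}

#' Build the CHA reaction network
#'
#' @param rates A [rate_config()].
#' @return Object of class `reaction_network`: `species`, `reactions` (tibble
#'   with rate names and constants), stoichiometry matrix `S` (species x
#'   reactions) and the four structural conservation vectors (thrombin,
#'   S-strand, H1 and H2 moieties).
#' @export
build_network <- function(rates = rate_config()) {
  if (!inherits(rates, "rate_config")) rates <- do.call(rate_config, as.list(rates))
  rx <- tibble::tibble(
    id = c("R1", "R2f", "R2r", "R3", "R4"),
    rate = c("k_trigger", "k_open", "k_open_rev", "k_cat", "k_leak"),
    k = unlist(rates[c("k_trigger", "k_open", "k_open_rev", "k_cat", "k_leak")],
               use.names = FALSE),
    reactants = list(c("Thrombin", "AptamerS"), c("S", "H1"), "S_H1",
                     c("S_H1", "H2"), c("H1", "H2")),
    products = list(c("AptamerThrombin", "S"), "S_H1", c("S", "H1"),
                    c("DuplexH1H2", "S"), "DuplexH1H2")
  )
  S <- matrix(0, nrow = length(CHA_SPECIES), ncol = nrow(rx),
              dimnames = list(CHA_SPECIES, rx$id))
  for (r in seq_len(nrow(rx))) {
    for (sp in rx$reactants[[r]]) S[sp, r] <- S[sp, r] - 1
    for (sp in rx$products[[r]]) S[sp, r] <- S[sp, r] + 1
  }
  conservation <- rbind(
    thrombin = c(Thrombin = 1, AptamerS = 0, AptamerThrombin = 1, S = 0,
                 H1 = 0, H2 = 0, S_H1 = 0, DuplexH1H2 = 0),
    s_strand = c(Thrombin = 0, AptamerS = 1, AptamerThrombin = 0, S = 1,
                 H1 = 0, H2 = 0, S_H1 = 1, DuplexH1H2 = 0),
    h1 = c(Thrombin = 0, AptamerS = 0, AptamerThrombin = 0, S = 0,
           H1 = 1, H2 = 0, S_H1 = 1, DuplexH1H2 = 1),
    h2 = c(Thrombin = 0, AptamerS = 0, AptamerThrombin = 0, S = 0,
           H1 = 0, H2 = 1, S_H1 = 0, DuplexH1H2 = 1)
  )
  structure(list(species = CHA_SPECIES, reactions = rx, S = S,
                 conservation = conservation, rates = rates),
            class = "reaction_network")
}

#' Default initial concentrations of the assay (nM)
#'
#' 1 nM target, 50 nM aptamer:S probe, 300 nM of each hairpin — the standard
#' assay condition.
#'
#' @param thrombin_nM Target concentration (default 1).
#' @return Named vector over the network species.
#' @export
cha_initial_state <- function(thrombin_nM = 1) {
  setNames(c(thrombin_nM, 50, 0, 0, 300, 300, 0, 0), CHA_SPECIES)
}

#' Integrate the CHA network
#'
#' Deterministic stiff-capable integration (`deSolve::ode`, lsoda) of the
#' mass-action rate equations in nM and seconds.
#'
#' @param network A [build_network()] result.
#' @param init Named initial concentrations (nM) covering the species;
#'   missing names default to 0.
#' @param t_end End time (s).
#' @param n_out Number of output time points (including t = 0).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `cha_timecourse`: tibble `trajectory` (time plus
#'   one column per species, nM) and `terminal` (named vector at `t_end`).
#' @export
simulate_cha <- function(network, init = cha_initial_state(), t_end = 7200,
                         n_out = 721L, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  y0 <- setNames(numeric(length(CHA_SPECIES)), CHA_SPECIES)
  if (length(init)) {
    bad <- setdiff(names(init), CHA_SPECIES)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    y0[names(init)] <- init
  }
  if (any(y0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  k <- unlist(network$rates, use.names = TRUE)
  Smat <- network$S
  deriv <- function(t, y, parms) {
    v <- c(
      k[["k_trigger"]] * y[["Thrombin"]] * y[["AptamerS"]],
      k[["k_open"]] * y[["S"]] * y[["H1"]],
      k[["k_open_rev"]] * y[["S_H1"]],
      k[["k_cat"]] * y[["S_H1"]] * y[["H2"]],
      k[["k_leak"]] * y[["H1"]] * y[["H2"]]
    )
    list(drop(Smat %*% v))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integrator failed; last accepted time ", max(sol[, "time"]), call. = FALSE)
  }
  tr <- tibble::as_tibble(as.data.frame(sol))
  structure(list(trajectory = tr,
                 terminal = setNames(as.numeric(tr[nrow(tr), CHA_SPECIES]), CHA_SPECIES),
                 network = network),
            class = "cha_timecourse")
}

#' @export
print.cha_timecourse <- function(x, ...) {
  cat(sprintf("cha_timecourse: %d time points to t = %g s\n",
              nrow(x$trajectory), max(x$trajectory$time)))
  print(round(x$terminal, 4))
  invisible(x)
}

#' With/without-target amplification ratio
#'
#' Runs the circuit twice — once with the given target concentration, once
#' with none — and reports `DuplexH1H2(t_end)` with target divided by the
#' leak-only value. With zero leak the denominator is exactly zero and the
#' ratio is reported as infinite (flagged), not an error.
#'
#' @param rates A [rate_config()].
#' @param init Initial state with the target present (nM).
#' @param t_end Evaluation time (s).
#' @param ... Passed to [simulate_cha()].
#' @return List: `ratio`, `duplex_with`, `duplex_without`, `infinite` flag.
#' @export
amplification_ratio <- function(rates = rate_config(), init = cha_initial_state(),
                                t_end = 7200, ...) {
  stopifnot(t_end > 0)
  net <- build_network(rates)
  init0 <- init
  init0[["Thrombin"]] <- 0
  with_t <- simulate_cha(net, init, t_end, ...)$terminal[["DuplexH1H2"]]
  without <- simulate_cha(net, init0, t_end, ...)$terminal[["DuplexH1H2"]]
  if (without <= 0) {
    return(list(ratio = Inf, duplex_with = with_t, duplex_without = without,
                infinite = TRUE))
  }
  list(ratio = with_t / without, duplex_with = with_t, duplex_without = without,
       infinite = FALSE)
}
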