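#' Continuous-time Markov rate model
#'
#' A `rate_model` holds the generator of a finite-state continuous-time Markov
#' chain: a set of state labels and a matrix of transition rates (s^-1).
#' Transitions whose rate scales with the free RecA concentration are flagged,
#' so that a concentration-independent rate constant (e.g. `k_on` in
#' uM^-1 s^-1) can be recovered from the effective rates.
#'
#' @param states character vector of state labels.
#' @param rates numeric K x K matrix of effective transition rates in s^-1
#'   (already multiplied by concentration where applicable). Diagonal must be
#'   zero; all entries finite and non-negative.
#' @param conc_scaled logical K x K matrix flagging which transitions scale
#'   with `[RecA]`. Default: none.
#' @param concentration RecA concentration in uM baked into the scaled rates
#'   (NA if none are scaled).
#'
#' @return An object of class `rate_model` with elements `states`, `rates`,
#'   `conc_scaled`, `concentration`.
#' @seealso [build_nucleation_model()], [build_end_dynamics_model()]
#' @export
rate_model <- function(states, rates, conc_scaled = NULL, concentration = NA_real_) {
  states <- as.character(states)
  K <- length(states)
  stopifnot(K >= 1, !anyDuplicated(states))
  rates <- as.matrix(rates)
  if (!all(dim(rates) == K)) stop("rates must be a ", K, " x ", K, " matrix")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (any(diag(rates) != 0)) stop("diagonal rates must be zero")
  if (is.null(conc_scaled)) conc_scaled <- matrix(FALSE, K, K)
  dimnames(rates) <- dimnames(conc_scaled) <- list(states, states)
  structure(
    list(states = states, rates = rates, conc_scaled = conc_scaled,
         concentration = concentration),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  if (is.finite(x$concentration))
    cat("  [RecA] =", x$concentration, "uM (binding rates concentration-scaled)\n")
  print(round(x$rates, 4))
  invisible(x)
}

#' Two-state filament nucleation model
#'
#' Nucleation of a RecA cluster (~6 monomers) on a short ssDNA tail is resolved
#' as a single kinetic step at 0.1 s frame times, so the cluster binds and
#' unbinds atomically: a two-state chain `unbound <-> nucleated`.
#'
#' @param k_nuc per-molecule nucleation rate in s^-1 at the experiment's fixed
#'   RecA concentration (the concentration law is left to the caller).
#' @param k_disassembly disassembly rate of the nucleated cluster in s^-1.
#' @return A [rate_model()] with states `unbound`, `nucleated`.
#' @export
build_nucleation_model <- function(k_nuc, k_disassembly) {
  stopifnot(k_nuc >= 0, k_disassembly >= 0)
  rates <- matrix(c(0, k_nuc, k_disassembly, 0), 2, 2, byrow = TRUE)
  rate_model(c("unbound", "nucleated"), rates)
}

#' Three-state 5'-end monomer occupancy model
#'
#' Monomer binding and dissociation at the 5' disassembly end of a RecA
#' filament, observed through a 10-nt two-dye probe window that accommodates at
#' most two monomers: a linear birth-death chain `M0 <-> M1 <-> M2` (zero, one,
#' two monomers bound). Each binding step has effective rate
#' `k_on * [RecA]`; each dissociation step has rate `k_off`. There is no
#' direct `M0 <-> M2` transition (single-monomer resolution).
#'
#' @param k_on monomer binding rate constant, uM^-1 s^-1.
#' @param k_off monomer dissociation rate, s^-1.
#' @param reca_concentration free RecA concentration, uM.
#' @return A [rate_model()] with states `M0`, `M1`, `M2`.
#' @export
build_end_dynamics_model <- function(k_on, k_off, reca_concentration) {
  stopifnot(k_on >= 0, k_off >= 0, reca_concentration >= 0)
  kb <- k_on * reca_concentration
  rates <- matrix(0, 3, 3)
  rates[1, 2] <- kb
  rates[2, 3] <- kb
  rates[2, 1] <- k_off
  rates[3, 2] <- k_off
  scaled <- matrix(FALSE, 3, 3)
  scaled[1, 2] <- scaled[2, 3] <- TRUE
  rate_model(c("M0", "M1", "M2"), rates, scaled, reca_concentration)
}

#' Stationary distribution of a rate model
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for the chain's generator. For a reducible
#' chain this returns one stationary distribution (least-squares solution).
#'
#' @param model a [rate_model()].
#' @return named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(model) {
  Q <- model$rates
  diag(Q) <- -rowSums(Q)
  K <- nrow(Q)
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  p <- qr.solve(A, b)
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- model$states
  p
}
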