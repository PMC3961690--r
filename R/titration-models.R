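#' One-pKa titration model parameters
#'
#' Limiting chemical shifts and midpoint of a single-site acid titration
#' followed by NMR in fast exchange. The observed shift at any pH is the
#' population-weighted average of the protonated and deprotonated limits.
#' The two limits need not be ordered: titrations may move a resonance
#' upfield or downfield.
#'
#' @param delta_protonated Chemical shift (ppm) of the fully protonated limit.
#' @param delta_deprotonated Chemical shift (ppm) of the fully deprotonated
#'   limit.
#' @param pka Midpoint of the titration on the pH axis.
#' @return An object of class `one_pka_params`.
#' @seealso [shift_one_pka()]
#' @export
one_pka_params <- function(delta_protonated, delta_deprotonated, pka) {
  stopifnot(
    is.numeric(delta_protonated), length(delta_protonated) == 1L,
    is.finite(delta_protonated),
    is.numeric(delta_deprotonated), length(delta_deprotonated) == 1L,
    is.finite(delta_deprotonated),
    is.numeric(pka), length(pka) == 1L, is.finite(pka)
  )
  structure(
    list(
      delta_protonated = as.numeric(delta_protonated),
      delta_deprotonated = as.numeric(delta_deprotonated),
      pka = as.numeric(pka)
    ),
    class = "one_pka_params"
  )
}

#' Two-pKa titration model parameters
#'
#' Parameters of a double-sigmoid chemical-shift titration: three limiting
#' shifts (doubly protonated, intermediate plateau, doubly deprotonated) and
#' two midpoints with `pka1 <= pka2`.
#'
#' @param delta_state0 Shift (ppm) of the doubly protonated limit.
#' @param delta_state1 Shift (ppm) of the intermediate (singly deprotonated)
#'   plateau.
#' @param delta_state2 Shift (ppm) of the doubly deprotonated limit.
#' @param pka1,pka2 First and second midpoints (pH units), `pka1 <= pka2`.
#' @return An object of class `two_pka_params`.
#' @seealso [shift_two_pka()]
#' @export
two_pka_params <- function(delta_state0, delta_state1, delta_state2,
                           pka1, pka2) {
  vals <- c(delta_state0, delta_state1, delta_state2, pka1, pka2)
  stopifnot(is.numeric(vals), length(vals) == 5L, all(is.finite(vals)))
  if (pka1 > pka2) {
    stop("pka1 must not exceed pka2; order the transitions before construction",
         call. = FALSE)
  }
  structure(
    list(
      delta_state0 = as.numeric(delta_state0),
      delta_state1 = as.numeric(delta_state1),
      delta_state2 = as.numeric(delta_state2),
      pka1 = as.numeric(pka1),
      pka2 = as.numeric(pka2)
    ),
    class = "two_pka_params"
  )
}

#' Chemical shift of a one-pKa titration
#'
#' Evaluates the fast-exchange population-weighted shift
#' \deqn{\delta(pH) = \frac{\delta_{HA} + \delta_{A}\,10^{pH-pK_a}}
#'                         {1 + 10^{pH-pK_a}}.}
#' The implementation works with the deprotonated fraction
#' `1 / (1 + 10^-(pH - pKa))`, which stays finite for arbitrarily large
#' `|pH - pKa|`.
#'
#' @param ph pH value(s); finite numeric vector.
#' @param params A [one_pka_params()] object.
#' @return Chemical shift(s) in ppm, same length as `ph`.
#' @export
shift_one_pka <- function(ph, params) {
  stopifnot(inherits(params, "one_pka_params"), is.numeric(ph),
            all(is.finite(ph)))
  f <- 1 / (1 + 10^(params$pka - ph)) # deprotonated fraction, overflow-safe
  params$delta_protonated * (1 - f) + params$delta_deprotonated * f
}

#' Chemical shift of a two-pKa titration
#'
#' Evaluates the double-sigmoid fast-exchange shift
#' \deqn{\delta(pH) = \frac{\delta_{H_2A} + \delta_{HA}\,10^{pH-pK_{a1}}
#'                          + \delta_{A}\,10^{2pH-pK_{a1}-pK_{a2}}}
#'                         {1 + 10^{pH-pK_{a1}} + 10^{2pH-pK_{a1}-pK_{a2}}}.}
#' All powers of ten are rescaled by the largest exponent before summation so
#' the curve is finite far outside the titrating region.
#'
#' @inheritParams shift_one_pka
#' @param params A [two_pka_params()] object.
#' @return Chemical shift(s) in ppm, same length as `ph`.
#' @export
shift_two_pka <- function(ph, params) {
  stopifnot(inherits(params, "two_pka_params"), is.numeric(ph),
            all(is.finite(ph)))
  e1 <- ph - params$pka1
  e2 <- 2 * ph - params$pka1 - params$pka2
  m <- pmax(0, e1, e2)
  w0 <- 10^(-m)
  w1 <- 10^(e1 - m)
  w2 <- 10^(e2 - m)
  (params$delta_state0 * w0 + params$delta_state1 * w1 +
      params$delta_state2 * w2) / (w0 + w1 + w2)
}

#' Coupled two-site microscopic ionization model
#'
#' Four-microstate scheme for two interacting titratable groups A and B
#' (e.g. a buried active-site aspartate and the attacking cysteine thiol of a
#' thioredoxin-fold -CXXC- motif). Each site has two microscopic constants,
#' one for deprotonating while the partner is still protonated and one for
#' deprotonating after the partner has ionized. Thermodynamic cycle closure
#' requires `pk_a_first + pk_b_given_a == pk_b_first + pk_a_given_b`; the
#' constructor accepts three constants and derives the fourth, or validates
#' closure when all four are supplied.
#'
#' @param pk_a_first Microscopic pKa of site A while B is protonated.
#' @param pk_b_first Microscopic pKa of site B while A is protonated.
#' @param pk_a_given_b Microscopic pKa of site A after B has deprotonated
#'   (derived from the cycle when `NULL`).
#' @param pk_b_given_a Microscopic pKa of site B after A has deprotonated
#'   (derived from the cycle when `NULL`).
#' @param tol Cycle-closure tolerance (pH units).
#' @return An object of class `coupled_site_model`.
#' @seealso [microstate_fractions()], [macroscopic_from_microscopic()]
#' @export
coupled_site_model <- function(pk_a_first, pk_b_first,
                               pk_a_given_b = NULL, pk_b_given_a = NULL,
                               tol = 1e-9) {
  stopifnot(is.finite(pk_a_first), is.finite(pk_b_first))
  if (is.null(pk_a_given_b) && is.null(pk_b_given_a)) {
    stop("supply at least one of pk_a_given_b, pk_b_given_a", call. = FALSE)
  }
  if (is.null(pk_b_given_a)) {
    stopifnot(is.finite(pk_a_given_b))
    pk_b_given_a <- pk_b_first + pk_a_given_b - pk_a_first
  } else if (is.null(pk_a_given_b)) {
    stopifnot(is.finite(pk_b_given_a))
    pk_a_given_b <- pk_a_first + pk_b_given_a - pk_b_first
  } else {
    stopifnot(is.finite(pk_a_given_b), is.finite(pk_b_given_a))
    gap <- abs((pk_a_first + pk_b_given_a) - (pk_b_first + pk_a_given_b))
    if (gap > tol) {
      stop(sprintf(
        "thermodynamic cycle closure violated by %.3g pH units (tol %.3g)",
        gap, tol
      ), call. = FALSE)
    }
  }
  structure(
    list(
      pk_a_first = as.numeric(pk_a_first),
      pk_b_first = as.numeric(pk_b_first),
      pk_a_given_b = as.numeric(pk_a_given_b),
      pk_b_given_a = as.numeric(pk_b_given_a)
    ),
    class = "coupled_site_model"
  )
}

#' Symmetric coupled-site model
#'
#' Convenience constructor for the fully coupled case in which both sites
#' share the same pair of microscopic constants: whichever site ionizes first
#' does so with `pk_first`, and the remaining site then ionizes with
#' `pk_second`. This is the scheme used to describe active sites where an
#' aspartate and the attacking cysteine are indistinguishable in their
#' ionization behaviour.
#'
#' @param pk_first Shared microscopic pKa of the first deprotonation.
#' @param pk_second Shared microscopic pKa of the second deprotonation.
#' @return A [coupled_site_model()].
#' @export
symmetric_coupled_model <- function(pk_first, pk_second) {
  coupled_site_model(pk_first, pk_first, pk_second, pk_second)
}

#' Microstate population fractions of a coupled two-site model
#'
#' Populations of the four protonation microstates at given pH, from the
#' partition function
#' \deqn{Z = 1 + (K_A + K_B)/[H^+] + K_A K_{B|A}/[H^+]^2}
#' with \eqn{[H^+] = 10^{-pH}} and \eqn{K_x = 10^{-pK_x}}. Exponents are
#' rescaled by their maximum before exponentiation, so the fractions are
#' well defined at any pH.
#'
#' @param ph pH value(s).
#' @param model A [coupled_site_model()].
#' @return A data frame with columns `ph`, `f_hh` (both sites protonated),
#'   `f_ah` (A deprotonated only), `f_hb` (B deprotonated only), `f_ab`
#'   (both deprotonated). Rows sum to one.
#' @export
microstate_fractions <- function(ph, model) {
  stopifnot(inherits(model, "coupled_site_model"), is.numeric(ph),
            all(is.finite(ph)))
  e_ah <- ph - model$pk_a_first
  e_hb <- ph - model$pk_b_first
  e_ab <- 2 * ph - model$pk_a_first - model$pk_b_given_a
  m <- pmax(0, e_ah, e_hb, e_ab)
  w_hh <- 10^(-m)
  w_ah <- 10^(e_ah - m)
  w_hb <- 10^(e_hb - m)
  w_ab <- 10^(e_ab - m)
  z <- w_hh + w_ah + w_hb + w_ab
  data.frame(
    ph = ph,
    f_hh = w_hh / z,
    f_ah = w_ah / z,
    f_hb = w_hb / z,
    f_ab = w_ab / z
  )
}

#' Deprotonation fraction of one site in a coupled model
#'
#' Probability that the named site is deprotonated at a given pH, i.e. the
#' sum of the two microstate populations in which it has lost its proton.
#' This marginal curve is exactly the two-pKa closed form evaluated with the
#' macroscopic constants of the model and an intermediate plateau of
#' `K_B / (K_A + K_B)` (for site B).
#'
#' @inheritParams microstate_fractions
#' @param site `"A"` or `"B"`.
#' @return Numeric vector of fractions in `[0, 1]`, one per `ph`.
#' @export
site_deprotonation_fraction <- function(ph, model, site = c("A", "B")) {
  site <- match.arg(site)
  f <- microstate_fractions(ph, model)
  if (site == "A") f$f_ah + f$f_ab else f$f_hb + f$f_ab
}

#' Macroscopic constants of a coupled two-site model
#'
#' Converts microscopic constants to the two macroscopic (proton-counting)
#' constants: \eqn{K_{a1} = K_A + K_B} and
#' \eqn{K_{a2} = K_A K_{B|A} / (K_A + K_B)}. For a symmetric model the
#' macroscopic values sit `log10(2)` outside the shared microscopic pair
#' (the statistical factor).
#'
#' @param model A [coupled_site_model()].
#' @return Named numeric vector `c(pka1 = ..., pka2 = ...)` with
#'   `pka1 <= pka2`.
#' @seealso [microscopic_from_macroscopic()] for the inverse under a
#'   symmetry assumption.
#' @export
macroscopic_from_microscopic <- function(model) {
  stopifnot(inherits(model, "coupled_site_model"))
  ka <- 10^(-model$pk_a_first)
  kb <- 10^(-model$pk_b_first)
  pka1 <- -log10(ka + kb)
  # Ka1 * Ka2 = K_A * K_{B|A}, so the second constant follows in log space
  pka2 <- model$pk_a_first + model$pk_b_given_a - pka1
  out <- sort(c(pka1 = pka1, pka2 = pka2))
  names(out) <- c("pka1", "pka2")
  out
}

#' Symmetric microscopic constants from macroscopic ones
#'
#' Inverts [macroscopic_from_microscopic()] under the assumption that both
#' sites share the same microscopic pair (fully coupled, symmetric case):
#' the shared first-step constant is `pka1 + log10(2)` and the shared
#' second-step constant is `pka2 - log10(2)`. Two macroscopic constants
#' cannot determine four microscopic ones in general; symmetry supplies the
#' missing constraint and is the natural reading of a double-sigmoid curve
#' with two almost equal steps.
#'
#' @param pka1,pka2 Macroscopic constants with `pka1 <= pka2`.
#' @return A symmetric [coupled_site_model()].
#' @export
microscopic_from_macroscopic <- function(pka1, pka2) {
  stopifnot(is.finite(pka1), is.finite(pka2))
  if (pka1 > pka2) stop("pka1 must not exceed pka2", call. = FALSE)
  symmetric_coupled_model(pka1 + log10(2), pka2 - log10(2))
}

#' @export
print.coupled_site_model <- function(x, ...) {
  cat("Coupled two-site ionization model (microscopic pKa values)\n")
  cat(sprintf("  site A first: %.3f   A after B: %.3f\n",
              x$pk_a_first, x$pk_a_given_b))
  cat(sprintf("  site B first: %.3f   B after A: %.3f\n",
              x$pk_b_first, x$pk_b_given_a))
  mac <- macroscopic_from_microscopic(x)
  cat(sprintf("  macroscopic: %.3f, %.3f\n", mac[["pka1"]], mac[["pka2"]]))
  invisible(x)
}
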