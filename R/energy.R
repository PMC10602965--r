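#' Energy and rate parameters for the integrin reaction ladder
#'
#' Bundles every constant of the three-reaction model of integrin clustering:
#' activation (inside-out, substrate independent), ligand binding, and
#' lateral association into focal-adhesion clusters. All energies are in kT
#' units, so the Boltzmann constant and temperature never appear separately.
#'
#' The binding energy of an integrin over a site with local gold
#' concentration `c` on a substrate of pore size `r_p` (nm) is
#' \deqn{E_b = \alpha c B / r_p + A c}
#' and the association energy is
#' \deqn{E_c = \beta c r_p / r_{max} + C}
#' with `B < 0`, so both energies increase with pore size: small pores
#' penalise binding and weaken association.
#'
#' @param E_a activation energy, kT. Constant across substrates because
#'   activation is driven by inside-out signalling, not topography.
#' @param A dimensionless coefficient of the concentration term of the
#'   binding energy, kT.
#' @param B pore-size coupling of the binding energy, kT·nm (negative).
#' @param C offset of the association energy, kT.
#' @param r_max pore size (nm) at which association on a nanoporous
#'   substrate matches a flat gold surface.
#' @param alpha intensity of the substrate effect on binding (1 = baseline).
#' @param beta intensity of the substrate effect on association (1 = baseline).
#' @param k_a_plus,k_b_plus,k_c_plus forward rates for activation, binding
#'   and association, 1/s.
#' @param dt Monte Carlo time step, seconds.
#'
#' @return An object of class `energy_params` (a named list).
#' @examples
#' p <- energy_params()
#' association_energy(150, 1, p) # 6.2 kT
#' @export
energy_params <- function(E_a = 3, A = 3.5, B = -12, C = 5.2, r_max = 150,
                          alpha = 1, beta = 1,
                          k_a_plus = 10, k_b_plus = 10, k_c_plus = 1,
                          dt = 0.010) {
  stopifnot(k_a_plus > 0, k_b_plus > 0, k_c_plus > 0, dt > 0, r_max > 0)
  structure(
    list(E_a = E_a, A = A, B = B, C = C, r_max = r_max,
         alpha = alpha, beta = beta,
         k_a_plus = k_a_plus, k_b_plus = k_b_plus, k_c_plus = k_c_plus,
         dt = dt),
    class = "energy_params"
  )
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params>\n")
  cat(sprintf("  E_a = %g kT, A = %g, B = %g kT nm, C = %g kT, r_max = %g nm\n",
              x$E_a, x$A, x$B, x$C, x$r_max))
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  cat(sprintf("  k+ (act/bind/assoc) = %g / %g / %g 1/s, dt = %g s\n",
              x$k_a_plus, x$k_b_plus, x$k_c_plus, x$dt))
  invisible(x)
}

#' Scenario presets for the pore-size sweep
#'
#' Four readings of how strongly the substrate couples into the energetics:
#' * `constant_association`: E_c pinned at 6.2 kT; only binding feels pore size.
#' * `baseline`: alpha = 1, beta = 1 — both energies depend on pore size.
#' * `weak_coupling`: alpha = 0.5, beta = 0.5 — weaker dependence.
#' * `strong_coupling`: alpha = 2.5, beta = 2 — stronger dependence.
#'
#' @param scenario one of `"constant_association"`, `"baseline"`,
#'   `"weak_coupling"`, `"strong_coupling"`.
#' @param ... overrides passed on to [energy_params()].
#' @return An `energy_params` object with an `ec_constant` attribute flagging
#'   the constant-association mode.
#' @export
scenario_params <- function(scenario = c("baseline", "constant_association",
                                         "weak_coupling", "strong_coupling"),
                            ...) {
  scenario <- match.arg(scenario)
  p <- switch(scenario,
    constant_association = energy_params(alpha = 1, beta = 1, ...),
    baseline             = energy_params(alpha = 1, beta = 1, ...),
    weak_coupling        = energy_params(alpha = 0.5, beta = 0.5, ...),
    strong_coupling      = energy_params(alpha = 2.5, beta = 2, ...)
  )
  attr(p, "ec_constant") <- identical(scenario, "constant_association")
  attr(p, "scenario") <- scenario
  p
}

#' Equilibrium activation ratio k_a+/k_a-
#'
#' The activation reaction is biased against the active state:
#' k_a+/k_a- = exp(-E_a).
#'
#' @param params an [energy_params()] object.
#' @return exp(-E_a), dimensionless.
#' @export
activation_ratio <- function(params = energy_params()) {
  exp(-params$E_a)
}

#' Binding energy of an integrin, kT
#'
#' E_b = alpha * c * B / r_p + A * c. A flat gold surface is represented by
#' the sentinel `r_p = Inf`, where the pore term vanishes and E_b = A * c.
#'
#' @param r_p pore size in nm (> 0), or `Inf` for flat gold.
#' @param c local gold concentration in \[0, 1\]. Vectorised over `r_p` and `c`.
#' @param params an [energy_params()] object.
#' @return Binding energy in kT.
#' @examples
#' binding_energy(150, 1) # 3.42 kT
#' binding_energy(20, 1)  # 2.90 kT
#' @export
binding_energy <- function(r_p, c, params = energy_params()) {
  if (any(r_p <= 0)) {
    stop("pore size `r_p` must be positive (use Inf for flat gold)",
         call. = FALSE)
  }
  if (any(c < 0 | c > 1)) {
    stop("gold concentration `c` must lie in [0, 1]", call. = FALSE)
  }
  pore_term <- params$alpha * c * params$B / r_p
  pore_term[is.infinite(r_p)] <- 0
  pore_term + params$A * c
}

#' Association energy between neighbouring bound integrins, kT
#'
#' E_c = beta * c * r_p / r_max + C, or a fixed 6.2 kT when
#' `constant_mode = TRUE` (the reading in which pore size does not couple
#' into association at all). Flat gold (`r_p = Inf`) maps onto the r_max
#' value: association on flat gold equals association at the largest pore.
#'
#' @inheritParams binding_energy
#' @param constant_mode if `TRUE`, return 6.2 kT regardless of inputs.
#' @return Association energy in kT.
#' @examples
#' association_energy(150, 1) # 6.2 kT
#' association_energy(75, 1)  # 5.7 kT
#' @export
association_energy <- function(r_p, c, params = energy_params(),
                               constant_mode = FALSE) {
  if (isTRUE(constant_mode)) {
    return(rep_len(6.2, max(length(r_p), length(c))))
  }
  if (any(r_p <= 0)) {
    stop("pore size `r_p` must be positive (use Inf for flat gold)",
         call. = FALSE)
  }
  if (any(c < 0 | c > 1)) {
    stop("gold concentration `c` must lie in [0, 1]", call. = FALSE)
  }
  r_eff <- pmin(r_p, params$r_max)
  params$beta * c * r_eff / params$r_max + params$C
}

#' Reverse rate from a forward rate and an energy
#'
#' Makes the detailed-balance ratio hold for each reaction channel:
#' * activation (`direction = "favors_reverse"`): k+/k- = exp(-E), so
#'   k- = k+ * exp(+E);
#' * binding and association (`direction = "favors_forward"`):
#'   k+/k- = exp(+E), so k- = k+ * exp(-E).
#'
#' @param k_plus forward rate, 1/s (> 0).
#' @param energy_kT channel energy in kT.
#' @param direction which side of the reaction the energy favours.
#' @return Reverse rate in 1/s.
#' @examples
#' reverse_rate(10, 3, "favors_reverse")  # k_a- = 10 e^3
#' reverse_rate(1, 6.2, "favors_forward") # k_c- ~ 2.03e-3
#' @export
reverse_rate <- function(k_plus, energy_kT,
                         direction = c("favors_forward", "favors_reverse")) {
  direction <- match.arg(direction)
  if (any(k_plus <= 0)) stop("`k_plus` must be positive", call. = FALSE)
  if (direction == "favors_forward") k_plus * exp(-energy_kT)
  else k_plus * exp(energy_kT)
}

#' Per-step event probability for a Poisson channel
#'
#' Converts a rate into the probability that the channel fires at least once
#' within one fixed time step: p = 1 - exp(-k dt). Unlike the naive k * dt
#' this is a valid probability for any rate (with the default constants the
#' inactivation channel has k * dt ~ 2, which would overflow a linear
#' mapping), and it agrees with k * dt to first order as dt -> 0.
#'
#' @param k rate, 1/s (>= 0). Vectorised.
#' @param dt time step, seconds (> 0).
#' @return Probability in \[0, 1).
#' @examples
#' step_probability(10, 0.01) # ~0.09516
#' @export
step_probability <- function(k, dt) {
  if (any(k < 0)) stop("rate `k` must be non-negative", call. = FALSE)
  if (dt <= 0) stop("time step `dt` must be positive", call. = FALSE)
  -expm1(-k * dt)
}
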