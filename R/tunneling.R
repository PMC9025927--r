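# Stable log-space hyperbolic helpers: exact for small arguments,
# overflow-free for large ones.
log_cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)
log_sinh <- function(x) {
  stopifnot(all(x > 0))
  x + log1p(-exp(-2 * x)) - log(2)
}

#' Eckart potential energy profile of a closed gate
#'
#' Evaluates U(x) = G sech^2(x/L): the peak energy G sits at x = 0 and the
#' potential falls to 0.42 G at |x| = L (sech^2(1) = 0.4199...).
#'
#' @param x Ion position along the pore axis (m); vectorised.
#' @param barrier An [eckart_barrier()].
#' @return Potential energy (J) at each `x`.
#' @export
#' @examples
#' b <- eckart_barrier(2e-20, 1e-10)
#' eckart_potential(0, b)                       # the full barrier height
#' eckart_potential(1e-10, b) / b$height_G      # 0.42
eckart_potential <- function(x, barrier) {
  stopifnot(inherits(barrier, "eckart_barrier"))
  if (barrier$gate_length_L == 0) {
    if (any(x != 0))
      stop("gate_length_L = 0 gives an undefined barrier shape at x != 0")
    return(rep(barrier$height_G, length(x)))
  }
  barrier$height_G / cosh(x / barrier$gate_length_L)^2
}

#' Kinetic energy of an ion arriving at the closed gate
#'
#' Extracellular ions are accelerated by the fraction Vm/n of the membrane
#' potential before reaching the gate and additionally carry thermal energy,
#' E_K(E) = q Vm / n + (3/2) k_B T. Intracellular ions hit the gate before
#' traversing the field and carry thermal energy only, E_K(I) = (3/2) k_B T.
#' `Vm` follows the absolute-value sign convention of the membrane solvers
#' (positive number, inside negative).
#'
#' @param ion An [ion_species()].
#' @param side "extracellular" or "intracellular".
#' @param Vm Membrane potential magnitude (V), >= 0.
#' @param barrier An [eckart_barrier()]; supplies the gate-location index n.
#' @param constants A [physical_constants()].
#' @return Kinetic energy (J).
#' @export
kinetic_energy <- function(ion, side = c("extracellular", "intracellular"),
                           Vm = 0, barrier = eckart_barrier(1e-20, 1e-10),
                           constants = physical_constants()) {
  side <- match.arg(side)
  if (!is.numeric(Vm) || any(Vm < 0))
    stop("Vm must be the absolute (non-negative) membrane potential")
  thermal <- 1.5 * constants$boltzmann_kB * constants$body_temperature_T
  if (side == "intracellular") return(thermal)
  ion$charge_q * Vm / barrier$gate_location_n + thermal
}

# 2 pi * 2 alpha  =  2 pi L sqrt(2 m E_K) / hbar  (energy-side cosh argument)
cosh_arg_energy <- function(mass, L, E_K, constants) {
  2 * pi * L * sqrt(2 * mass * E_K) / constants$hbar
}

# 2 pi * delta with delta = (1/2) sqrt(16 pi^2 L^2 * 2 G m / h^2 - 1);
# the -1 is dropped by default, in which case 2 pi delta = 2 pi L sqrt(2mG)/hbar
# (using h = 2 pi hbar). With the -1 retained it is only defined when
# 8 m G L^2 / hbar^2 >= 1.
cosh_arg_barrier <- function(mass, L, G, constants, drop_minus_one = TRUE) {
  if (drop_minus_one)
    return(pi * sqrt(16 * pi^2 * L^2 * 2 * G * mass) / constants$planck_h)
  arg <- 16 * pi^2 * L^2 * 2 * G * mass / constants$planck_h^2
  if (arg < 1)
    stop("barrier cosh argument undefined with the -1 retained (8mGL^2/hbar^2 < 1); ",
         "use drop_minus_one = TRUE")
  pi * sqrt(arg - 1)
}

#' Exact Eckart transmission probability
#'
#' Full closed-form transmission through a symmetric Eckart barrier,
#' T = (cosh(a) - 1) / (cosh(a) + cosh(b)) with a = 2 pi L sqrt(2 m E_K)/hbar
#' and b = 2 pi delta, delta = (1/2) sqrt(16 pi^2 L^2 2 G m / h^2 - 1).
#' Evaluated entirely in log space via cosh(a) - 1 = 2 sinh^2(a/2) and
#' cosh(a) + cosh(b) = 2 cosh((a+b)/2) cosh((a-b)/2), so arbitrarily large
#' arguments never overflow. By default the -1 under delta's square root is
#' dropped (it is negligible for ionic masses and gate dimensions); set
#' `drop_minus_one = FALSE` to retain it for sensitivity analysis.
#'
#' @inheritParams kinetic_energy
#' @param E_K Kinetic energy of the ion (J), > 0.
#' @param drop_minus_one Drop the -1 under delta's square root (default TRUE).
#' @param log Return log(T) instead of T.
#' @return Transmission probability in [0, 1] (or its log).
#' @export
transmission_exact <- function(ion, barrier, E_K,
                               constants = physical_constants(),
                               drop_minus_one = TRUE, log = FALSE) {
  stopifnot(inherits(ion, "ion_species"), inherits(barrier, "eckart_barrier"))
  if (E_K < 0) stop("E_K must be >= 0")
  if (barrier$height_G <= 0) stop("barrier height must be > 0")
  if (E_K == 0 || barrier$gate_length_L == 0) {
    # zero kinetic energy cannot transmit; a zero-length gate is transparent
    t <- if (E_K == 0) 0 else 1
    return(if (log) base::log(t) else t)
  }
  a <- cosh_arg_energy(ion$mass_m, barrier$gate_length_L, E_K, constants)
  b <- cosh_arg_barrier(ion$mass_m, barrier$gate_length_L, barrier$height_G,
                        constants, drop_minus_one)
  logT <- 2 * log_sinh(a / 2) - log_cosh((a + b) / 2) - log_cosh((a - b) / 2)
  logT <- min(logT, 0)
  if (log) logT else exp(logT)
}

#' Approximate Eckart transmission probability
#'
#' The large-argument approximation of the exact Eckart transmission,
#' T = exp(-(2 pi sqrt(2 m) / hbar) L (sqrt(G) - sqrt(E_K))), valid when both
#' cosh arguments of the exact form are >= 3 (cosh x ~ e^x / 2). In the
#' over-barrier regime E_K >= G the exponential would exceed one and the
#' result is clamped to 1. A warning is emitted when the validity condition
#' fails (suppress with `warn = FALSE`); the exact form remains available.
#'
#' @inheritParams transmission_exact
#' @param warn Warn when the cosh-argument validity condition fails.
#' @return Transmission probability in (0, 1] (or its log).
#' @export
transmission_approx <- function(ion, barrier, E_K,
                                constants = physical_constants(),
                                warn = TRUE, log = FALSE) {
  stopifnot(inherits(ion, "ion_species"), inherits(barrier, "eckart_barrier"))
  if (E_K < 0) stop("E_K must be >= 0")
  if (barrier$height_G <= 0) stop("barrier height must be > 0")
  G <- barrier$height_G
  L <- barrier$gate_length_L
  if (E_K >= G || L == 0) return(if (log) 0 else 1)  # over-barrier clamp
  if (warn && E_K > 0) {
    a <- cosh_arg_energy(ion$mass_m, L, E_K, constants)
    b <- cosh_arg_barrier(ion$mass_m, L, G, constants, drop_minus_one = TRUE)
    if (a < 3 || b < 3)
      warning("approximation condition cosh arguments >= 3 not met ",
              sprintf("(a = %.3g, b = %.3g); ", a, b),
              "transmission_approx may deviate from transmission_exact")
  }
  logT <- -(2 * pi * sqrt(2 * ion$mass_m) / constants$hbar) * L *
    (sqrt(G) - sqrt(E_K))
  if (log) logT else exp(logT)
}

#' Tunneling probability of an ion through a closed gate
#'
#' Composes [kinetic_energy()] with the barrier transmission: extracellular
#' ions tunnel with T_Q(E) = T(q Vm / n + 3/2 k_B T), intracellular ions with
#' T_Q(I) = T(3/2 k_B T). The approximate transmission is the default; the
#' exact Eckart form is selectable.
#'
#' @inheritParams kinetic_energy
#' @param mode "approx" (default) or "exact".
#' @param log Return log(T_Q).
#' @param warn Passed to [transmission_approx()].
#' @return Tunneling probability (or its log).
#' @export
tunneling_probability <- function(ion, barrier,
                                  side = c("extracellular", "intracellular"),
                                  Vm = 0, constants = physical_constants(),
                                  mode = c("approx", "exact"),
                                  log = FALSE, warn = FALSE) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  E_K <- kinetic_energy(ion, side, Vm, barrier, constants)
  if (mode == "approx")
    transmission_approx(ion, barrier, E_K, constants, warn = warn, log = log)
  else
    transmission_exact(ion, barrier, E_K, constants, log = log)
}

#' Quantum unitary conductance of a single closed channel
#'
#' C_Q = (q^2 / h) T_Q, in Siemens. The conductance quantum q^2/h is
#' 3.88e-5 S (3.88e-2 mS) for monovalent and 15.52e-5 S for divalent ions.
#'
#' @param ion An [ion_species()] (supplies q).
#' @param T_Q Tunneling probability in [0, 1]; vectorised.
#' @param constants A [physical_constants()].
#' @return Single-channel conductance (S).
#' @export
unitary_conductance <- function(ion, T_Q, constants = physical_constants()) {
  if (any(T_Q < 0 | T_Q > 1)) stop("T_Q must lie in [0, 1]")
  ion$charge_q^2 / constants$planck_h * T_Q
}

#' Quantum membrane conductance per unit area
#'
#' MC_Q = C_Q x D, converted to mS/cm2. Densities may be given per cm2
#' (default) or per um2 (1 um2 = 1e-8 cm2).
#'
#' @param C_Q Single-channel conductance (S); vectorised.
#' @param D Channel density (channels per `density_unit`), >= 0.
#' @param density_unit "cm2" or "um2".
#' @return Areal conductance (mS/cm2).
#' @export
#' @examples
#' membrane_conductance(3.88e-5 * 1e-11, D = 1e10)        # 3.88e-3 mS/cm2
#' membrane_conductance(3.88e-5 * 1e-11, D = 1e2, "um2")  # the same density
membrane_conductance <- function(C_Q, D, density_unit = c("cm2", "um2")) {
  density_unit <- match.arg(density_unit)
  if (any(D < 0)) stop("channel density D must be >= 0")
  if (density_unit == "um2") D <- D * 1e8
  C_Q * 1e3 * D
}
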