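#' Physical constants
#'
#' Bundle of physical constants used throughout the model. Defaults are the
#' rounded values conventionally used in channel biophysics calculations:
#' h = 6.6e-34 J s, hbar = 1.05e-34 J s, k_B = 1.38e-23 J/K,
#' F = 96485.33 C/mol, R = 8.31 J/(K mol), N_A = 6.02e23 /mol and a body
#' temperature of 310 K. Note that the rounded h and hbar are mutually
#' inconsistent in their fourth digit (6.6e-34 / 2 pi = 1.0504e-34); both are
#' kept as given so that worked examples reproduce exactly, and each is used
#' where the corresponding formula uses it.
#'
#' @param planck_h Planck constant (J s).
#' @param hbar Reduced Planck constant (J s).
#' @param boltzmann_kB Boltzmann constant (J/K).
#' @param faraday_F Faraday constant (C/mol).
#' @param gas_R Molar gas constant (J/(K mol)).
#' @param avogadro_NA Avogadro number (1/mol).
#' @param body_temperature_T Absolute temperature (K).
#' @return An object of class `physical_constants`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(planck_h = 6.6e-34,
                               hbar = 1.05e-34,
                               boltzmann_kB = 1.38e-23,
                               faraday_F = 96485.33,
                               gas_R = 8.31,
                               avogadro_NA = 6.02e23,
                               body_temperature_T = 310) {
  x <- list(planck_h = planck_h, hbar = hbar, boltzmann_kB = boltzmann_kB,
            faraday_F = faraday_F, gas_R = gas_R, avogadro_NA = avogadro_NA,
            body_temperature_T = body_temperature_T)
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    stop("physical constants must be single positive finite numbers: ",
         paste(names(x)[bad], collapse = ", "))
  structure(x, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

ELEMENTARY_CHARGE <- 1.6e-19 # C, rounded as used in the conductance quanta

#' Ion species
#'
#' Describes one permeant ion: its mass, valence (hence charge) and its
#' concentrations on the two sides of the membrane, in mmol/L. `ion()`
#' returns the built-in defaults for sodium, potassium and calcium on the
#' inner-hair-cell basolateral membrane (perilymph outside, cytoplasm
#' inside). Intracellular calcium defaults to 0 mmol/L, reflecting its
#' negligible free concentration relative to the other species.
#'
#' @param name Label, e.g. "Na".
#' @param mass_m Ion mass (kg).
#' @param valence Integer valence, 1 or 2.
#' @param conc_extracellular,conc_intracellular Concentrations (mmol/L).
#' @return An object of class `ion_species` with fields `name`, `mass_m`,
#'   `charge_q` (C), `valence`, `conc_extracellular`, `conc_intracellular`.
#' @export
#' @examples
#' ion("Na")
#' ion_species("Li", mass_m = 1.15e-26, valence = 1,
#'             conc_extracellular = 1, conc_intracellular = 0.5)
ion_species <- function(name, mass_m, valence,
                        conc_extracellular, conc_intracellular) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass_m) || mass_m <= 0) stop("mass_m must be positive")
  if (!valence %in% c(1, 2)) stop("valence must be 1 or 2")
  if (conc_extracellular < 0 || conc_intracellular < 0)
    stop("concentrations must be non-negative")
  structure(list(name = name, mass_m = mass_m,
                 charge_q = valence * ELEMENTARY_CHARGE,
                 valence = as.integer(valence),
                 conc_extracellular = conc_extracellular,
                 conc_intracellular = conc_intracellular),
            class = "ion_species")
}

#' @rdname ion_species
#' @param species One of "Na", "K", "Ca".
#' @export
ion <- function(species = c("Na", "K", "Ca")) {
  species <- match.arg(species)
  switch(species,
    Na = ion_species("Na", mass_m = 3.8e-26, valence = 1,
                     conc_extracellular = 140, conc_intracellular = 15),
    # K and Ca masses: bare atomic masses 39 u and 40 u
    K  = ion_species("K", mass_m = 6.5e-26, valence = 1,
                     conc_extracellular = 5, conc_intracellular = 120),
    Ca = ion_species("Ca", mass_m = 6.64e-26, valence = 2,
                     conc_extracellular = 1.4, conc_intracellular = 0))
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("Ion %s: m = %g kg, q = %g C (valence %d), [out]/[in] = %g/%g mmol/L\n",
              x$name, x$mass_m, x$charge_q, x$valence,
              x$conc_extracellular, x$conc_intracellular))
  invisible(x)
}

#' Eckart barrier describing a closed channel gate
#'
#' The closed gate of a voltage-gated channel is modelled as a symmetric
#' Eckart energy barrier U(x) = G sech^2(x/L). `height_G` is the peak energy
#' of the gate, `gate_length_L` the half-width at which the potential has
#' fallen to 0.42 G, and `gate_location_n` an index 1-4 for the position of
#' the gate along the pore: extracellular ions are accelerated by the
#' fraction Vm/n of the membrane potential before reaching the gate.
#'
#' @param height_G Barrier height (J), > 0.
#' @param gate_length_L Gate length (m), >= 0.
#' @param gate_location_n Integer in 1:4.
#' @return An object of class `eckart_barrier`.
#' @export
#' @examples
#' eckart_barrier(height_G = 2e-20, gate_length_L = 1e-10)
eckart_barrier <- function(height_G, gate_length_L, gate_location_n = 1L) {
  if (!is.numeric(height_G) || height_G <= 0) stop("height_G must be > 0")
  if (!is.numeric(gate_length_L) || gate_length_L < 0)
    stop("gate_length_L must be >= 0")
  if (!gate_location_n %in% 1:4) stop("gate_location_n must be in 1:4")
  structure(list(height_G = height_G, gate_length_L = gate_length_L,
                 gate_location_n = as.integer(gate_location_n)),
            class = "eckart_barrier")
}

#' @export
print.eckart_barrier <- function(x, ...) {
  cat(sprintf("Eckart barrier: G = %g J, L = %g m, n = %d\n",
              x$height_G, x$gate_length_L, x$gate_location_n))
  invisible(x)
}

#' Leak conductances and ionic concentrations of the basolateral membrane
#'
#' Classical (resting-state) leak membrane conductances for K+ and Na+ and
#' the compartment concentrations entering the Goldman-Hodgkin-Katz balance
#' of the inner-hair-cell basolateral membrane. Defaults: MC_K = 0.5 and
#' MC_Na = 0.01 mS/cm2; [K] 5/120, [Na] 140/15, [Ca] 1.4/0 mmol/L
#' (extracellular/intracellular).
#'
#' @param MC_K,MC_Na Leak membrane conductances (mS/cm2).
#' @param K_out,K_in,Na_out,Na_in,Ca_out,Ca_in Concentrations (mmol/L).
#' @return An object of class `leak_profile`.
#' @export
leak_profile <- function(MC_K = 0.5, MC_Na = 0.01,
                         Na_out = 140, Na_in = 15,
                         K_out = 5, K_in = 120,
                         Ca_out = 1.4, Ca_in = 0) {
  x <- list(MC_K = MC_K, MC_Na = MC_Na, Na_out = Na_out, Na_in = Na_in,
            K_out = K_out, K_in = K_in, Ca_out = Ca_out, Ca_in = Ca_in)
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("leak profile values must be non-negative numbers: ",
         paste(names(x)[bad], collapse = ", "))
  structure(x, class = "leak_profile")
}

#' @export
print.leak_profile <- function(x, ...) {
  cat(sprintf("Leak profile: MC_K = %g, MC_Na = %g mS/cm2\n", x$MC_K, x$MC_Na))
  cat(sprintf("  [Na] %g/%g, [K] %g/%g, [Ca] %g/%g mmol/L (out/in)\n",
              x$Na_out, x$Na_in, x$K_out, x$K_in, x$Ca_out, x$Ca_in))
  invisible(x)
}

# Weighted leak sums of the GHK balance (mS/cm2 * mmol/L).
# S1 gathers extracellular, S2 intracellular leak terms.
leak_sums <- function(leak) {
  list(S1 = leak$MC_Na * leak$Na_out + leak$MC_K * leak$K_out,
       S2 = leak$MC_Na * leak$Na_in + leak$MC_K * leak$K_in)
}

#' Axon geometry for the quantum-synapse release calculation
#'
#' A demyelinated axon segment is idealised as a cylinder. Defaults describe
#' an axon of radius 0.5 um and length 100 um (lateral surface 314 um2,
#' volume 78.5 um3), an extracellular-to-intracellular volume ratio of 0.67,
#' a potassium efflux of 1.37e6 ions per action potential over that surface,
#' and a channel density of 100 channels/um2.
#'
#' @param radius_r Axon radius (um).
#' @param length_Laxon Axon length (um).
#' @param extra_to_intra_ratio Extracellular/intracellular volume ratio.
#' @param N_AP_total K+ ions released per action potential over the surface.
#' @param channel_density_Dum2 Channel density (channels/um2).
#' @return An object of class `axon_geometry`.
#' @export
axon_geometry <- function(radius_r = 0.5, length_Laxon = 100,
                          extra_to_intra_ratio = 0.67,
                          N_AP_total = 1.37e6,
                          channel_density_Dum2 = 100) {
  if (radius_r <= 0 || length_Laxon <= 0) stop("radius and length must be > 0")
  if (extra_to_intra_ratio <= 0) stop("extra_to_intra_ratio must be > 0")
  if (N_AP_total < 0) stop("N_AP_total must be >= 0")
  if (channel_density_Dum2 < 0) stop("channel_density_Dum2 must be >= 0")
  structure(list(radius_r = radius_r, length_Laxon = length_Laxon,
                 extra_to_intra_ratio = extra_to_intra_ratio,
                 N_AP_total = N_AP_total,
                 channel_density_Dum2 = channel_density_Dum2),
            class = "axon_geometry")
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat(sprintf("Axon: r = %g um, L = %g um, V_E/V_I = %g, N_AP = %g, D = %g /um2\n",
              x$radius_r, x$length_Laxon, x$extra_to_intra_ratio,
              x$N_AP_total, x$channel_density_Dum2))
  invisible(x)
}
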