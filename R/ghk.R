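#' Quantum GHK scenario
#'
#' Bundles everything one self-consistent membrane-potential solve needs:
#' the tunneling ion, the closed-gate barrier, the channel density of the
#' tunneling pathway, the classical leak profile, physical constants and the
#' transmission mode. One scenario carries exactly one tunneling ion;
#' per-ion depolarization curves are obtained by sweeping scenarios.
#'
#' @param tunneling_ion An [ion_species()].
#' @param barrier An [eckart_barrier()].
#' @param channel_density_D Channel density (channels/cm2), >= 0.
#' @param leak A [leak_profile()].
#' @param constants A [physical_constants()].
#' @param transmission_mode "approx" or "exact".
#' @return An object of class `quantum_ghk_scenario`.
#' @export
quantum_scenario <- function(tunneling_ion, barrier, channel_density_D = 1e10,
                             leak = leak_profile(),
                             constants = physical_constants(),
                             transmission_mode = c("approx", "exact")) {
  stopifnot(inherits(tunneling_ion, "ion_species"),
            inherits(barrier, "eckart_barrier"),
            inherits(leak, "leak_profile"))
  if (channel_density_D < 0) stop("channel_density_D must be >= 0")
  structure(list(tunneling_ion = tunneling_ion, barrier = barrier,
                 channel_density_D = channel_density_D, leak = leak,
                 constants = constants,
                 transmission_mode = match.arg(transmission_mode)),
            class = "quantum_ghk_scenario")
}

vm_solution <- function(Vm, converged, residual, branch_note = "") {
  structure(list(Vm = Vm, converged = converged, residual = residual,
                 branch_note = branch_note), class = "vm_solution")
}

#' @export
print.vm_solution <- function(x, ...) {
  cat(sprintf("Vm = %.6f V (absolute value, inside negative)%s\n", x$Vm,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  residual = %.3g", x$residual))
  if (nzchar(x$branch_note)) cat("  note:", x$branch_note)
  cat("\n")
  invisible(x)
}

#' Classical GHK membrane potential of the basolateral membrane
#'
#' Closed-form resting potential from the two-ion Goldman-Hodgkin-Katz
#' balance MC_Na [Na]_E + MC_K [K]_E = exp(-F Vm / RT) (MC_Na [Na]_I +
#' MC_K [K]_I), i.e. Vm = (RT/F) log(S2/S1). The sign convention is the
#' absolute magnitude (positive number, cytoplasm negative). With the
#' default leak profile this gives 0.073 V.
#'
#' @param leak A [leak_profile()].
#' @param constants A [physical_constants()].
#' @return A `vm_solution` (exact; residual 0 up to round-off).
#' @export
#' @examples
#' classical_vm()$Vm   # 0.073 V
classical_vm <- function(leak = leak_profile(),
                         constants = physical_constants()) {
  s <- leak_sums(leak)
  if (s$S1 <= 0 || s$S2 <= 0)
    stop("both weighted conductance-concentration sums must be positive")
  cFRT <- constants$faraday_F /
    (constants$gas_R * constants$body_temperature_T)
  Vm <- log(s$S2 / s$S1) / cFRT
  vm_solution(Vm = Vm, converged = TRUE,
              residual = abs(s$S1 - exp(-cFRT * Vm) * s$S2),
              branch_note = "classical closed form")
}

# Quantum term MC_Q * [ion] (mS/cm2 * mmol/L) for one side, as a function of
# the Vm used in the extracellular kinetic energy.
quantum_term <- function(scenario, side, Vm_kinetic) {
  ion <- scenario$tunneling_ion
  T_Q <- tunneling_probability(ion, scenario$barrier, side, Vm_kinetic,
                               scenario$constants,
                               mode = scenario$transmission_mode)
  conc <- if (side == "extracellular") ion$conc_extracellular
          else ion$conc_intracellular
  membrane_conductance(unitary_conductance(ion, T_Q, scenario$constants),
                       scenario$channel_density_D) * conc
}

# Root function of the self-consistent GHK balance; strictly increasing in
# Vm, so it has at most one zero on [0, Vm_max].
ghk_residual_fn <- function(scenario, kinetic_vm = NULL) {
  s <- leak_sums(scenario$leak)
  cFRT <- scenario$constants$faraday_F /
    (scenario$constants$gas_R * scenario$constants$body_temperature_T)
  H_I <- quantum_term(scenario, "intracellular", 0)
  divalent <- scenario$tunneling_ion$valence == 2L
  function(Vm) {
    Vk <- if (is.null(kinetic_vm)) Vm else kinetic_vm
    H_E <- quantum_term(scenario, "extracellular", Vk)
    if (!divalent) {
      s$S1 + H_E - exp(-cFRT * Vm) * (s$S2 + H_I)
    } else {
      disc <- (s$S1 + s$S2)^2 +
        4 * (s$S1 * H_I + s$S2 * H_E + H_E * H_I)
      stopifnot(disc >= 0)
      (s$S1 - s$S2) + sqrt(disc) - 2 * exp(-cFRT * Vm) * (s$S2 + H_I)
    }
  }
}

solve_ghk <- function(scenario, kinetic_vm = NULL, warm_start = NULL,
                      Vm_max = NULL, n_scan = 24, tol = 1e-15) {
  if (is.null(Vm_max)) {
    # the quantum terms only deepen the extracellular drive, so the root sits
    # at or below the classical potential; 0.12 V covers the physiological
    # range and the classical bound (plus margin) covers unusual profiles
    s <- leak_sums(scenario$leak)
    cFRT <- scenario$constants$faraday_F /
      (scenario$constants$gas_R * scenario$constants$body_temperature_T)
    cl <- if (s$S2 > s$S1) log(s$S2 / s$S1) / cFRT else 0
    Vm_max <- max(0.12, cl + 0.05)
  }
  f <- ghk_residual_fn(scenario, kinetic_vm)
  f0 <- f(0)
  if (f0 >= 0)  # quantum drive already exceeds the balance at Vm = 0
    return(vm_solution(0, TRUE, abs(f0), "fully depolarized (boundary)"))
  grid <- seq(0, Vm_max, length.out = n_scan + 1)
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  if (length(cross) == 0)
    return(vm_solution(Vm_max, FALSE, abs(fv[length(fv)]),
                       "no sign change in [0, Vm_max]"))
  note <- ""
  if (length(cross) > 1) {
    note <- sprintf("multistable: %d sign changes", length(cross))
    pick <- if (is.null(warm_start)) cross[length(cross)]
            else cross[which.min(abs(grid[cross] - warm_start))]
  } else pick <- cross
  r <- stats::uniroot(f, lower = grid[pick], upper = grid[pick + 1],
                      tol = tol, maxiter = 200)
  vm_solution(r$root, TRUE, abs(f(r$root)), note)
}

#' Quantum GHK membrane potential, monovalent tunneling ion
#'
#' Solves the GHK balance extended with the quantum conductance terms of one
#' monovalent tunneling ion (Na+ or K+): S1 + MC_Q(E) [ion]_E =
#' exp(-F Vm/RT) (S2 + MC_Q(I) [ion]_I). The extracellular tunneling
#' probability depends on the very Vm being solved for (the potential feeds
#' the kinetic energy that feeds the conductance), so the equation is solved
#' self-consistently as a bracketed scalar root problem on [0, 0.12] V.
#' Passing `kinetic_vm` instead freezes the kinetic energy at that potential
#' (e.g. the classical resting value) and solves only the GHK exponential.
#'
#' @param scenario A [quantum_scenario()] with a monovalent tunneling ion.
#' @param kinetic_vm Optional fixed potential (V) for the extracellular
#'   kinetic energy; `NULL` (default) solves self-consistently.
#' @param warm_start Optional previous root (V) used to pick the continuous
#'   branch if several sign changes are detected.
#' @return A `vm_solution`; non-convergence is flagged, never silent.
#' @export
quantum_vm_monovalent <- function(scenario, kinetic_vm = NULL,
                                  warm_start = NULL) {
  stopifnot(inherits(scenario, "quantum_ghk_scenario"))
  if (scenario$tunneling_ion$valence != 1L)
    stop("tunneling ion must be monovalent; use quantum_vm_divalent() for Ca")
  solve_ghk(scenario, kinetic_vm, warm_start)
}

#' Quantum GHK membrane potential, divalent tunneling ion
#'
#' Solves the divalent (quadratic-form) GHK balance
#' (S1 - S2) + sqrt((S1 + S2)^2 + 4 (S1 H2 + S2 H1 + H1 H2)) =
#' 2 exp(-F Vm/RT) (S2 + H2), with H1 = MC_Q(Ca,E) [Ca]_E and
#' H2 = MC_Q(Ca,I) [Ca]_I, self-consistently in Vm. The default leak profile
#' has [Ca]_I = 0, i.e. H2 = 0 (free intracellular calcium is negligible);
#' supplying `Ca_in > 0` in the leak profile exercises the general form.
#' With H1 = H2 = 0 the equation reduces algebraically to the classical
#' two-ion balance.
#'
#' @inheritParams quantum_vm_monovalent
#' @param scenario A [quantum_scenario()] with a divalent tunneling ion.
#' @return A `vm_solution`.
#' @export
quantum_vm_divalent <- function(scenario, kinetic_vm = NULL,
                                warm_start = NULL) {
  stopifnot(inherits(scenario, "quantum_ghk_scenario"))
  if (scenario$tunneling_ion$valence != 2L)
    stop("tunneling ion must be divalent (Ca)")
  solve_ghk(scenario, kinetic_vm, warm_start)
}

#' Quantum GHK membrane potential (dispatching on valence)
#'
#' @inheritParams quantum_vm_monovalent
#' @return A `vm_solution`.
#' @export
quantum_vm <- function(scenario, kinetic_vm = NULL, warm_start = NULL) {
  if (scenario$tunneling_ion$valence == 2L)
    quantum_vm_divalent(scenario, kinetic_vm, warm_start)
  else
    quantum_vm_monovalent(scenario, kinetic_vm, warm_start)
}

#' Sweep the barrier height and solve the membrane potential per ion
#'
#' Reproduces the depolarization curves Vm(G) for Na+, K+ and Ca2+ while one
#' gate parameter is varied: `sweep_axis = "gate_length"` runs the curve set
#' L in {0.5, 1, 1.5, 2} x 1e-10 m at fixed n; `"gate_location"` runs
#' n in {1, 2, 3, 4} at fixed L. The grid must be descending in G so each
#' solve is warm-started from the previous (higher-G) root, keeping the
#' branch continuous with the classical resting state. Non-converged points
#' are flagged in the `converged` column, never dropped.
#'
#' @param G_grid Barrier heights (J), sorted descending.
#' @param sweep_axis "gate_length" or "gate_location".
#' @param ions List of [ion_species()]; defaults to Na, K, Ca.
#' @param L_values Gate lengths (m) for the gate_length sweep.
#' @param n_values Gate locations for the gate_location sweep.
#' @param fixed_L,fixed_n The non-swept gate parameter.
#' @param channel_density_D Channel density (channels/cm2).
#' @param leak A [leak_profile()].
#' @param constants A [physical_constants()].
#' @param transmission_mode "approx" or "exact".
#' @param kinetic_vm Optional frozen kinetic-energy potential (V).
#' @return A data.frame with columns
#'   `ion, G_J, L_m, n, D_per_cm2, Vm_V, converged, branch_note`, ordered by
#'   ion then descending G.
#' @export
sweep_barrier_height <- function(G_grid,
                                 sweep_axis = c("gate_length", "gate_location"),
                                 ions = list(ion("Na"), ion("K"), ion("Ca")),
                                 L_values = c(0.5, 1, 1.5, 2) * 1e-10,
                                 n_values = 1:4,
                                 fixed_L = 1e-10, fixed_n = 1L,
                                 channel_density_D = 1e10,
                                 leak = leak_profile(),
                                 constants = physical_constants(),
                                 transmission_mode = c("approx", "exact"),
                                 kinetic_vm = NULL) {
  sweep_axis <- match.arg(sweep_axis)
  transmission_mode <- match.arg(transmission_mode)
  if (length(G_grid) == 0) stop("G_grid must be non-empty")
  if (is.unsorted(rev(G_grid), strictly = FALSE))
    stop("G_grid must be sorted in descending order")
  curves <- if (sweep_axis == "gate_length")
    lapply(L_values, function(L) list(L = L, n = fixed_n))
  else
    lapply(n_values, function(n) list(L = fixed_L, n = n))
  rows <- list()
  for (io in ions) {
    for (cv in curves) {
      prev <- NULL
      for (G in G_grid) {
        sc <- quantum_scenario(io, eckart_barrier(G, cv$L, cv$n),
                               channel_density_D, leak, constants,
                               transmission_mode)
        sol <- quantum_vm(sc, kinetic_vm = kinetic_vm, warm_start = prev)
        prev <- sol$Vm
        rows[[length(rows) + 1L]] <- data.frame(
          ion = io$name, G_J = G, L_m = cv$L, n = cv$n,
          D_per_cm2 = channel_density_D, Vm_V = sol$Vm,
          converged = sol$converged, branch_note = sol$branch_note,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
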