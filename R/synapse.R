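#' Cylinder geometry of a demyelinated axon segment
#'
#' Lateral surface 2 pi r L, intracellular volume pi r^2 L, and the
#' extracellular volume the released K+ diffuses into, taken as
#' `extra_to_intra_ratio` times the intracellular volume. Defaults give
#' surface 314 um2, V_I = 78.5 um3 and V_E = 52.6 um3.
#'
#' @param geom An [axon_geometry()].
#' @return List with `surface_area` (um2), `intra_volume` (um3),
#'   `extra_volume` (um3).
#' @export
cylinder_geometry <- function(geom = axon_geometry()) {
  stopifnot(inherits(geom, "axon_geometry"))
  surface <- 2 * pi * geom$radius_r * geom$length_Laxon
  intra <- pi * geom$radius_r^2 * geom$length_Laxon
  list(surface_area = surface, intra_volume = intra,
       extra_volume = geom$extra_to_intra_ratio * intra)
}

#' Extracellular potassium concentration rise per action potential
#'
#' [K]_AP = N_AP / (N_A V_E): the K+ ions released during one action
#' potential, diluted into the periaxonal extracellular volume. `V_E` is in
#' um3 (1 um3 = 1e-15 L); the result is in mmol/L.
#'
#' @param N_AP Number of K+ ions released per action potential.
#' @param V_E Extracellular volume (um3), > 0.
#' @param constants A [physical_constants()] (supplies Avogadro's number).
#' @return Concentration rise (mmol/L).
#' @export
#' @examples
#' k_release_concentration(1.37e6, 52.6)   # ~4.3e-2 mmol/L
k_release_concentration <- function(N_AP, V_E,
                                    constants = physical_constants()) {
  if (V_E <= 0) stop("V_E must be > 0")
  if (N_AP < 0) stop("N_AP must be >= 0")
  mol_per_L <- N_AP / (constants$avogadro_NA * V_E * 1e-15)
  mol_per_L * 1e3
}

#' Average number of released K+ ions hitting one closed channel
#'
#' N_K = N_AP / D with N_AP as an areal density (ions/um2) and D the channel
#' density (channels/um2). The nearest integer is used as the Bernoulli
#' trial count; the unrounded ratio is kept alongside.
#'
#' @param area_density_NAP Released ions per um2.
#' @param D Channel density (channels/um2), > 0.
#' @return List with `N_K` (integer count) and `ratio` (unrounded).
#' @export
#' @examples
#' ions_per_channel(1.37e6 / (2 * pi * 0.5 * 100), 100)$N_K   # 44
ions_per_channel <- function(area_density_NAP, D) {
  if (D <= 0) stop("channel density D must be > 0")
  if (area_density_NAP < 0) stop("ion density must be >= 0")
  ratio <- area_density_NAP / D
  list(N_K = as.integer(round(ratio)), ratio = ratio)
}

#' Threshold tunneling probability for action-potential induction
#'
#' Solves the GHK threshold balance S1 + [K]_AP MC_Q-K(E) =
#' exp(-F Vm(Thr)/RT) S2 for the tunneling probability hidden inside
#' MC_Q = (q^2/h) T_Q D: the smallest T_Q whose quantum conductance, driven
#' by the per-AP potassium rise [K]_AP, depolarizes the membrane to the
#' firing threshold. Closed form:
#' T_Q(Thr) = (exp(-F Vm_thr / RT) S2 - S1) / ((q^2/h) D [K]_AP),
#' with the conductance quantum in mS so the units match the mS/cm2 x mmol/L
#' leak sums. T_Q(Thr) is inversely proportional to [K]_AP; the
#' proportionality coefficient T_Q(Thr) x [K]_AP is returned alongside.
#'
#' @param K_AP Potassium concentration rise (mmol/L), > 0.
#' @param Vm_threshold Firing-threshold potential magnitude (V); default
#'   0.055 V (the membrane fires when |Vm| falls from 0.073 to 0.055 V).
#' @param D Channel density (channels/cm2); default 1e8 (1 channel/um2: one
#'   channel per patch suffices to reach threshold).
#' @param leak A [leak_profile()].
#' @param constants A [physical_constants()].
#' @return List with `T_Q_thr` and `coefficient` (= T_Q_thr x K_AP, mmol/L).
#' @export
#' @examples
#' threshold_tunneling(4.3e-2)$T_Q_thr   # ~2.25e-5
threshold_tunneling <- function(K_AP, Vm_threshold = 0.055, D = 1e8,
                                leak = leak_profile(),
                                constants = physical_constants()) {
  if (K_AP <= 0) stop("K_AP must be > 0")
  if (Vm_threshold <= 0) stop("Vm_threshold must be > 0")
  s <- leak_sums(leak)
  cFRT <- constants$faraday_F /
    (constants$gas_R * constants$body_temperature_T)
  drive <- exp(-cFRT * Vm_threshold) * s$S2 - s$S1
  if (drive <= 0)
    stop("threshold potential lies below the resting drive: ",
         "exp(-F Vm_thr/RT) S2 - S1 <= 0; no positive T_Q reaches it")
  q <- ELEMENTARY_CHARGE  # monovalent K+
  quantum_mS <- q^2 / constants$planck_h * 1e3
  coefficient <- drive / (quantum_mS * D)
  list(T_Q_thr = coefficient / K_AP, coefficient = coefficient)
}

#' Binomial (Bernoulli-trial) probability mass
#'
#' Probability of exactly `Z` successes in `N` independent trials with
#' success probability `P`, evaluated in log space (via [stats::dbinom()])
#' so large N does not overflow the factorials.
#'
#' @param N Trial count (non-negative integer).
#' @param Z Success count, 0 <= Z <= N.
#' @param P Success probability in [0, 1].
#' @return The binomial mass P(Z).
#' @export
bernoulli_pmf <- function(N, Z, P) {
  if (any(Z > N)) stop("Z must not exceed N")
  if (any(Z < 0) || any(N < 0)) stop("N and Z must be non-negative")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  stats::dbinom(Z, N, P)
}

#' Action-potential induction probabilities of the quantum synapse
#'
#' Three-level "at least one" cascade: P1 = 1 - (1 - T_Q)^N_K is the chance
#' that at least one of the N_K potassium ions hitting a single closed
#' channel tunnels through; P2 = 1 - (1 - P1)^D that at least one of the D
#' channels in a 1-um2 patch is tunneled; P3 = 1 - (1 - P2)^N that at least
#' one of the N patches of the demyelinated area fires. Complements are
#' accumulated with log1p/expm1 so the cascade is numerically stable down to
#' T_Q ~ 1e-300; the closed-form identity
#' 1 - P3 = (1 - T_Q)^(N_K D N) holds to near machine precision.
#'
#' @param T_Q Tunneling probability of one ion, in [0, 1].
#' @param N_K Ions hitting one channel (count >= 0).
#' @param D_um2 Channels per um2 (count >= 0).
#' @param N_um2 Number of 1-um2 patches (count >= 0).
#' @return An object of class `induction_probabilities` with fields
#'   `P1`, `P2`, `P3`.
#' @export
#' @examples
#' induction_probability(2.27e-2, N_K = 44, D_um2 = 1, N_um2 = 1)
induction_probability <- function(T_Q, N_K, D_um2, N_um2) {
  if (T_Q < 0 || T_Q > 1) stop("T_Q must lie in [0, 1]")
  if (N_K < 0 || D_um2 < 0 || N_um2 < 0) stop("counts must be >= 0")
  l1 <- N_K * log1p(-T_Q)       # log(1 - P1)
  P1 <- -expm1(l1)
  l2 <- D_um2 * log1p(-P1)      # log(1 - P2)
  P2 <- -expm1(l2)
  l3 <- N_um2 * log1p(-P2)      # log(1 - P3)
  P3 <- -expm1(l3)
  structure(list(P1 = P1, P2 = P2, P3 = P3),
            class = "induction_probabilities")
}

#' @export
print.induction_probabilities <- function(x, ...) {
  cat(sprintf("AP induction: P1 = %.6g (channel), P2 = %.6g (1-um2 patch), P3 = %.6g (area)\n",
              x$P1, x$P2, x$P3))
  invisible(x)
}

#' Demyelinated-area patch count
#'
#' N_um2 = A / 1 um2: the demyelinated membrane area counted in 1-um2
#' patches.
#'
#' @param area_um2 Demyelinated area (um2), >= 0.
#' @return Patch count.
#' @export
area_patch_count <- function(area_um2) {
  if (area_um2 < 0) stop("area must be >= 0")
  area_um2 / 1
}

#' Sweep a quantum-synapse parameter against the barrier height
#'
#' For each value of one swept parameter (`axis`) and each barrier height in
#' `G_grid`, computes the extracellular K+ tunneling probability at the base
#' membrane potential and the P1/P2/P3 induction cascade. Base settings:
#' L = 1e-10 m, Vm = 0.07 V, N_K = 100, D = 100 channels/um2, N = 100
#' patches, gate location n = 1. The Vm entering the kinetic energy is the
#' fixed base (or swept) value; no self-consistency is applied here since Vm
#' is an independent axis of the sweep.
#'
#' @param axis One of "G", "L", "Vm", "N_K", "D_um2", "N_um2".
#' @param axis_values Values of the swept parameter (for `axis = "G"` the
#'   G grid itself is the axis; `axis_values` is ignored).
#' @param G_grid Barrier heights (J), descending; default 50 points from
#'   4e-20 to 1e-20 J.
#' @param L Gate length (m).
#' @param Vm Membrane potential (V) entering the kinetic energy.
#' @param N_K Ions per channel.
#' @param D_um2 Channels per um2.
#' @param N_um2 Patch count.
#' @param n Gate location index.
#' @param potassium An [ion_species()] for the tunneling K+.
#' @param constants A [physical_constants()].
#' @param transmission_mode "approx" or "exact".
#' @return A data.frame with columns
#'   `axis, axis_value, G_J, T_Q, P1, P2, P3`, ordered by axis value then
#'   descending G.
#' @export
sweep_induction <- function(axis = c("G", "L", "Vm", "N_K", "D_um2", "N_um2"),
                            axis_values = NULL,
                            G_grid = seq(4e-20, 1e-20, length.out = 50),
                            L = 1e-10, Vm = 0.07, N_K = 100, D_um2 = 100,
                            N_um2 = 100, n = 1L,
                            potassium = ion("K"),
                            constants = physical_constants(),
                            transmission_mode = c("approx", "exact")) {
  axis <- match.arg(axis)
  transmission_mode <- match.arg(transmission_mode)
  if (length(G_grid) == 0) stop("G_grid must be non-empty")
  if (is.unsorted(rev(G_grid), strictly = FALSE))
    stop("G_grid must be sorted in descending order")
  if (axis == "G") axis_values <- G_grid
  if (is.null(axis_values) || length(axis_values) == 0)
    stop("axis_values must be non-empty")
  base <- list(L = L, Vm = Vm, N_K = N_K, D_um2 = D_um2, N_um2 = N_um2)
  rows <- list()
  for (av in axis_values) {
    p <- base
    if (axis != "G") p[[axis]] <- av
    Gs <- if (axis == "G") av else G_grid
    for (G in Gs) {
      barrier <- eckart_barrier(G, p$L, n)
      T_Q <- tunneling_probability(potassium, barrier, "extracellular",
                                   p$Vm, constants,
                                   mode = transmission_mode)
      pr <- induction_probability(T_Q, p$N_K, p$D_um2, p$N_um2)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, axis_value = av, G_J = G, T_Q = T_Q,
        P1 = pr$P1, P2 = pr$P2, P3 = pr$P3, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
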