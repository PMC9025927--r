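---
title: "A quantum-tunneling model of ion permeation through closed voltage-gated channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantum-tunneling model of ion permeation through closed voltage-gated channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontunnel)
```

## The model

A closed voltage-gated channel seals its pore with a short hydrophobic
constriction — the gate. Classically the gate is an absolute barrier: an ion
whose kinetic energy is below the gate's barrier height cannot pass. This
package implements a steady-state model in which ions instead *tunnel*
through the closed gate with a small but non-zero probability, and follows
that probability through three stages:

1. **Transmission through the gate.** The gate is idealised as a symmetric
   Eckart barrier, $U(x) = G\,\mathrm{sech}^2(x/L)$, with height $G$ (J) and
   length $L$ (m; the potential falls to $0.42\,G$ at $|x| = L$). The exact
   transmission coefficient of this barrier is
   $$T_Q = \frac{\cosh(a) - 1}{\cosh(a) + \cosh(b)},\qquad
     a = \frac{2\pi L\sqrt{2mE_K}}{\hbar},\quad
     b = \frac{4\pi^2 L\sqrt{2mG}}{h},$$
   and in the regime where both $\cosh$ arguments exceed ~3 it collapses to
   the exponential form
   $$T_Q \approx \exp\!\Big[-\frac{2\pi\sqrt{2m}}{\hbar}\,
     L\,\big(\sqrt{G} - \sqrt{E_K}\big)\Big].$$
   `transmission_exact()` and `transmission_approx()` implement the two
   forms; `transmission_approx()` is the default route because the
   derivation chain of the model develops it for use, and the two agree to
   within a factor of $e$ ($|\Delta\ln T_Q|\le 1$) wherever the validity
   condition holds (a warning is raised where it does not).

2. **From transmission to conductance.** Each tunneled charge contributes
   the quantum unitary conductance $C_Q = (q^2/h)\,T_Q$ (3.88×10⁻² mS per
   unit $T_Q$ for monovalent ions, four times that for divalent), and a
   membrane patch with channel density $D$ carries the areal conductance
   $MC_Q = C_Q D$ (mS/cm²).

3. **From conductance to membrane potential.** The quantum conductance
   enters the Goldman–Hodgkin–Katz (GHK) balance of the inner-hair-cell
   basolateral membrane alongside the classical K⁺ and Na⁺ leaks. For a
   monovalent tunneling ion the balance is
   $$S_1 + MC_Q^{(E)}[\mathrm{ion}]_E =
     e^{-FV_m/RT}\big(S_2 + MC_Q^{(I)}[\mathrm{ion}]_I\big),$$
   with $S_1, S_2$ the extracellular/intracellular leak sums; for a divalent
   ion the balance takes a quadratic form (see `quantum_vm_divalent()`).
   Without quantum terms the closed form $V_m = (RT/F)\ln(S_2/S_1)$ gives
   0.073 V with the default leak profile.

Side matters: extracellular ions fall through the fraction $V_m/n$ of the
membrane potential before reaching the gate ($n \in \{1,\dots,4\}$ indexes
the gate's position along the pore) and arrive with
$E_K = qV_m/n + \tfrac32 k_B T$, while intracellular ions carry thermal
energy only. The extracellular tunneling probability therefore always
dominates, and falls as the gate sits deeper in the pore (larger $n$).

A second, independent use of the same tunneling probability is the
**quantum synapse**: during an action potential a demyelinated axon releases
$N_{AP}$ potassium ions into the periaxonal space. Each closed K⁺ channel of
an adjacent, unstimulated demyelinated axon is struck by
$N_K = N_{AP}/D$ of them, and the chance that at least one ion tunnels
somewhere over the exposed area follows the three-level Bernoulli cascade
$$P_1 = 1-(1-T_Q)^{N_K},\quad P_2 = 1-(1-P_1)^{D_{\mu m^2}},\quad
  P_3 = 1-(1-P_2)^{N_{\mu m^2}}.$$
$P_3$ is the probability that the stimulated axon induces an action
potential in its neighbour without any chemical or electrical synapse.

## Self-consistency of the quantum GHK solve

The extracellular tunneling term contains the very $V_m$ the GHK balance is
being solved for: the potential sets the kinetic energy, the kinetic energy
sets the conductance, and the conductance sets the potential. The package
treats this as a single scalar root problem in $V_m$ and solves it
self-consistently — that is what the written-out equation states. Because the
left side of the balance rises monotonically with $V_m$ while the right side
falls, the root is unique; the solver nevertheless scans the bracket for
multiple sign changes and records a `branch_note` if any appear, selecting
the root continuous with the previous (higher-$G$) solution during sweeps.

A frozen-kinetic-energy mode (`kinetic_vm = 0.073` or any fixed value)
evaluates the tunneling term at a fixed potential instead, because published
depolarization curves cannot distinguish the two conventions; the two modes
agree wherever the quantum term is small.

Sign convention: $V_m$ is the *magnitude* of the inside-negative potential
(0.073 V at rest, falling toward 0 as the membrane depolarizes). If the
quantum drive at $V_m = 0$ already exceeds the balance, the membrane is
reported as fully depolarized at the 0 V boundary with a flag rather than a
reversed potential.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| $G$ | J | swept $4\to1\times10^{-20}$ | potential-of-mean-force studies place the closed-gate barrier at order $10^{-20}$ J; membrane damage lowers it |
| $L$ | m | $1\times10^{-10}$, set {0.5, 1, 1.5, 2}×10⁻¹⁰ | one hydrophobic residue ≈ 1.5 Å; the set spans one-to-few residues |
| $n$ | – | 1 (set 1–4) | activation gates sit intracellularly ($n=1$); inactivation gates sit deeper |
| $D$ | /cm² | $10^{10}$ (= $10^2$/μm²) | typical voltage-gated channel density |
| $MC_K, MC_{Na}$ | mS/cm² | 0.5, 0.01 | resting leak ratio 100:2 of the basolateral membrane |
| concentrations | mmol/L | [K] 5/120, [Na] 140/15, [Ca] 1.4/0 | perilymph vs cytoplasm |
| $V_m^{(Thr)}$ | V | 0.055 | firing threshold, read as the absolute depolarized potential (0.073 → 0.055 V) |
| axon $r$, length | μm | 0.5, 100 | thin demyelinated fibre; surface 314 μm², $V_E$ = 52.6 μm³ at ratio 0.67 |
| $N_{AP}$ | ions | $1.37\times10^6$ | K⁺ efflux per action potential over 314 μm² |

Ion masses: $m_{Na} = 3.8\times10^{-26}$ kg; for K⁺ and Ca²⁺ no value is
conventional in this model's sources, so the bare atomic masses
$m_K = 6.5\times10^{-26}$ kg (39 u) and $m_{Ca} = 6.64\times10^{-26}$ kg
(40 u) are the defaults — whether hydrated or bare masses are intended is
genuinely open, and `ion_species()` accepts any mass. The bundled constants
are the rounded conventional values; note $h = 6.6\times10^{-34}$ and
$\hbar = 1.05\times10^{-34}$ J s are mutually inconsistent in the fourth
digit — both are kept as given, each used where the corresponding formula
uses it, so worked examples reproduce exactly.

## Numerical choices

* **Everything in log space.** Tunneling probabilities reach $e^{-100}$ and
  far below; both transmission forms are computed as log-transmissions
  (`log = TRUE` exposes them), using
  $\cosh a - 1 = 2\sinh^2(a/2)$ and
  $\cosh a + \cosh b = 2\cosh\frac{a+b}{2}\cosh\frac{a-b}{2}$ with stable
  `log(cosh)`/`log(sinh)` helpers, so no argument ever overflows.
* **Over-barrier clamp.** The exponential form exceeds 1 when $E_K \ge G$;
  `transmission_approx()` clamps to 1 there (it is a probability). The exact
  form remains available for the true over-barrier value.
* **The $-1$ under the barrier square root** (in $b$) is negligible for
  ionic masses at gate dimensions and is dropped by default;
  `drop_minus_one = FALSE` restores it for sensitivity analysis (only
  defined when $8mGL^2/\hbar^2 \ge 1$).
* **Root finding.** Bracketed scalar search on $[0, V_{max}]$ with
  $V_{max} = \max(0.12\ \mathrm{V},\ V_m^{classical} + 0.05)$ — the quantum
  terms only deepen the extracellular drive, so the root cannot exceed the
  classical potential by more than the intracellular quantum term allows.
  A 24-point scan detects sign changes, then Brent refinement
  (`uniroot`, tolerance $10^{-15}$ V, ≤ 200 iterations) polishes the root;
  converged residuals are below $10^{-9}$ in the balance's natural units
  (mS/cm² × mmol/L) and are reported, with non-convergence flagged rather
  than silently returned.
* **Cascade stability.** The $P_1/P_2/P_3$ complements are accumulated with
  `log1p`/`expm1`, stable down to $T_Q \sim 10^{-300}$; the closed-form
  identity $1-P_3 = (1-T_Q)^{N_K D N}$ holds to relative $10^{-10}$.
  $N_K$ is rounded to the nearest integer for use as a trial count (43.6 →
  44); the unrounded ratio is preserved.
* **Determinism.** The model has no stochastic component — the Bernoulli
  cascade is evaluated analytically — so no seeds are involved anywhere, and
  sweep CSVs (10 significant digits, scientific notation) are byte-identical
  across runs.

## The sweeps, and what they do and do not show

`sweep_barrier_height()` solves $V_m(G)$ on a descending 50-point grid from
$4$ to $1\times10^{-20}$ J for Na⁺, K⁺ and Ca²⁺, one curve per gate length
$L \in \{0.5, 1, 1.5, 2\}\times10^{-10}$ m or gate location
$n \in \{1,2,3,4\}$; `sweep_induction()` computes $P_3(G)$ over the same
grid for curve families in $L$, $V_m$, $N_K$, $D$ and $N$. Base synapse
settings: $L = 10^{-10}$ m, $V_m = 0.07$ V, $N_K = 100$, $D = 100$/μm²,
$N = 100$; the $V_m$ entering the kinetic energy in these sweeps is the
fixed base (or swept) value — $V_m$ is an independent axis there, not a
solved quantity. The curve-family values for $V_m$
({0.055, 0.06, 0.065, 0.07} V, resting to threshold) and for $N_K$, $D$, $N$
(decade steps around each base value) are this package's choices, spanning
the physiologically interesting range of each multiplier.

These sweeps are *shape* claims, and the test suite checks them as such:
$V_m(G)$ is non-increasing as $G$ falls for every ion, $L$ and $n$; calcium
depolarizes at higher $G$ than sodium or potassium (its doubled charge
harvests twice the kinetic energy, outweighing its larger mass); larger $L$
or deeper gate location delays the onset to lower $G$; $P_3(G)$ is
non-decreasing as $G$ falls and monotone in every cascade multiplier. No
published numeric axis values exist to pin the curves pointwise, so passing
tests demonstrate correct curve ordering and monotonicity — not agreement
with any measured depolarization, and nothing about real cochlear membranes,
where the barrier shape is only approximately an Eckart profile and the
leak parameters vary from cell to cell.

## A worked chain

```{r worked}
classical_vm()$Vm                        # resting potential, 0.073 V

geom <- axon_geometry()
cyl <- cylinder_geometry(geom)
unlist(cyl)                              # 314 um2, 78.5 / 52.6 um3

kap <- k_release_concentration(geom$N_AP_total, cyl$extra_volume)
signif(kap, 2)                           # 4.3e-2 mmol/L per action potential

nk <- ions_per_channel(geom$N_AP_total / cyl$surface_area,
                       geom$channel_density_Dum2)
nk$N_K                                   # 44 ions strike one closed channel

thr <- threshold_tunneling(signif(kap, 2))
thr                                      # T_Q(Thr) ~ 2.26e-5; coefficient ~ 9.7e-7

1 / nk$N_K > thr$T_Q_thr                 # one tunneled ion out of 44 suffices
```

The threshold chain re-derivation lands within ~1% of the conventionally
quoted 9.64×10⁻⁷ and 2.24×10⁻⁵ — the residual is intermediate rounding in
the quoted values, which cannot be reconstructed exactly;
`validate_model()` records every such comparison with its tolerance.

## Known limitations

* Steady-state only: no Hodgkin–Huxley gating dynamics, no time course of
  depolarization, no K⁺ diffusion or clearance in the periaxonal space.
* The symmetric Eckart profile underestimates transmission through the
  asymmetric barriers seen in potential-of-mean-force calculations; barrier
  shape is not computed from structure.
* One tunneling ion species per membrane solve (per-ion curves); combined
  multi-ion quantum terms are outside the model as formulated.
* The divalent balance omits the intracellular quantum term by default
  ($H_2 = 0$, free intracellular Ca²⁺ being negligible), and the threshold
  balance omits the intracellular quantum term as formulated — both
  omissions are conservative since $T_Q^{(I)} \ll T_Q^{(E)}$.
* The ephaptic narrative (what $P_3$ means for an auditory pathway) is not
  modelled; the package computes the probabilities, not their perceptual
  consequences.
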