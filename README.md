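# iontunnel

Steady-state biophysics of ion permeation through **closed** voltage-gated
channels by quantum tunneling, for computational neuroscientists and channel
biophysicists who want the full chain — barrier transmission → single-channel
conductance → membrane potential → ephaptic signaling probability — as tested,
composable functions.

The closed gate is modelled as a symmetric Eckart barrier
U(x) = G sech²(x/L). An ion of mass m and kinetic energy E_K tunnels through
it with probability

    T_Q = (cosh a − 1) / (cosh a + cosh b),
    a = 2πL√(2mE_K)/ħ,   b = 4π²L√(2mG)/h,

which in the deep-tunneling regime collapses to
T_Q ≈ exp[−(2π√(2m)/ħ)·L·(√G − √E_K)]. Extracellular ions arrive with
E_K = qVm/n + (3/2)k_BT (the gate-location index n = 1–4 sets the fraction
of the membrane potential that accelerates them); intracellular ions carry
thermal energy only. Each channel then conducts C_Q = (q²/h)·T_Q, a membrane
with channel density D conducts MC_Q = C_Q·D, and that quantum conductance
enters the Goldman–Hodgkin–Katz balance of the inner-hair-cell basolateral
membrane, which is solved self-consistently for |Vm| (monovalent and
divalent forms). A separate "quantum synapse" module propagates the same T_Q
through the Bernoulli cascade P1/P2/P3 giving the probability that potassium
released by one action potential induces an action potential in an adjacent
demyelinated axon.

All probabilities are computed in log space (stable down to T_Q ~ 1e-300);
the model is fully deterministic.

## Worked example

```r
library(iontunnel)

classical_vm()$Vm
#> [1] 0.07304594        # resting basolateral potential, V (inside negative)

# lower the gate barrier to 1.5e-20 J: sodium tunneling depolarizes the cell
sc <- quantum_scenario(ion("Na"), eckart_barrier(1.5e-20, 1e-10), 1e10)
quantum_vm(sc)
#> Vm = 0.034200 V (absolute value, inside negative)
#>   residual = 8.53e-14

# quantum synapse: 1.37e6 K+ ions per action potential on a 0.5 x 100 um axon
geom <- axon_geometry(); cyl <- cylinder_geometry(geom)
kap  <- k_release_concentration(geom$N_AP_total, cyl$extra_volume)
signif(kap, 2)
#> [1] 0.043             # mmol/L rise in periaxonal K+
nk <- ions_per_channel(geom$N_AP_total / cyl$surface_area, 100)$N_K
nk
#> [1] 44                # K+ ions striking one closed channel
threshold_tunneling(signif(kap, 2))$T_Q_thr
#> [1] 2.258301e-05      # tunneling fraction needed to reach the firing threshold
induction_probability(1 / nk, N_K = nk, D_um2 = 1, N_um2 = 1)
#> AP induction: P1 = 0.635894 (channel), P2 = 0.635894 (1-um2 patch), P3 = 0.635894 (area)
```

One tunneled ion in 44 (a fraction 2.27e-2) comfortably exceeds the
threshold fraction 2.26e-5, which is why a single channel can fire the
neighbouring fibre. `validate_model()` prints the full worked-example
report; `sweep_barrier_height()` and `sweep_induction()` generate the
depolarization and induction curve families (see the vignette for their
shapes and what they do and do not establish).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/iontunnel validate
Rscript inst/cli/iontunnel reproduce vm_gate_length --out vm_L.csv
Rscript inst/cli/iontunnel make-scenarios --dir scenarios
```

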