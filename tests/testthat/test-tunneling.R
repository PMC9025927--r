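# Eckart-barrier transmission and the conductance chain.

test_that("eckart_potential has the sech^2 profile", {
  b <- eckart_barrier(height_G = 2e-20, gate_length_L = 1e-10)
  expect_equal(eckart_potential(0, b), 2e-20)
  # the potential falls to 0.42 G at |x| = L
  expect_equal(eckart_potential(1e-10, b) / 2e-20, 1 / cosh(1)^2)
  expect_equal(round(eckart_potential(1e-10, b) / 2e-20, 2), 0.42)
  # even in x, vanishing in the tails
  xs <- c(0.3, 0.9, 2.4) * 1e-10
  expect_equal(eckart_potential(xs, b), eckart_potential(-xs, b))
  b1 <- eckart_barrier(1e-20, 1e-10)
  expect_lt(eckart_potential(10e-10, b1), 1e-27)
  expect_error(eckart_potential(1e-10, eckart_barrier(1e-20, 0)),
               "undefined")
})

test_that("kinetic energy splits by membrane side and gate location", {
  const <- physical_constants()
  b <- eckart_barrier(1e-20, 1e-10, gate_location_n = 1L)
  thermal <- kinetic_energy(ion("Na"), "intracellular", constants = const)
  # (3/2) k_B T at 310 K
  expect_equal(thermal, 1.5 * 1.38e-23 * 310)
  expect_equal(signif(thermal, 3), 6.42e-21)
  extra <- kinetic_energy(ion("Na"), "extracellular", Vm = 0.073, barrier = b)
  expect_equal(extra, 1.6e-19 * 0.073 + thermal)
  expect_equal(signif(extra, 3), 1.81e-20)
  # at Vm = 0 the two sides coincide; otherwise extracellular is larger
  expect_equal(kinetic_energy(ion("K"), "extracellular", 0, b), thermal)
  expect_gt(kinetic_energy(ion("K"), "extracellular", 0.01, b), thermal)
  # the gate-location index divides the available potential
  b2 <- eckart_barrier(1e-20, 1e-10, gate_location_n = 2L)
  expect_equal(kinetic_energy(ion("Na"), "extracellular", 0.073, b2),
               1.6e-19 * 0.073 / 2 + thermal)
  expect_error(kinetic_energy(ion("Na"), "extracellular", -0.01, b),
               "absolute")
})

test_that("exact transmission matches its algebraic limits", {
  na <- ion("Na")
  # vanishing barrier height: T -> tanh^2(pi k L), k = sqrt(2 m E)/hbar
  b <- eckart_barrier(1e-45, 1e-10)
  E <- 6.42e-21
  k <- sqrt(2 * na$mass_m * E) / 1.05e-34
  expect_equal(transmission_exact(na, b, E), tanh(pi * k * 1e-10)^2,
               tolerance = 1e-9)
  # zero kinetic energy cannot transmit
  expect_equal(transmission_exact(na, eckart_barrier(1e-20, 1e-10), 0), 0)
  # bounded in [0, 1] across a wide grid, no overflow anywhere
  for (G in c(1, 2, 4) * 1e-20)
    for (L in c(0.5, 1, 2) * 1e-10)
      for (E in c(0.1, 0.5, 1, 2, 5) * 1e-20) {
        t <- transmission_exact(na, eckart_barrier(G, L), E)
        expect_true(is.finite(t) && t >= 0 && t <= 1)
      }
})

test_that("approximate transmission agrees with the exact form where valid", {
  na <- ion("Na")
  # the large-argument check point: L = 0.5e-10 m, E_K = G = 1e-20 J region
  b <- eckart_barrier(1e-20, 0.5e-10)
  lex <- transmission_exact(na, b, 0.999e-20, log = TRUE)
  lap <- transmission_approx(na, b, 0.999e-20, log = TRUE)
  expect_lt(abs(lex - lap), 1)
  # and across the sub-barrier domain with both cosh arguments >= 3
  set.seed(42)
  n_ok <- 0
  for (i in 1:200) {
    m <- runif(1, 3e-26, 7e-26)
    L <- runif(1, 0.3, 2) * 1e-10
    G <- runif(1, 1, 4) * 1e-20
    E <- runif(1, 0.2, 0.99) * G
    io <- ion_species("X", m, 1, 1, 1)
    bb <- eckart_barrier(G, L)
    a_arg <- 2 * pi * L * sqrt(2 * m * E) / 1.05e-34
    b_arg <- 4 * pi^2 * L * sqrt(2 * m * G) / 6.6e-34
    if (a_arg >= 3 && b_arg >= 3) {
      n_ok <- n_ok + 1
      expect_lt(abs(transmission_exact(io, bb, E, log = TRUE) -
                    transmission_approx(io, bb, E, log = TRUE)), 1)
    }
  }
  expect_gt(n_ok, 100)
  # a warning is emitted when the validity condition fails
  expect_warning(
    transmission_approx(na, eckart_barrier(1e-20, 1e-13), 5e-21),
    "approximation condition")
})

test_that("approximate transmission reproduces worked exponents and clamps", {
  na <- ion("Na")
  b <- eckart_barrier(2e-20, 1e-10)
  # exponent from direct arithmetic with the rounded constants
  expo <- 2 * pi * sqrt(2 * 3.8e-26) / 1.05e-34 * 1e-10 *
    (sqrt(2e-20) - sqrt(6.42e-21))
  expect_equal(signif(expo, 3), 101)
  expect_equal(transmission_approx(na, b, 6.42e-21, log = TRUE), -expo)
  # intracellular potassium at G = 1e-20 J, L = 1e-10 m: ~ e^-43
  lt <- tunneling_probability(ion("K"), eckart_barrier(1e-20, 1e-10),
                              "intracellular", log = TRUE)
  expect_equal(round(-lt), 43)
  # over-barrier and zero-length clamps
  expect_equal(transmission_approx(na, b, 2e-20), 1)
  expect_equal(transmission_approx(na, b, 3e-20), 1)
  expect_equal(transmission_approx(na, eckart_barrier(2e-20, 0), 1e-21), 1)
})

test_that("approximate transmission is monotone in G, L, m and E_K", {
  base <- list(m = 3.8e-26, L = 1e-10, G = 2e-20, E = 6.42e-21)
  lt <- function(m, L, G, E)
    transmission_approx(ion_species("X", m, 1, 1, 1), eckart_barrier(G, L),
                        E, log = TRUE)
  for (f in c(1.25, 1.5, 1.75, 2)) {
    # decreasing in G (sub-barrier), L and m; increasing in E_K
    expect_lt(lt(base$m, base$L, base$G * f, base$E),
              lt(base$m, base$L, base$G, base$E))
    expect_lt(lt(base$m, base$L * f, base$G, base$E),
              lt(base$m, base$L, base$G, base$E))
    expect_lt(lt(base$m * f, base$L, base$G, base$E),
              lt(base$m, base$L, base$G, base$E))
    expect_gt(lt(base$m, base$L, base$G, base$E * f),
              lt(base$m, base$L, base$G, base$E))
  }
})

test_that("tunneling probability favors the extracellular side", {
  b <- eckart_barrier(2e-20, 1e-10)
  for (io in list(ion("Na"), ion("K"), ion("Ca"))) {
    expect_gt(tunneling_probability(io, b, "extracellular", 0.073, log = TRUE),
              tunneling_probability(io, b, "intracellular", log = TRUE))
    expect_equal(tunneling_probability(io, b, "extracellular", 0),
                 tunneling_probability(io, b, "intracellular"))
  }
  # the divalent charge gains more kinetic energy from the same potential
  expect_gt(
    tunneling_probability(ion_species("Ca", 3.8e-26, 2, 1.4, 0), b,
                          "extracellular", 0.073, log = TRUE),
    tunneling_probability(ion("Na"), b, "extracellular", 0.073, log = TRUE))
})

test_that("conductance quanta and areal conversion are exact", {
  # q^2/h: 3.88e-2 mS monovalent, 15.52e-2 mS divalent
  expect_equal(signif(unitary_conductance(ion("Na"), 1) * 1e3, 3), 3.88e-2)
  expect_equal(signif(unitary_conductance(ion("Ca"), 1) * 1e3, 4), 15.52e-2)
  expect_equal(unitary_conductance(ion("K"), 0), 0)
  # linear in T_Q; divalent/monovalent ratio exactly 4 at equal T_Q
  tq <- c(1e-30, 1e-11, 0.5, 1)
  expect_equal(unitary_conductance(ion("Na"), tq),
               tq * unitary_conductance(ion("Na"), 1))
  expect_equal(unitary_conductance(ion("Ca"), tq) /
                 unitary_conductance(ion("Na"), tq), rep(4, length(tq)))
  # MC_Q = C_Q x D with S -> mS; densities per um2 convert at 1e8
  cq <- 3.88e-5 * 1e-11
  expect_equal(membrane_conductance(cq, 1e10), 3.88e-3)
  expect_equal(membrane_conductance(cq, 1e2, "um2"),
               membrane_conductance(cq, 1e10))
  expect_equal(membrane_conductance(cq, 0), 0)
  expect_error(membrane_conductance(cq, -1), ">= 0")
  expect_error(unitary_conductance(ion("Na"), 1.2), "\\[0, 1\\]")
})
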