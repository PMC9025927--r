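# Potassium-release geometry, threshold tunneling and the induction cascade.

test_that("cylinder geometry reproduces the release compartment", {
  cyl <- cylinder_geometry(axon_geometry())
  expect_equal(signif(cyl$surface_area, 3), 314)
  expect_equal(signif(cyl$intra_volume, 3), 78.5)
  expect_equal(signif(cyl$extra_volume, 3), 52.6)
  # scaling laws: doubling r doubles the surface and quadruples the volume
  big <- cylinder_geometry(axon_geometry(radius_r = 1))
  expect_equal(big$surface_area, 2 * cyl$surface_area)
  expect_equal(big$intra_volume, 4 * cyl$intra_volume)
})

test_that("potassium concentration rise follows N/(N_A V)", {
  expect_equal(signif(k_release_concentration(1.37e6, 52.6), 2), 4.3e-2)
  expect_equal(k_release_concentration(0, 52.6), 0)
  expect_equal(k_release_concentration(1.37e6, 2 * 52.6),
               k_release_concentration(1.37e6, 52.6) / 2)
  expect_error(k_release_concentration(1e6, 0), "> 0")
  # direct arithmetic oracle: mol / (N_A * litres), in mmol/L
  expect_equal(k_release_concentration(1.37e6, 52.6),
               1.37e6 / (6.02e23 * 52.6e-15) * 1e3)
})

test_that("ions per channel is the areal density ratio, rounded for trials", {
  r <- ions_per_channel(1.37e6 / (2 * pi * 0.5 * 100), 100)
  expect_equal(r$N_K, 44L)
  expect_equal(signif(r$ratio, 3), 43.6)
  expect_equal(ions_per_channel(1e3, 10)$N_K, 100L)
  expect_equal(ions_per_channel(0, 10)$N_K, 0L)
  expect_error(ions_per_channel(1e3, 0), "> 0")
})

test_that("threshold tunneling inverts the GHK balance at Vm(Thr)", {
  thr <- threshold_tunneling(4.3e-2)
  # closed-form re-derivation as the oracle
  cFRT <- 96485.33 / (8.31 * 310)
  drive <- exp(-cFRT * 0.055) * 60.15 - 3.9
  coef <- drive / ((1.6e-19)^2 / 6.6e-34 * 1e3 * 1e8)
  expect_equal(thr$coefficient, coef)
  expect_equal(thr$T_Q_thr, coef / 4.3e-2)
  # conventionally quoted values are matched within 2%
  expect_lt(abs(thr$coefficient - 9.64e-7) / 9.64e-7, 0.02)
  expect_lt(abs(thr$T_Q_thr - 2.24e-5) / 2.24e-5, 0.02)
  # inverse proportionality: the coefficient is invariant in [K]_AP
  for (kap in c(1e-3, 4.3e-2, 0.086, 1)) {
    t2 <- threshold_tunneling(kap)
    expect_equal(t2$coefficient, coef)
    expect_equal(t2$T_Q_thr * kap, coef)
  }
  expect_equal(threshold_tunneling(2 * 4.3e-2)$T_Q_thr, thr$T_Q_thr / 2)
  # a threshold below the resting drive is rejected
  expect_error(threshold_tunneling(4.3e-2, Vm_threshold = 0.08),
               "resting drive")
  # the minimum achievable fraction with 44 ions exceeds the threshold
  expect_gt(1 / 44, thr$T_Q_thr)
})

test_that("binomial mass matches brute-force enumeration", {
  # exhaustive enumeration over all 2^N outcomes, N <= 12
  enum_pmf <- function(N, Z, P) {
    if (N == 0) return(as.numeric(Z == 0))
    hits <- rowSums(as.matrix(expand.grid(rep(list(0:1), N))))
    sum(ifelse(hits == Z, P^hits * (1 - P)^(N - hits), 0))
  }
  set.seed(11)
  for (N in c(0L, 1L, 4L, 7L, 12L)) {
    P <- runif(1)
    for (Z in 0:N)
      expect_equal(bernoulli_pmf(N, Z, P), enum_pmf(N, Z, P),
                   tolerance = 1e-12)
  }
  expect_equal(bernoulli_pmf(4, 2, 0.5), 6 / 16)
  # P(0) = (1 - P)^N and normalization
  expect_equal(bernoulli_pmf(10, 0, 0.3), 0.7^10)
  expect_equal(sum(bernoulli_pmf(9, 0:9, 0.42)), 1)
  expect_error(bernoulli_pmf(3, 4, 0.5), "exceed")
})

test_that("induction cascade equals its closed form and is ordered", {
  # 1 - P3 = (1 - T_Q)^(N_K * D * N), relative 1e-10, down to T_Q = 1e-300
  tq_grid <- 10^seq(-300, 0, length.out = 61)
  tq_grid[length(tq_grid)] <- 1
  for (tq in tq_grid) {
    pr <- induction_probability(tq, N_K = 44, D_um2 = 100, N_um2 = 100)
    p3_closed <- -expm1(44 * 100 * 100 * log1p(-tq))
    expect_equal(pr$P3, p3_closed, tolerance = 1e-10)
    expect_true(pr$P1 <= pr$P2 + 1e-15 && pr$P2 <= pr$P3 + 1e-15)
    expect_true(pr$P1 >= 0 && pr$P3 <= 1)
  }
  # small-probability limit: P3 = N_K D N T_Q within 0.1%
  for (tq in c(1e-12, 1e-9, 1e-8)) {
    pr <- induction_probability(tq, 10, 10, 1)
    expect_equal(pr$P3, 100 * tq, tolerance = 1e-3)
  }
  # degenerate ends
  expect_equal(unlist(induction_probability(0, 44, 100, 100)),
               c(P1 = 0, P2 = 0, P3 = 0))
  expect_equal(unlist(induction_probability(1, 44, 100, 100)),
               c(P1 = 1, P2 = 1, P3 = 1))
  # worked single-channel example: 1 - (1 - 1/44)^44 ~ 0.636
  pr <- induction_probability(2.27e-2, 44, 1, 1)
  expect_equal(signif(pr$P1, 3), 0.636)
  expect_equal(pr$P3, pr$P1)
})

test_that("patch count is the area in square microns", {
  expect_equal(area_patch_count(100), 100)
  expect_equal(area_patch_count(0), 0)
  expect_error(area_patch_count(-1), ">= 0")
})
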