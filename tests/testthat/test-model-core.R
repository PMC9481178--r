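p_std <- kai_params(N = 1)

test_that("structure drive reproduces closed-form field values", {
  pB_free <- c(1, rep(0, 6))
  # all coupling terms vanish: D = 1/2, F = 0 at q_mean chosen so F = 0
  expect_equal(structure_drive(0, pB_free, D = 0.5, q_mean = 0.5, X = 0.5,
                               p_std), 2)
  # fully phosphorylated, all-ADP, X = 1: d0 - d3 - d4
  expect_equal(structure_drive(0, pB_free, D = 1, q_mean = 1, X = 1, p_std),
               2 - 3 - 2)
  # fully dephosphorylated, all-ATP, X = 0: d0 + d3 + d4
  expect_equal(structure_drive(0, pB_free, D = 0, q_mean = 0, X = 0, p_std),
               2 + 3 + 2)
  # KaiA binding adds d1*pA, KaiB binding subtracts d2*P(bound)
  pB_one <- c(0.4, 0.6, rep(0, 5))
  expect_equal(structure_drive(0.2, pB_one, 0.5, 0.5, 0.5, p_std),
               2 + 5 * 0.2 - 5 * 0.6)
})

test_that("structure order parameter is the tanh quasi-equilibrium", {
  expect_equal(structure_update(0), 0.5)
  expect_equal(structure_update(2), 0.5 * (1 + tanh(2)))
  expect_gt(structure_update(50), 1 - 1e-10)
  expect_lt(structure_update(-50), 1e-10)
  # beta scales with absolute temperature: same R gives smaller |X - 1/2|
  # when hotter
  expect_lt(structure_update(1, T_c = 45), structure_update(1, T_c = 30))
  # antisymmetry X(R) + X(-R) = 1, at reference and shifted temperature
  for (R in seq(-6, 6, by = 0.37)) {
    expect_equal(structure_update(R) + structure_update(-R), 1,
                 tolerance = 1e-12)
    expect_equal(structure_update(R, 40) + structure_update(-R, 40), 1,
                 tolerance = 1e-12)
  }
  expect_true(all(diff(structure_update(seq(-4, 4, by = 0.1))) > 0))
})

test_that("CII KaiA occupancy follows the quasi-equilibrium split", {
  expect_equal(kaiA_cii_equilibrium(0, 0.7, p_std)$pA, 0)
  eq <- kaiA_cii_equilibrium(1, 0.5, p_std)
  expect_equal(eq$hA, p_std$hA0)
  expect_equal(eq$fA, p_std$fA0)
  expect_equal(eq$g, 5e-4)
  expect_equal(kaiA_cii_equilibrium(1, 1, p_std)$hA,
               p_std$hA0 * (1 + tanh(1)))
  # occupancy saturates in xA and scales with the KaiB-free probability
  eq2 <- kaiA_cii_equilibrium(1e9, 0.5, p_std, pB0 = 0.8)
  expect_equal(eq2$pA, 0.8, tolerance = 1e-4)
  # X -> 1 guard: unbinding rate hits zero, occupancy stays defined
  eqg <- kaiA_cii_equilibrium(1, 1 + 1e-16, p_std)
  expect_true(is.finite(eqg$pA) && eqg$pA <= 1)
})

test_that("KaiA-on-KaiB saturation is the binding isotherm", {
  expect_equal(kaiA_on_kaiB_alpha(0, p_std), 0)
  g <- p_std$hAB / p_std$fAB
  expect_equal(kaiA_on_kaiB_alpha(1 / g, p_std), 0.5)
  expect_lt(kaiA_on_kaiB_alpha(1e12, p_std), 1)
})

test_that("KaiB ring chain conserves mass and relaxes to the binomial law", {
  pB <- c(1, rep(0, 6))
  # no free KaiB and nothing bound: stationary
  expect_equal(kaiB_ring_step(pB, xB = 0, X = 0.5, p_std), pB)
  # X = 1/2 rates are the bare constants
  r <- kaiB_rates(0.5, p_std)
  expect_equal(r$hB, p_std$hB0)
  expect_equal(r$fB, p_std$fB0)
  # probability conservation per step at machine precision
  set.seed(1)
  pB <- runif(7)
  pB <- pB / sum(pB)
  for (i in 1:50) {
    pB <- kaiB_ring_step(pB, xB = 4000, X = 0.2, p_std, dt = 1e-3)
    expect_lt(abs(sum(pB) - 1), 1e-12)
  }
  # long-run stationary law equals Binomial(6, hB xB/(hB xB + fB)):
  # independent-oracle closed form from detailed balance of the chain
  X <- 0.3
  xB <- 3000
  r <- kaiB_rates(X, p_std)
  p_site <- r$hB * xB / (r$hB * xB + r$fB)
  oracle <- dbinom(0:6, 6, p_site)
  pB <- c(1, rep(0, 6))
  for (i in seq_len(30000)) pB <- kaiB_ring_step(pB, xB, X, p_std, dt = 1e-3)
  expect_lt(max(abs(pB - oracle)), 1e-6)
  # gross step-size violation is detected
  expect_error(kaiB_ring_step(c(0, 1, rep(0, 5)), xB = 0, X = 0, p_std,
                              dt = 10), "instability")
})

test_that("phosphorylation step has the stated limits and fixed point", {
  # no CII KaiA: pure dephosphorylation at rate kdp
  expect_equal(phospho_step(0.5, 0, p_std, dt = 1e-3),
               0.5 - 1e-3 * p_std$kdp * 0.5)
  # saturated KaiA: pure phosphorylation toward 1
  expect_equal(phospho_step(0.5, 1e9, p_std, dt = 1e-3),
               0.5 + 1e-3 * p_std$kp * 0.5, tolerance = 1e-6)
  # z = 1 with kp = kdp: relaxes to D* = 1/2 (balance of H+ and H-)
  D <- 0.9
  for (i in seq_len(60000)) D <- phospho_step(D, p_std$P0, p_std, dt = 1e-3)
  expect_equal(D, 0.5, tolerance = 1e-4)
  # bounded for admissible steps
  expect_true(phospho_step(1, 1e9, p_std, dt = 0.9 / p_std$kp) <= 1)
})

test_that("ADP lifetime tracks the structure", {
  expect_equal(adp_lifetime(0.5, p_std), p_std$dADP0)
  expect_equal(adp_lifetime(1, p_std), p_std$dADP0 * (1 - tanh(0.5)))
  expect_equal(adp_lifetime(0, p_std), p_std$dADP0 * (1 + tanh(0.5)))
  X <- seq(0, 1, by = 0.05)
  expect_true(all(diff(adp_lifetime(X, p_std)) < 0))
})

test_that("nucleotide flips have the prescribed hazards", {
  set.seed(42)
  p0 <- kai_params(N = 1, f_hyd = 0)
  q <- rep(0L, 6)
  for (i in 1:200) {
    st <- atpase_step(q, 0.5, p0)
    expect_equal(st$q, q) # no hydrolysis ever
  }
  pInf <- kai_params(N = 1, dADP0 = Inf)
  q <- rep(1L, 6)
  st <- atpase_step(q, 0.5, pInf)
  expect_equal(st$q, q) # ADP never released
  # alternating renewal: long-run ADP occupancy = Delta/(Delta + 1/f_hyd);
  # with Delta = 1/f_hyd at X = 1/2 this is 1/2 (closed form)
  set.seed(7)
  q <- rep(0L, 6)
  occ <- 0
  n <- 40000
  for (i in seq_len(n)) {
    q <- atpase_step(q, 0.5, p_std, dt = 5e-3)$q
    occ <- occ + mean(q)
  }
  # ~ 240 renewal cycles per domain; MC s.e. about 0.01
  expect_equal(occ / n, 0.5, tolerance = 0.04)
})
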