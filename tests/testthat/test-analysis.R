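test_that("period and amplitude are recovered from a pure sinusoid", {
  d <- make_sinusoid(period = 24, amplitude_half = 0.3, t_max = 240)
  s <- period_amplitude(d)
  expect_true(s$oscillatory)
  expect_equal(s$period, 24, tolerance = 0.02)
  expect_equal(s$amplitude, 0.6, tolerance = 0.02)
  expect_equal(s$n_cycles, 9)
})

test_that("flat and short traces are reported as non-oscillatory", {
  d <- data.frame(t = seq(0, 200, 0.1), D_mean = 0.5)
  expect_false(period_amplitude(d)$oscillatory)
  expect_error(period_amplitude(data.frame(t = 1:3, D_mean = 1:3)),
               "too short")
})

test_that("saw-tooth vertex times are recovered exactly", {
  pk <- c(20, 45, 70, 95, 120)
  tr <- c(10, 32, 57, 82, 107, 130)
  d <- make_sawtooth(pk, tr)
  s <- period_amplitude(d, smooth_h = 0)
  expect_equal(s$peak_times, pk, tolerance = 0.11)
  expect_equal(s$period, 25, tolerance = 0.01)
  expect_equal(s$amplitude, 0.6, tolerance = 1e-6)
})

test_that("summary is invariant under time shift and mild observation noise", {
  set.seed(5)
  base <- make_sinusoid(period = 22, amplitude_half = 0.25, t_max = 220)
  s0 <- period_amplitude(base)
  shifted <- base
  shifted$t <- shifted$t + 500
  s1 <- period_amplitude(shifted)
  expect_equal(s1$period, s0$period, tolerance = 1e-9)
  expect_equal(s1$amplitude, s0$amplitude, tolerance = 1e-9)
  noisy <- base
  noisy$D_mean <- noisy$D_mean + rnorm(nrow(noisy), sd = 1e-3)
  s2 <- period_amplitude(noisy)
  expect_equal(s2$period, s0$period, tolerance = 0.02)
  expect_equal(s2$amplitude, s0$amplitude, tolerance = 0.02)
})

test_that("Q10 ratio is the low/high period quotient", {
  expect_equal(q10_ratio(26, 26), 1)
  # periods following the canonical Arrhenius inverse give the ~1.4 ratio
  P <- function(Tc) 24 / arrhenius_factor(10, Tc)
  expect_equal(q10_ratio(P(25), P(35)),
               arrhenius_factor(10, 35) / arrhenius_factor(10, 25))
  expect_error(q10_ratio(NA, 24), "positive periods")
  expect_error(q10_ratio(24, -1), "positive periods")
})

test_that("circadian time pins the peak at CT 16 and wraps the cycle", {
  d <- make_sinusoid(period = 24, t_max = 240, phase = 0)
  ctm <- circadian_time_map(period_amplitude(d))
  pk <- ctm$peak_times[2]
  expect_equal(ctm$ct_of_time(pk), 16, tolerance = 1e-6)
  expect_equal(ctm$ct_of_time(pk + 12), 4, tolerance = 0.01)
  expect_equal(ctm$ct_of_time(pk + 6), 22, tolerance = 0.01)
  # inverse mapping lands on the requested circadian time
  for (ct in c(0, 5, 16, 23)) {
    expect_equal(ctm$ct_of_time(ctm$time_of_ct(ct, cycle = 2)), ct,
                 tolerance = 0.01)
  }
  expect_error(circadian_time_map(
    period_amplitude(data.frame(t = seq(0, 200, 0.1), D_mean = 0.5))),
    "non-oscillatory")
})

test_that("phase shift is signed, wrapped and antisymmetric", {
  ref <- make_sinusoid(period = 24, t_max = 240)
  expect_equal(phase_shift(ref, ref), 0)
  # perturbed rhythm 2 h late = 2 CT h delay (negative)
  late <- make_sinusoid(period = 24, t_max = 240, phase = 2)
  expect_equal(phase_shift(late, ref, after = 48), -2, tolerance = 0.05)
  early <- make_sinusoid(period = 24, t_max = 240, phase = -3)
  expect_equal(phase_shift(early, ref, after = 48), 3, tolerance = 0.05)
  expect_equal(phase_shift(late, ref, after = 48),
               -phase_shift(ref, late, after = 48), tolerance = 1e-6)
  # half-period shift wraps to +12 by convention
  anti <- make_sinusoid(period = 24, t_max = 240, phase = 12)
  expect_equal(abs(phase_shift(anti, ref, after = 48)), 12, tolerance = 0.05)
  flat <- data.frame(t = seq(0, 240, 0.1), D_mean = 0.5)
  expect_warning(sh <- phase_shift(flat, ref), "rhythm lost")
  expect_true(is.na(sh))
})

test_that("synchrony index separates coherent from incoherent ensembles", {
  t <- seq(0, 240, 0.1)
  coherent <- do.call(rbind, lapply(1:20, function(m) {
    data.frame(t = t, molecule = m, D = 0.5 + 0.3 * sin(2 * pi * t / 24))
  }))
  ens <- data.frame(t = t,
                    D_mean = tapply(coherent$D, coherent$t, mean)[
                      as.character(t)])
  ens$D_mean <- 0.5 + 0.3 * sin(2 * pi * t / 24)
  si <- sync_index(coherent, ens)
  expect_equal(si$index, 1, tolerance = 1e-9)
  set.seed(2)
  phases <- runif(40, 0, 24)
  incoh <- do.call(rbind, lapply(seq_along(phases), function(m) {
    data.frame(t = t, molecule = m,
               D = 0.5 + 0.3 * sin(2 * pi * (t - phases[m]) / 24))
  }))
  Dm <- rowMeans(sapply(seq_along(phases), function(m) {
    0.5 + 0.3 * sin(2 * pi * (t - phases[m]) / 24)
  }))
  si2 <- sync_index(incoh, data.frame(t = t, D_mean = Dm))
  expect_lt(si2$index, 0.35)
  # finite sampling of shifted sinusoids moves the quantile range slightly
  expect_equal(si2$molecule_amplitude_mean, si$molecule_amplitude_mean,
               tolerance = 0.01)
})

test_that("tidy and glance summarize cycles", {
  d <- make_sinusoid(period = 24, amplitude_half = 0.3, t_max = 240)
  s <- period_amplitude(d)
  td <- tidy(s)
  expect_true(all(c("cycle", "peak_time", "trough_time", "period",
                    "amplitude") %in% names(td)))
  expect_equal(nrow(td), length(s$peak_times))
  expect_equal(mean(td$period, na.rm = TRUE), 24, tolerance = 0.05)
  g <- glance(s)
  expect_equal(nrow(g), 1)
  expect_true(g$oscillatory)
})
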