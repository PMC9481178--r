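# synthetic oscillation fixtures with known period/amplitude/peak times

make_sinusoid <- function(period = 24, amplitude_half = 0.3, mean = 0.5,
                          t_max = 240, stride = 0.1, phase = 0,
                          col = "D_mean") {
  t <- seq(0, t_max, by = stride)
  out <- data.frame(t = t)
  out[[col]] <- mean + amplitude_half * sin(2 * pi * (t - phase) / period)
  out
}

# piecewise-linear saw-tooth with vertices at known times
make_sawtooth <- function(peak_times, trough_times, peak = 0.8, trough = 0.2,
                          stride = 0.1, col = "D_mean") {
  verts <- rbind(data.frame(t = peak_times, v = peak),
                 data.frame(t = trough_times, v = trough))
  verts <- verts[order(verts$t), ]
  t <- seq(min(verts$t), max(verts$t), by = stride)
  out <- data.frame(t = t)
  out[[col]] <- approx(verts$t, verts$v, xout = t)$y
  out
}

# small standard parameter set used across simulation tests
tiny_params <- function(N = 40, ...) kai_params(N = N, ...)

# direct kernel call on a hand-built single-hexamer state
kernel_once <- function(params, thermo = kai_thermo(), state, n_steps = 1L,
                        record_every = n_steps) {
  kaiabc:::kai_kernel(state, kaiabc:::kernel_pars(params, thermo),
                      as.integer(n_steps), as.integer(record_every),
                      integer(0))
}
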