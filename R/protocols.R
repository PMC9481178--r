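#' Feedback-strength scaling scan
#'
#' Rescales chosen structural couplings by a factor `s` and measures the
#' resulting period and amplitude: `mode = "neg"` scales the time-delayed
#' negative feedback (`d3`) together with the ATPase coupling (`d4`),
#' `"pos"` the binding positive feedback (`d1`, `d2`), and `"d3_only"` /
#' `"d4_only"` a single coupling. Each scan point runs an independent
#' simulation with a seed derived from `seed` and the scanned value, so
#' results do not depend on scan order.
#'
#' @param params Base [kai_params()].
#' @param mode Which couplings to scale.
#' @param s_values Positive scale factors.
#' @param thermo [kai_thermo()] (default: reference temperature).
#' @param seed Master seed.
#' @param duration,warmup Simulation lengths (h).
#' @param ... Passed to [period_amplitude()].
#' @return A tibble of class `kai_scan`: one row per `s` with `period`,
#'   `period_se`, `amplitude`, `n_cycles`, `oscillatory`, and `X_end` (mean
#'   structure over the last recorded 24 h, identifying arrest at X ~ 1).
#' @export
scan_feedback <- function(params, mode = c("neg", "pos", "d3_only", "d4_only"),
                          s_values, thermo = kai_thermo(),
                          seed = 1, duration = 360, warmup = 100, ...) {
  mode <- match.arg(mode)
  stopifnot(all(s_values > 0))
  rows <- purrr::map(s_values, function(s) {
    p <- unclass(params)
    if (mode %in% c("neg", "d3_only")) p$d3 <- p$d3 * s
    if (mode %in% c("neg", "d4_only")) p$d4 <- p$d4 * s
    if (mode == "pos") {
      p$d1 <- p$d1 * s
      p$d2 <- p$d2 * s
    }
    p <- structure(p, class = "kai_params")
    traj <- simulate_ensemble(p, thermo, duration = duration, warmup = warmup,
                              seed = derive_seed(seed, round(s * 1e4)))
    sm <- period_amplitude(traj, ...)
    tail24 <- traj$X_mean[traj$t > max(traj$t) - 24]
    tibble::tibble(s = s, period = sm$period, period_se = sm$period_se,
                   amplitude = sm$amplitude, n_cycles = sm$n_cycles,
                   oscillatory = sm$oscillatory, X_end = mean(tail24))
  })
  structure(dplyr::bind_rows(rows),
            class = c("kai_scan", "tbl_df", "tbl", "data.frame"),
            scan_var = "s", mode = mode)
}

#' Temperature scan of period and amplitude
#'
#' Simulates the ensemble at each temperature under a common rule set and
#' summarizes the rhythm. When the scan covers `T0 - 5` and `T0 + 5`, the Q10
#' of the period is attached.
#'
#' @param params Base [kai_params()] (defined at `T0`).
#' @param T_values Temperatures in degrees C.
#' @param thermo Template [kai_thermo()]; its `T_c` is replaced per point.
#' @param seed Master seed.
#' @param n_reps Replicate simulations per temperature (periods averaged).
#' @param duration,warmup Simulation lengths (h).
#' @param ... Passed to [period_amplitude()].
#' @return A `kai_scan` tibble with one row per temperature; attribute `q10`
#'   when both `T0 +/- 5` are present and oscillatory.
#' @export
scan_temperature <- function(params, T_values, thermo = kai_case("A"),
                             seed = 1, n_reps = 1,
                             duration = 360, warmup = 100, ...) {
  rows <- purrr::map(T_values, function(Tc) {
    th <- thermo
    th$T_c <- Tc
    periods <- numeric(0)
    amps <- numeric(0)
    osc <- logical(0)
    ncyc <- 0L
    for (r in seq_len(n_reps)) {
      traj <- simulate_ensemble(params, th, duration = duration,
                                warmup = warmup,
                                seed = derive_seed(seed,
                                                   round(Tc * 100) * 100 + r))
      sm <- period_amplitude(traj, ...)
      periods <- c(periods, sm$period)
      amps <- c(amps, sm$amplitude)
      osc <- c(osc, sm$oscillatory)
      ncyc <- ncyc + sm$n_cycles
    }
    tibble::tibble(T_c = Tc,
                   period = mean(periods), period_se = stats::sd(periods) /
                     sqrt(max(1, length(periods))),
                   amplitude = mean(amps), n_cycles = ncyc,
                   oscillatory = all(osc))
  })
  out <- dplyr::bind_rows(rows)
  q10 <- NA_real_
  lo <- which(abs(out$T_c - (thermo$T0_c - 5)) < 1e-9)
  hi <- which(abs(out$T_c - (thermo$T0_c + 5)) < 1e-9)
  if (length(lo) == 1 && length(hi) == 1 &&
      out$oscillatory[lo] && out$oscillatory[hi]) {
    q10 <- q10_ratio(out$period[lo], out$period[hi])
  }
  structure(out, class = c("kai_scan", "tbl_df", "tbl", "data.frame"),
            scan_var = "T_c", q10 = q10)
}

#' Q10 of the simulated rhythm under a rule set
#'
#' Convenience wrapper around [scan_temperature()] at exactly `T0 - 5` and
#' `T0 + 5` degrees C.
#'
#' @inheritParams scan_temperature
#' @return A list with `q10`, `period_low`, `period_high`, and the scan
#'   tibble.
#' @export
kai_q10 <- function(params, thermo = kai_case("A"), seed = 1, n_reps = 2,
                    duration = 360, warmup = 100, ...) {
  sc <- scan_temperature(params,
                         T_values = c(thermo$T0_c - 5, thermo$T0_c + 5),
                         thermo = thermo, seed = seed, n_reps = n_reps,
                         duration = duration, warmup = warmup, ...)
  list(q10 = attr(sc, "q10"),
       period_low = sc$period[1], period_high = sc$period[2], scan = sc)
}

#' Phase-response curve to a temperature step
#'
#' For each circadian-time onset, a trajectory stepped from `T_from` to
#' `T_to` is compared against the constant-`T_from` reference run with the
#' same seed (identical random stream, so the two rhythms coincide exactly
#' until the step). The onset CT is read off the reference rhythm (peak =
#' CT 16, cycle = 24 h). Because the stepped rhythm settles into the target
#' temperature's own period, a raw peak-time difference would drift by the
#' period mismatch every cycle; instead each rhythm's post-step peak grid
#' is projected back to the onset with its own period, and the shift is the
#' wrapped difference of the two phases in CT hours, advance positive —
#' the same per-temperature cycle normalization used to define CT.
#'
#' @param params Base [kai_params()].
#' @param thermo Rule set template; `T_c` is set to `T_from` / `T_to`.
#' @param T_from,T_to Step temperatures (degrees C).
#' @param ct_grid Onset circadian times (default every 2 h over one cycle).
#' @param anchor_cycle Which reference inter-peak interval carries the onsets.
#' @param seed Master seed.
#' @param duration,warmup Simulation lengths (h).
#' @param settle Hours skipped after the step before matching peaks.
#' @return A tibble of class `kai_prc`: `ct`, `onset_h`, `shift_ct_h`,
#'   `desynchronized`.
#' @export
tstep_prc <- function(params, thermo = kai_case("A"), T_from = 30, T_to = 45,
                      ct_grid = seq(0, 22, by = 2), anchor_cycle = 3,
                      seed = 1, duration = 360, warmup = 100, settle = 24) {
  th_from <- thermo
  th_from$T_c <- T_from
  ref <- simulate_ensemble(params, th_from, duration = duration,
                           warmup = warmup, seed = seed)
  sref <- period_amplitude(ref)
  if (!sref$oscillatory) stop("reference rhythm is non-oscillatory",
                              call. = FALSE)
  ctm <- circadian_time_map(sref)
  # phase of a rhythm at `at`, in cycle fraction until its next peak,
  # taken from the post-settle peak grid projected back with its own period
  phase_at <- function(sm, at, skip) {
    pk <- sm$peak_times[sm$peak_times > at + skip]
    if (length(pk) < 2) return(NULL)
    P <- mean(diff(pk))
    list(frac = ((pk[1] - at) / P) %% 1, period = P)
  }
  rows <- purrr::map(ct_grid, function(ct) {
    onset <- ctm$time_of_ct(ct, cycle = anchor_cycle)
    pert <- simulate_ensemble(
      params, th_from, duration = duration, warmup = warmup, seed = seed,
      events = list(kai_event("temperature_step", time = onset, T_to = T_to)))
    sp <- period_amplitude(pert)
    sh <- NA_real_
    if (sp$oscillatory) {
      pr <- phase_at(sref, onset, settle)
      pp <- phase_at(sp, onset, settle)
      if (!is.null(pr) && !is.null(pp)) {
        d <- (pr$frac - pp$frac) %% 1  # perturbed peak sooner => advance
        if (d > 0.5) d <- d - 1
        sh <- 24 * d
      }
    }
    tibble::tibble(ct = ct, onset_h = onset, shift_ct_h = sh,
                   desynchronized = !sp$oscillatory)
  })
  structure(dplyr::bind_rows(rows),
            class = c("kai_prc", "tbl_df", "tbl", "data.frame"),
            kind = "temperature_step", T_from = T_from, T_to = T_to,
            reference_period = sref$period)
}

#' Phase-response curve to an ADP pulse
#'
#' Emulates a transient rise in the ADP/ATP ratio by multiplying the ADP
#' lifetime scale `dADP0` by `multiplier` for `pulse_h` hours, starting at
#' each circadian-time onset. The post-pulse ensemble amplitude relative to
#' the unperturbed rhythm flags desynchronization.
#'
#' @inheritParams tstep_prc
#' @param multiplier Lifetime multiplier during the pulse (default 4).
#' @param pulse_h Pulse duration in hours (default 6).
#' @param desync_frac Post-pulse amplitude fraction below which the ensemble
#'   counts as desynchronized (default 0.5).
#' @return A `kai_prc` tibble: `ct`, `onset_h`, `shift_ct_h`,
#'   `amplitude_after`, `amplitude_ratio`, `desynchronized`.
#' @export
adp_pulse_prc <- function(params, thermo = kai_thermo(), multiplier = 4,
                          pulse_h = 6, ct_grid = seq(0, 22, by = 2),
                          anchor_cycle = 3, seed = 1, duration = 360,
                          warmup = 100, settle = 24, desync_frac = 0.5) {
  stopifnot(multiplier > 0)
  ref <- simulate_ensemble(params, thermo, duration = duration,
                           warmup = warmup, seed = seed)
  sref <- period_amplitude(ref)
  if (!sref$oscillatory) stop("reference rhythm is non-oscillatory",
                              call. = FALSE)
  ctm <- circadian_time_map(sref)
  rows <- purrr::map(ct_grid, function(ct) {
    onset <- ctm$time_of_ct(ct, cycle = anchor_cycle)
    pert <- simulate_ensemble(
      params, thermo, duration = duration, warmup = warmup, seed = seed,
      events = list(kai_event("adp_pulse", time = onset,
                              multiplier = multiplier, duration = pulse_h)))
    late <- pert[pert$t > onset + pulse_h + settle, , drop = FALSE]
    sp <- period_amplitude(late)
    amp_ratio <- if (is.finite(sp$amplitude)) sp$amplitude / sref$amplitude
                 else 0
    sh <- suppressWarnings(
      phase_shift(sp, sref, after = onset + pulse_h, settle = 0,
                  reference_period = sref$period))
    tibble::tibble(ct = ct, onset_h = onset, shift_ct_h = sh,
                   amplitude_after = sp$amplitude,
                   amplitude_ratio = amp_ratio,
                   desynchronized = !sp$oscillatory ||
                     amp_ratio < desync_frac)
  })
  structure(dplyr::bind_rows(rows),
            class = c("kai_prc", "tbl_df", "tbl", "data.frame"),
            kind = "adp_pulse", multiplier = multiplier, pulse_h = pulse_h,
            reference_period = sref$period)
}

#' ATPase rate scaling scan
#'
#' Scales the CI ATPase rate constants by `sa` in two ways: case `"I"`
#' multiplies both the inverse ADP lifetime `1/dADP0` and the hydrolysis
#' frequency `f_hyd` by `sa` (preserving the product `Delta_ADP * f_hyd`, and
#' with it the stationary ADP occupancy); case `"II"` multiplies `dADP0` and
#' `f_hyd` by `sa`, breaking the constraint. The ATPase activity at each
#' point is measured in the non-oscillatory condition without KaiA and KaiB.
#'
#' @param params Base [kai_params()].
#' @param case `"I"` or `"II"`.
#' @param sa_values Positive scale factors.
#' @param thermo [kai_thermo()].
#' @param seed Master seed.
#' @param duration,warmup Simulation lengths (h).
#' @return A `kai_scan` tibble: `sa`, `period`, `amplitude`, `oscillatory`,
#'   `frequency` (1/period), `atpase_activity` (ADP released per CI domain
#'   per day, KaiA/KaiB-free).
#' @export
scan_atpase <- function(params, case = c("I", "II"), sa_values,
                        thermo = kai_thermo(), seed = 1,
                        duration = 360, warmup = 100) {
  case <- match.arg(case)
  stopifnot(all(sa_values > 0))
  rows <- purrr::map(sa_values, function(sa) {
    p <- unclass(params)
    if (case == "I") {
      p$dADP0 <- p$dADP0 / sa   # 1/dADP0 -> sa/dADP0
      p$f_hyd <- p$f_hyd * sa
    } else {
      p$dADP0 <- p$dADP0 * sa
      p$f_hyd <- p$f_hyd * sa
    }
    p <- structure(p, class = "kai_params")
    traj <- simulate_ensemble(p, thermo, duration = duration,
                              warmup = warmup,
                              seed = derive_seed(seed, round(sa * 1e4)))
    sm <- period_amplitude(traj)
    act <- atpase_activity(p, thermo,
                           seed = derive_seed(seed, round(sa * 1e4) + 1))
    tibble::tibble(sa = sa, period = sm$period, amplitude = sm$amplitude,
                   oscillatory = sm$oscillatory,
                   frequency = ifelse(sm$oscillatory, 1 / sm$period,
                                      NA_real_),
                   atpase_activity = act)
  })
  structure(dplyr::bind_rows(rows),
            class = c("kai_scan", "tbl_df", "tbl", "data.frame"),
            scan_var = "sa", case = case)
}

#' ATPase activity in the absence of KaiA and KaiB
#'
#' Simulates the ensemble with total KaiA and KaiB set to zero (the
#' non-oscillatory free-KaiC condition) and returns the steady-state ADP
#' release rate per CI domain per day.
#'
#' @param params Base [kai_params()].
#' @param thermo [kai_thermo()].
#' @param seed Seed.
#' @param duration Production length (h) over which the rate is averaged.
#' @param warmup Discarded relaxation (h).
#' @return Released ADP per CI domain per day.
#' @export
atpase_activity <- function(params, thermo = kai_thermo(), seed = 1,
                            duration = 48, warmup = 24) {
  p <- unclass(params)
  p$AT2 <- 0
  p$BT <- 0
  p <- structure(p, class = "kai_params")
  traj <- simulate_ensemble(p, thermo, duration = duration, warmup = warmup,
                            seed = seed)
  mean(traj$qr) * 24
}

#' Desynchronization assay: weakened KaiA sequestration
#'
#' Reduces the KaiA-on-KaiB binding rate `hAB` by `hAB_factor` and compares
#' the ensemble rhythm with single-molecule rhythms at each temperature.
#' With strongly reduced `hAB` the sequestration coupling fails: the
#' ensemble-mean oscillation collapses while individual hexamers keep
#' oscillating at full amplitude.
#'
#' @param params Base [kai_params()].
#' @param hAB_factor Multiplier in `(0, 1]` applied to `hAB`.
#' @param temperatures Temperatures (degrees C) to assay.
#' @param thermo Rule-set template.
#' @param seed Master seed.
#' @param n_track Number of tracked molecules (default 20).
#' @param duration,warmup Simulation lengths (h).
#' @param mol_prominence Peak prominence used on single-molecule traces.
#' @return A tibble: one row per temperature with `sync_index`,
#'   `ensemble_amplitude`, `molecule_amplitude`, `molecule_period` (mean
#'   single-molecule period, h), `ensemble_oscillatory`.
#' @export
desync_assay <- function(params, hAB_factor = 1, temperatures = 30,
                         thermo = kai_thermo(), seed = 1, n_track = 20,
                         duration = 360, warmup = 100,
                         mol_prominence = 0.2) {
  stopifnot(hAB_factor > 0, hAB_factor <= 1)
  p <- unclass(params)
  p$hAB <- p$hAB * hAB_factor
  p <- structure(p, class = "kai_params")
  rows <- purrr::imap(temperatures, function(Tc, i) {
    th <- thermo
    th$T_c <- Tc
    traj <- simulate_ensemble(p, th, duration = duration, warmup = warmup,
                              seed = derive_seed(seed, i), n_track = n_track)
    si <- sync_index(traj)
    sm <- period_amplitude(traj)
    mol <- molecule_traces(traj)
    mp <- vapply(split(mol, mol$molecule), function(m) {
      s <- period_amplitude(m, col = "D", min_prominence = mol_prominence,
                            smooth_h = 2)
      if (s$oscillatory) s$period else NA_real_
    }, numeric(1))
    tibble::tibble(T_c = Tc, hAB_factor = hAB_factor,
                   sync_index = si$index,
                   ensemble_amplitude = si$ensemble_amplitude,
                   molecule_amplitude = si$molecule_amplitude_mean,
                   molecule_period = mean(mp, na.rm = TRUE),
                   ensemble_oscillatory = sm$oscillatory)
  })
  dplyr::bind_rows(rows)
}
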