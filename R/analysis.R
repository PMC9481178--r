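#' Period and amplitude of an oscillatory trajectory
#'
#' Detects peaks and troughs on a lightly smoothed copy of the signal
#' (moving average, default 1 h window) and prunes turning points until every
#' adjacent peak-trough difference exceeds `min_prominence`. The period is
#' the mean inter-peak interval, the amplitude the mean peak-to-trough drop.
#' A trajectory is declared non-oscillatory when fewer than `min_peaks`
#' qualifying peaks remain or the amplitude falls below `amp_floor`.
#'
#' @param traj A `kai_trajectory`, or any data frame with a time column `t`
#'   and the value column named by `col`.
#' @param col Column to analyze (default `"D_mean"`).
#' @param min_prominence Minimum peak-to-adjacent-trough difference.
#' @param smooth_h Moving-average window in hours (0 disables smoothing).
#' @param min_peaks Minimum number of qualifying peaks.
#' @param amp_floor Amplitude below which the signal counts as flat.
#' @return An object of class `kai_summary`: a list with `period`,
#'   `period_se`, `amplitude`, `n_cycles`, `peak_times`, `trough_times`,
#'   `peak_values`, `trough_values`, `oscillatory`.
#' @examples
#' t <- seq(0, 240, by = 0.1)
#' d <- data.frame(t = t, D_mean = 0.5 + 0.3 * sin(2 * pi * t / 24))
#' period_amplitude(d)$period  # 24
#' @export
period_amplitude <- function(traj, col = "D_mean", min_prominence = 0.02,
                             smooth_h = 1, min_peaks = 3, amp_floor = 0.02) {
  t <- traj$t
  y <- traj[[col]]
  if (is.null(y)) stop("column '", col, "' not found", call. = FALSE)
  if (length(t) < 10) stop("trajectory too short", call. = FALSE)
  stride <- stats::median(diff(t))

  ys <- y
  if (smooth_h > 0) {
    k <- max(1L, as.integer(round(smooth_h / stride)))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && k < length(y)) {
      ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
      pad <- (k - 1L) %/% 2L
      ys[seq_len(pad)] <- ys[pad + 1L]
      ys[(length(ys) - pad + 1L):length(ys)] <- ys[length(ys) - pad]
    }
  }

  tp <- turning_points(t, ys)
  tp <- prune_turning_points(tp, min_prominence)
  peaks <- tp[tp$kind == "max", , drop = FALSE]
  troughs <- tp[tp$kind == "min", , drop = FALSE]

  res <- list(period = NA_real_, period_se = NA_real_,
              amplitude = NA_real_, n_cycles = 0L,
              peak_times = peaks$t, trough_times = troughs$t,
              peak_values = peaks$v, trough_values = troughs$v,
              oscillatory = FALSE)
  if (nrow(peaks) >= 2) {
    iv <- diff(peaks$t)
    res$period <- mean(iv)
    res$period_se <- if (length(iv) > 1) stats::sd(iv) / sqrt(length(iv))
                     else NA_real_
    res$n_cycles <- length(iv)
    # mean drop from each peak to the following trough
    drops <- vapply(seq_len(nrow(peaks)), function(i) {
      nxt <- troughs$t > peaks$t[i]
      if (any(nxt)) peaks$v[i] - troughs$v[which(nxt)[1]] else NA_real_
    }, numeric(1))
    res$amplitude <- mean(drops, na.rm = TRUE)
    res$oscillatory <- nrow(peaks) >= min_peaks &&
      is.finite(res$amplitude) && res$amplitude >= amp_floor
  }
  class(res) <- "kai_summary"
  res
}

# strictly alternating local extrema of a series (plateaus take their center)
turning_points <- function(t, y) {
  d <- diff(y)
  s <- sign(d)
  nz <- s != 0
  # collapse flat runs: carry last nonzero slope
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  idx <- which(diff(s_f) != 0) + 1L
  kind <- ifelse(s_f[idx - 1L] > 0, "max", "min")
  data.frame(t = t[idx], v = y[idx], kind = kind,
             stringsAsFactors = FALSE)
}

# iteratively drop the smallest adjacent peak-trough wiggle until all
# remaining adjacent differences reach the prominence threshold
prune_turning_points <- function(tp, min_prominence) {
  while (nrow(tp) >= 2) {
    dv <- abs(diff(tp$v))
    j <- which.min(dv)
    if (dv[j] >= min_prominence) break
    tp <- tp[-c(j, j + 1L), , drop = FALSE]
    # merging can leave same-kind neighbours; keep the more extreme one
    repeat {
      same <- which(diff(match(tp$kind, c("min", "max"))) == 0)
      if (!length(same)) break
      i <- same[1]
      drop_i <- if (tp$kind[i] == "max") {
        if (tp$v[i] >= tp$v[i + 1]) i + 1L else i
      } else {
        if (tp$v[i] <= tp$v[i + 1]) i + 1L else i
      }
      tp <- tp[-drop_i, , drop = FALSE]
    }
  }
  tp
}

#' @export
print.kai_summary <- function(x, ...) {
  if (x$oscillatory) {
    cat(sprintf(
      "<kai_summary> oscillatory: period %.2f h (se %.3f), amplitude %.3f, %d cycles\n",
      x$period, x$period_se, x$amplitude, x$n_cycles))
  } else {
    cat("<kai_summary> non-oscillatory\n")
  }
  invisible(x)
}

#' Temperature coefficient of the oscillation period
#'
#' `Q10 = period(T0 - 5) / period(T0 + 5)`: the ratio of periods measured
#' 10 degrees C apart. 1 means perfect temperature compensation.
#'
#' @param period_low Period at the lower temperature (h).
#' @param period_high Period at the higher temperature (h).
#' @return Dimensionless ratio.
#' @export
q10_ratio <- function(period_low, period_high) {
  if (!is.finite(period_low) || !is.finite(period_high) ||
      period_low <= 0 || period_high <= 0) {
    stop("Q10 needs positive periods at both temperatures", call. = FALSE)
  }
  period_low / period_high
}

#' Circadian-time mapping of a rhythm
#'
#' Maps incubation time to circadian time (CT) with the rhythm's peak pinned
#' at CT 16 and each cycle normalized to 24 h (piecewise-affine between
#' consecutive peaks; the mean period extrapolates beyond the first/last
#' peak).
#'
#' @param summary A `kai_summary` from [period_amplitude()] (or a
#'   `kai_trajectory`, which is summarized first).
#' @return A list with functions `ct_of_time(t)` and `time_of_ct(ct, cycle)`;
#'   `cycle` indexes the inter-peak interval used as the reference
#'   (1 = between the first two detected peaks).
#' @export
circadian_time_map <- function(summary) {
  if (inherits(summary, "kai_trajectory")) summary <- period_amplitude(summary)
  if (!summary$oscillatory) stop("non-oscillatory trajectory", call. = FALSE)
  pk <- summary$peak_times
  P <- summary$period
  ct_of_time <- function(t) {
    vapply(t, function(ti) {
      i <- findInterval(ti, pk)
      if (i == 0) {
        (16 + 24 * (ti - pk[1]) / P) %% 24
      } else if (i >= length(pk)) {
        (16 + 24 * (ti - pk[length(pk)]) / P) %% 24
      } else {
        (16 + 24 * (ti - pk[i]) / (pk[i + 1] - pk[i])) %% 24
      }
    }, numeric(1))
  }
  time_of_ct <- function(ct, cycle = 1) {
    if (cycle < 1 || cycle >= length(pk)) stop("cycle out of range",
                                               call. = FALSE)
    pk[cycle] + ((ct - 16) %% 24) / 24 * (pk[cycle + 1] - pk[cycle])
  }
  list(ct_of_time = ct_of_time, time_of_ct = time_of_ct,
       peak_times = pk, period = P)
}

#' Phase shift between a perturbed and a reference rhythm
#'
#' Mean difference of matched post-perturbation peak times, converted to
#' circadian-time hours (advance positive: the perturbed rhythm peaks
#' earlier), wrapped to `(-12, 12]`.
#'
#' @param perturbed,reference `kai_trajectory` objects (or `kai_summary`).
#' @param after Only peaks later than this time are compared (h).
#' @param n_peaks Number of post-perturbation peaks averaged (default 3).
#' @param reference_period Period used for the CT conversion; defaults to the
#'   reference rhythm's.
#' @param settle Skip this many hours after `after` before matching peaks
#'   (default 0), allowing amplitude transients to decay.
#' @return Phase shift in CT hours, or `NA` (with a warning) when either
#'   rhythm is non-oscillatory after the perturbation.
#' @export
phase_shift <- function(perturbed, reference, after = 0, n_peaks = 3,
                        reference_period = NULL, settle = 0) {
  sp <- if (inherits(perturbed, "kai_summary")) perturbed
        else period_amplitude(perturbed)
  sr <- if (inherits(reference, "kai_summary")) reference
        else period_amplitude(reference)
  if (!sp$oscillatory || !sr$oscillatory) {
    warning("phase shift undefined: rhythm lost after perturbation")
    return(NA_real_)
  }
  P <- if (is.null(reference_period)) sr$period else reference_period
  pk_p <- sp$peak_times[sp$peak_times > after + settle]
  pk_r <- sr$peak_times
  if (length(pk_p) < 1) {
    warning("no post-perturbation peaks")
    return(NA_real_)
  }
  pk_p <- utils::head(pk_p, n_peaks)
  d <- vapply(pk_p, function(tp) {
    dd <- pk_r - tp
    dd <- ((dd + P / 2) %% P) - P / 2  # nearest reference peak, mod period
    dd[which.min(abs(dd))]
  }, numeric(1))
  shift <- mean(d) * 24 / P
  ((shift + 12) %% 24) - 12 -> w
  if (w == -12) 12 else w
}

#' Synchrony index of an ensemble
#'
#' Ratio of the ensemble-mean oscillation amplitude to the mean
#' single-molecule amplitude. Both are measured as the robust range
#' (5th-95th percentile) of the phosphorylation signal, which stays defined
#' when the ensemble mean is flat. Near 1 for phase-locked molecules; near 0
#' when molecules oscillate incoherently.
#'
#' @param traj A `kai_trajectory` recorded with `n_track > 0`, or a
#'   molecules tibble (columns `t`, `molecule`, `D`) plus `ensemble` data.
#' @param ensemble Optional data frame with `t`, `D_mean` when `traj` is a
#'   molecules tibble.
#' @return A list with `index`, `ensemble_amplitude`,
#'   `molecule_amplitude_mean`.
#' @export
sync_index <- function(traj, ensemble = NULL) {
  if (inherits(traj, "kai_trajectory")) {
    mol <- molecule_traces(traj)
    ens <- traj
  } else {
    mol <- traj
    ens <- ensemble
    if (is.null(ens)) stop("ensemble data required", call. = FALSE)
  }
  rng <- function(v) diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))
  amp_e <- rng(ens$D_mean)
  amps <- vapply(split(mol$D, mol$molecule), rng, numeric(1))
  if (all(amps == 0)) stop("no oscillatory molecules", call. = FALSE)
  list(index = amp_e / mean(amps),
       ensemble_amplitude = amp_e,
       molecule_amplitude_mean = mean(amps))
}
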