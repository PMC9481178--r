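#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cycle tidy summary of an oscillation
#'
#' One row per detected cycle: peak time and value, the following trough,
#' the cycle's peak-to-peak period and peak-to-trough amplitude.
#'
#' @param x A `kai_summary` from [period_amplitude()].
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `peak_time`, `peak_value`,
#'   `trough_time`, `trough_value`, `period`, `amplitude`.
#' @exportS3Method generics::tidy
#' @export
tidy.kai_summary <- function(x, ...) {
  np <- length(x$peak_times)
  if (np == 0) {
    return(tibble::tibble(cycle = integer(0), peak_time = numeric(0),
                          peak_value = numeric(0), trough_time = numeric(0),
                          trough_value = numeric(0), period = numeric(0),
                          amplitude = numeric(0)))
  }
  tt <- vapply(seq_len(np), function(i) {
    nxt <- x$trough_times > x$peak_times[i]
    if (any(nxt)) x$trough_times[which(nxt)[1]] else NA_real_
  }, numeric(1))
  tv <- vapply(seq_len(np), function(i) {
    nxt <- x$trough_times > x$peak_times[i]
    if (any(nxt)) x$trough_values[which(nxt)[1]] else NA_real_
  }, numeric(1))
  tibble::tibble(
    cycle = seq_len(np),
    peak_time = x$peak_times,
    peak_value = x$peak_values,
    trough_time = tt,
    trough_value = tv,
    period = c(diff(x$peak_times), NA_real_),
    amplitude = x$peak_values - tv
  )
}

#' One-row summary of an oscillation
#'
#' @param x A `kai_summary`.
#' @param ... Unused.
#' @return A one-row tibble with `period`, `period_se`, `amplitude`,
#'   `n_cycles`, `oscillatory`.
#' @exportS3Method generics::glance
#' @export
glance.kai_summary <- function(x, ...) {
  tibble::tibble(period = x$period, period_se = x$period_se,
                 amplitude = x$amplitude, n_cycles = x$n_cycles,
                 oscillatory = x$oscillatory)
}
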