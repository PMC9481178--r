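#' Structural coupling field of a KaiC hexamer
#'
#' The quasi-equilibrium field `R` (in kB*T0 units) acting on the two-state
#' structural order parameter:
#' `R = d0 + d1*pA - d2*B - d3*(2D - 1) - d4*(q_mean*X - (1 - q_mean)*(1 - X))`,
#' where `B` is the probability that at least one KaiB monomer is bound
#' (or the full binding-state sum when `d2_includes_free` was set) and `X` is
#' the order parameter from the previous step (explicit lag).
#'
#' @param pA Probability that the CII binds a KaiA dimer.
#' @param pB Length-7 probability vector over the number of bound KaiB
#'   monomers (index 1 = none bound).
#' @param D Phosphorylation level in `[0, 1]`.
#' @param q_mean Mean ADP occupancy of the six CI domains in `[0, 1]`.
#' @param X Structure order parameter from the previous step.
#' @param params A [kai_params()] object (supplies `d0..d4`).
#' @return Field `R` in kB*T0 units.
#' @examples
#' p <- kai_params(N = 1)
#' structure_drive(0, c(1, rep(0, 6)), D = 0.5, q_mean = 0.5, X = 0.5, p)
#' @export
structure_drive <- function(pA, pB, D, q_mean, X, params) {
  stopifnot(length(pB) == 7, q_mean >= 0, q_mean <= 1)
  bsum <- if (isTRUE(params$include_pB0)) sum(pB) else sum(pB[-1])
  Fq <- q_mean * X - (1 - q_mean) * (1 - X)
  params$d0 + params$d1 * pA - params$d2 * bsum -
    params$d3 * (2 * D - 1) - params$d4 * Fq
}

#' Quasi-equilibrium structure order parameter
#'
#' `X = (1 + tanh(beta*R)) / 2` with `beta = 1/(kB*T)`; since `R` is expressed
#' in kB*T0 units, `beta*R = R * T0[K]/T[K]`.
#'
#' @param R Field in kB*T0 units.
#' @param T_c,T0_c Temperature and reference temperature (degrees C).
#' @return `X` in `(0, 1)`.
#' @examples
#' structure_update(0)    # 0.5
#' structure_update(2)    # ~0.982 at T = T0
#' @export
structure_update <- function(R, T_c = 30, T0_c = 30) {
  0.5 * (1 + tanh(R * (T0_c + 273.15) / (T_c + 273.15)))
}

#' KaiA binding on the CII ring (quasi-equilibrium)
#'
#' The CII KaiA binding/unbinding is fast, so the bound probability is the
#' equilibrium split of the KaiB-free state:
#' `pA = pB0 * xA*g / (1 + xA*g)` with `g = hA/fA`,
#' `hA = hA0*(1 + tanh((2X-1)/A_X))`, `fA = fA0*(1 - tanh((2X-1)/A_X))`.
#'
#' @param xA Free KaiA dimer concentration.
#' @param X Structure order parameter.
#' @param params A [kai_params()] object.
#' @param pB0 Probability of the KaiB-free state (default 1).
#' @return List with `pA`, `hA`, `fA`, `g`.
#' @export
kaiA_cii_equilibrium <- function(xA, X, params, pB0 = 1) {
  stopifnot(xA >= 0)
  tX <- tanh((2 * X - 1) / params$A_X)
  hA <- params$hA0 * (1 + tX)
  fA <- params$fA0 * (1 - tX)
  g <- if (fA > 0) hA / fA else Inf
  list(pA = pB0 * xA * g / (1 + xA * g), hA = hA, fA = fA, g = g)
}

#' KaiA saturation on CI-bound KaiB
#'
#' Each CI-bound KaiB monomer independently binds a KaiA dimer with
#' quasi-equilibrium occupancy `alpha = xA*g / (1 + xA*g)`, `g = hAB/fAB`.
#' Full complex probabilities are the binomial split
#' `C(i, j) alpha^j (1 - alpha)^(i - j)` of each KaiB occupancy class and
#' never need to be stored.
#'
#' @param xA Free KaiA dimer concentration.
#' @param params A [kai_params()] object.
#' @return `alpha` in `[0, 1)`.
#' @export
kaiA_on_kaiB_alpha <- function(xA, params) {
  stopifnot(xA >= 0)
  g <- params$hAB / params$fAB
  xA * g / (1 + xA * g)
}

#' Structure-dependent KaiB binding/unbinding rates
#'
#' @param X Structure order parameter.
#' @param params A [kai_params()] object.
#' @return List with `hB` (binding, 1/h per site) and `fB` (unbinding, 1/h).
#' @export
kaiB_rates <- function(X, params) {
  tB <- tanh((2 * X - 1) / params$B_X)
  list(hB = params$hB0 * (1 - tB), fB = params$fB0 * (1 + tB))
}

#' One Euler step of the KaiB ring occupancy chain
#'
#' Explicit Euler update of the 7-state birth-death chain over the number of
#' CI-bound KaiB monomers: binding at rate `(6-i)*hB*xB` out of state `i`,
#' unbinding at rate `i*fB`. Probability mass is conserved exactly by the
#' scheme; tiny negative excursions (< 1e-9) are clipped and renormalized,
#' larger ones abort as a step-size error.
#'
#' @param pB Length-7 probability vector (must sum to 1).
#' @param xB Free KaiB monomer concentration.
#' @param X Structure order parameter (sets `hB`, `fB`).
#' @param params A [kai_params()] object.
#' @param dt Step size (h); defaults to `params$dt`.
#' @return Updated length-7 probability vector.
#' @export
kaiB_ring_step <- function(pB, xB, X, params, dt = params$dt) {
  stopifnot(length(pB) == 7, xB >= 0)
  r <- kaiB_rates(X, params)
  i <- 0:6
  gain_bind <- c(0, (7 - i[-1]) * r$hB * xB * pB[-7])   # from i-1
  gain_unb  <- c((i[-1]) * r$fB * pB[-1], 0)            # from i+1
  loss      <- ((6 - i) * r$hB * xB + i * r$fB) * pB
  out <- pB + dt * (gain_bind + gain_unb - loss)
  if (any(out < 0)) {
    if (any(out < -1e-9)) {
      stop("kaiB_ring_step: step-size instability (pB < -1e-9)", call. = FALSE)
    }
    out[out < 0] <- 0
    out <- out / sum(out)
  }
  out
}

#' One Euler step of the phosphorylation level
#'
#' `dD/dt = kp*H+*(1 - D) - kdp*H-*D` with `H+ = z/(1+z)`, `H- = 1/(1+z)`,
#' `z = pA/P0`: CII-bound KaiA tips the balance toward phosphorylation.
#'
#' @param D Phosphorylation level in `[0, 1]`.
#' @param pA CII KaiA-bound probability.
#' @param params A [kai_params()] object.
#' @param dt Step size (h); defaults to `params$dt`.
#' @return Updated `D` in `[0, 1]`.
#' @export
phospho_step <- function(D, pA, params, dt = params$dt) {
  stopifnot(D >= 0, D <= 1)
  z <- pA / params$P0
  Hp <- z / (1 + z)
  Hm <- 1 / (1 + z)
  out <- D + dt * (params$kp * Hp * (1 - D) - params$kdp * Hm * D)
  pmin(pmax(out, 0), 1)
}

#' Structure-dependent lifetime of the ADP-bound CI state
#'
#' `Delta_ADP = dADP0 * (1 - tanh((2X - 1)/C_X))`: the ADP-bound state is
#' short-lived in the X ~ 1 (phosphorylating) structure and long-lived in the
#' X ~ 0 structure.
#'
#' @param X Structure order parameter.
#' @param params A [kai_params()] object.
#' @return Mean lifetime in hours.
#' @export
adp_lifetime <- function(X, params) {
  params$dADP0 * (1 - tanh((2 * X - 1) / params$C_X))
}

#' One stochastic step of the CI nucleotide states of a single hexamer
#'
#' Each ATP-bound domain (`q = 0`) hydrolyzes with probability `f_hyd*dt`;
#' each ADP-bound domain (`q = 1`) releases its ADP (and rebinds ATP) with
#' the memoryless hazard `dt / Delta_ADP(X)`. Lifetimes are therefore
#' exponential with the structure-tracking mean [adp_lifetime()].
#'
#' @param q Integer vector of length 6 with entries in `{0, 1}`.
#' @param X Structure order parameter.
#' @param params A [kai_params()] object.
#' @param dt Step size (h); defaults to `params$dt`.
#' @return List with the updated `q` and `releases`, the number of ADP release
#'   events in this step.
#' @export
atpase_step <- function(q, X, params, dt = params$dt) {
  stopifnot(length(q) == 6, all(q %in% c(0L, 1L)))
  p_hyd <- params$f_hyd * dt
  dl <- adp_lifetime(X, params)
  p_rel <- if (dl > 0) dt / dl else 1
  if (p_hyd >= 1 || p_rel > 1) {
    stop("atpase_step: step size too large for the transition hazards",
         call. = FALSE)
  }
  u <- stats::runif(6)
  was_adp <- q == 1L
  release <- was_adp & u < p_rel
  hydrol <- !was_adp & u < p_hyd
  q[release] <- 0L
  q[hydrol] <- 1L
  list(q = q, releases = sum(release))
}
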