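#' Model parameters for the KaiC hexamer ensemble
#'
#' Builds the full parameter set of the oscillator model. Defaults are the
#' standard values at the reference temperature (30 degrees C): rate constants
#' in 1/h with concentrations in counts per simulation volume V = 1, coupling
#' energies in units of kB*T0, and stoichiometric totals AT/2 = N KaiA dimers,
#' BT = 6N KaiB monomers (monomer ratio AT:BT:CT = 1:3:3).
#'
#' @param N Number of KaiC hexamers in the ensemble.
#' @param hA0,fA0 KaiA dimer binding/unbinding rate scales on the CII ring
#'   (1/h). The effective rates are `hA0*(1 + tanh((2X-1)/A_X))` and
#'   `fA0*(1 - tanh((2X-1)/A_X))`, so KaiA prefers the X ~ 1 structure.
#' @param hB0,fB0 KaiB monomer binding/unbinding rate scales on the CI ring
#'   (1/h); effective rates `hB0*(1 - tanh((2X-1)/B_X))` and
#'   `fB0*(1 + tanh((2X-1)/B_X))`, so KaiB prefers X ~ 0.
#' @param hAB,fAB KaiA dimer binding/unbinding rates on CI-bound KaiB (1/h);
#'   structure-independent.
#' @param kp,kdp Phosphorylation / dephosphorylation rate constants (1/h).
#' @param f_hyd Hydrolysis frequency of CI-bound ATP (1/h).
#' @param dADP0 Lifetime scale of the ADP-bound CI state (h); the
#'   structure-dependent lifetime is `dADP0*(1 - tanh((2X-1)/C_X))`.
#' @param d0,d1,d2,d3,d4 Structural coupling energies (kB*T0): baseline field,
#'   KaiA-binding and KaiB-binding positive feedback, phosphorylation
#'   (delayed negative feedback), and ATPase coupling.
#' @param A_X,B_X,C_X Dimensionless structure sensitivities of KaiA binding,
#'   KaiB binding, and the ADP lifetime.
#' @param P0 Sensitivity of the P/dP reactions to CII-bound KaiA
#'   (dimensionless; `z = pA/P0`).
#' @param AT2 Total KaiA dimers in the simulation volume (default `N`, i.e.
#'   AT:CT = 1:3 on a monomer basis).
#' @param BT Total KaiB monomers in the simulation volume (default `6*N`).
#' @param V Simulation volume in units of the reference volume that holds
#'   1000 hexamers (default `N/1000`), so concentrations — which is what the
#'   rate constants act on — are independent of the ensemble size. `V = 1`
#'   at `N = 1000` corresponds to 3e-15 litres.
#' @param dt Integration step (h).
#' @param adp_scheme ADP release scheme: `"hazard"` (memoryless, exponential
#'   lifetimes with the structure-tracking mean) or `"aging"` (an ADP-bound
#'   domain accumulates age at rate `1/Delta_ADP(X)` and releases when the
#'   age reaches 1, giving sharply peaked lifetimes that still track the
#'   structure).
#' @param x_scheme How the structural quasi-equilibrium is evaluated each
#'   step. The order parameter obeys `X = (1 + tanh(beta*(c - d4*X)))/2`
#'   (X enters its own drive through the ATPase coupling, since
#'   `q*X - (1-q)*(1-X) = X - (1-q)`). `"fixed_point"` (default) solves this
#'   self-consistently — the solution is unique because the right-hand side
#'   decreases in X. `"lagged"` inserts the previous step's X; note this
#'   makes the update an iterated map whose stability is independent of
#'   `dt` and which chatters near transitions once `d4*beta/2 > 1`.
#' @param d2_includes_free If `TRUE`, the KaiB stabilization term `d2` also
#'   counts the KaiB-free state (the literal reading of the coupling-field
#'   sum); the default counts only hexamers with at least one bound KaiB,
#'   which keeps `d2` a pure KaiB-binding effect distinguishable from `d0`.
#'
#' @return An object of class `kai_params` (a named list).
#' @examples
#' p <- kai_params(N = 100)
#' p$kp
#' @export
kai_params <- function(N = 1000,
                       hA0 = 5e-1, fA0 = 1e3,
                       hB0 = 5e-5, fB0 = 2,
                       hAB = 6e-1, fAB = 1e2,
                       kp = 0.18, kdp = 0.18,
                       f_hyd = 1, dADP0 = 1,
                       d0 = 2, d1 = 5, d2 = 5, d3 = 3, d4 = 2,
                       A_X = 1, B_X = 1, C_X = 2, P0 = 0.1,
                       AT2 = N, BT = 6 * N, V = N / 1000, dt = 1e-3,
                       d2_includes_free = FALSE,
                       adp_scheme = c("hazard", "aging"),
                       x_scheme = c("fixed_point", "lagged")) {
  adp_scheme <- match.arg(adp_scheme)
  x_scheme <- match.arg(x_scheme)
  p <- list(N = N, hA0 = hA0, fA0 = fA0, hB0 = hB0, fB0 = fB0,
            hAB = hAB, fAB = fAB, kp = kp, kdp = kdp,
            f_hyd = f_hyd, dADP0 = dADP0,
            d0 = d0, d1 = d1, d2 = d2, d3 = d3, d4 = d4,
            A_X = A_X, B_X = B_X, C_X = C_X, P0 = P0,
            AT2 = AT2, BT = BT, V = V, dt = dt,
            include_pB0 = isTRUE(d2_includes_free),
            adp_scheme = adp_scheme, x_scheme = x_scheme)
  validate_kai_params(p)
  structure(p, class = "kai_params")
}

validate_kai_params <- function(p) {
  rates <- c("hA0", "fA0", "hB0", "fB0", "hAB", "fAB", "kp", "kdp",
             "f_hyd", "dADP0", "AT2", "BT")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (p$N < 1 || p$N != round(p$N)) stop("N must be a positive integer",
                                         call. = FALSE)
  if (p$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p$A_X <= 0 || p$B_X <= 0 || p$C_X <= 0 || p$P0 <= 0) {
    stop("A_X, B_X, C_X and P0 must be positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kai_params <- function(x, ...) {
  cat("<kai_params> N =", x$N, " hexamers, dt =", x$dt, "h\n")
  cat("  rates (1/h): hA0", x$hA0, "fA0", x$fA0, "hB0", x$hB0, "fB0", x$fB0,
      "\n               hAB", x$hAB, "fAB", x$fAB, "kp", x$kp, "kdp", x$kdp,
      "f_hyd", x$f_hyd, "1/dADP0", 1 / x$dADP0, "\n")
  cat("  couplings (kB*T0): d0", x$d0, "d1", x$d1, "d2", x$d2,
      "d3", x$d3, "d4", x$d4, "\n")
  cat("  totals: AT/2 =", x$AT2, "dimers, BT =", x$BT, "monomers\n")
  invisible(x)
}

#' Report model concentrations and dissociation constants in micromolar
#'
#' Converts the simulation's concentration unit (one count per reference
#' volume, 3e-15 l) to molar units: N = 1000 hexamers in V = 1 corresponds
#' to 3.3 uM KaiC on a monomer basis. Dissociation constants are the
#' unbinding/binding rate ratios in the same unit.
#'
#' @param params A [kai_params()] object.
#' @param ref_volume_l Physical volume of the reference simulation volume
#'   (litres).
#' @return A tibble with columns `quantity`, `value_uM`, and `basis`.
#' @examples
#' kai_concentrations(kai_params(N = 1000))
#' @export
kai_concentrations <- function(params, ref_volume_l = 3e-15) {
  stopifnot(inherits(params, "kai_params"))
  count_to_uM <- 1e6 / (ref_volume_l * 6.02214076e23)
  tibble::tibble(
    quantity = c("KaiC_total", "KaiA_total", "KaiB_total",
                 "Kd_C:A", "Kd_C:B", "Kd_CB:A"),
    value_uM = c(6 * params$N / params$V * count_to_uM,
                 2 * params$AT2 / params$V * count_to_uM,
                 params$BT / params$V * count_to_uM,
                 (params$fA0 / params$hA0) * count_to_uM,
                 (params$fB0 / params$hB0) * count_to_uM,
                 (params$fAB / params$hAB) * count_to_uM),
    basis = c("monomer", "monomer", "monomer",
              "KaiA dimer on CII", "KaiB monomer on CI",
              "KaiA dimer on CI-bound KaiB")
  )
}
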