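#' Arrhenius scaling factor
#'
#' `s(dE; T, T0) = exp(-dE/(kB*T) + dE/(kB*T0))` with the activation energy
#' `dE` given in units of `kB*T0`. Equals 1 at `T = T0` and increases with
#' temperature for positive `dE`.
#'
#' @param dE Activation energy in kB*T0 units.
#' @param T_c Temperature in degrees Celsius.
#' @param T0_c Reference temperature in degrees Celsius (default 30).
#' @return Dimensionless scaling factor.
#' @examples
#' arrhenius_factor(10, 35) / arrhenius_factor(10, 25) # ~ 1.39
#' @export
arrhenius_factor <- function(dE, T_c, T0_c = 30) {
  TK <- T_c + 273.15
  T0K <- T0_c + 273.15
  if (any(TK <= 0) || any(T0K <= 0)) stop("temperatures must be above 0 K")
  exp(dE * (1 - T0K / TK))
}

#' Temperature model: Arrhenius scaling plus the three compensation rules
#'
#' Describes how the model parameters depend on temperature. The six generic
#' binding and (de)phosphorylation rate constants always scale with the common
#' activation energy `dE0`. Three optional rules modify the rest:
#'
#' * **Rule 1** (thermal attenuation of the reaction-structure coupling):
#'   `d3` and `d4` are divided by `s(dEf; T, T0)`, so the feedback weakens as
#'   temperature rises.
#' * **Rule 2** (thermally activated KaiB fold switch): `hB0` scales by
#'   `s(dE0)*s(dE_gs_fs)` and `fB0` by `s(dE0)*s(dE_fs_gs_p)`; with the rule
#'   off both scale by `s(dE0)` alone.
#' * **Rule 3** (temperature-insensitive ATPase): `f_hyd` and `1/dADP0` are
#'   held fixed; with the rule off they scale by `s(dE0)` — unless the
#'   mutant-style overrides `dEa` (inverse ADP lifetime) and/or `dEb`
#'   (hydrolysis frequency) are given, which take precedence.
#'
#' @param T_c Simulation temperature (degrees C).
#' @param T0_c Reference temperature (degrees C) at which base parameters are
#'   defined.
#' @param rule1,rule2,rule3 Logical flags for the three rules.
#' @param dE0 Common activation energy of the generic rates (kB*T0, default 10).
#' @param dEf Activation energy of the structural fluctuations attenuating
#'   `d3`/`d4` under Rule 1 (default 7).
#' @param dE_gs_fs KaiB ground-to-fold-switched activation energy (Rule 2
#'   binding side, default 10).
#' @param dE_fs_gs_p Effective reverse activation energy, fold-switched to
#'   ground plus the binding energy (Rule 2 unbinding side, default 12).
#' @param dEa,dEb Optional ATPase-specific activation energies overriding
#'   Rule 3: `1/dADP0` scales by `s(dEa)` and `f_hyd` by `s(dEb)`.
#' @return An object of class `kai_thermo`.
#' @examples
#' th <- kai_thermo(T_c = 35, rule1 = TRUE, rule2 = TRUE, rule3 = TRUE)
#' @export
kai_thermo <- function(T_c = 30, T0_c = 30,
                       rule1 = FALSE, rule2 = FALSE, rule3 = FALSE,
                       dE0 = 10, dEf = 7,
                       dE_gs_fs = 10, dE_fs_gs_p = 12,
                       dEa = NULL, dEb = NULL) {
  structure(list(T_c = T_c, T0_c = T0_c,
                 rule1 = isTRUE(rule1), rule2 = isTRUE(rule2),
                 rule3 = isTRUE(rule3),
                 dE0 = dE0, dEf = dEf,
                 dE_gs_fs = dE_gs_fs, dE_fs_gs_p = dE_fs_gs_p,
                 dEa = dEa, dEb = dEb),
            class = "kai_thermo")
}

#' @export
print.kai_thermo <- function(x, ...) {
  rules <- paste0(c("1", "2", "3")[c(x$rule1, x$rule2, x$rule3)],
                  collapse = "+")
  cat("<kai_thermo> T =", x$T_c, "C (T0 =", x$T0_c, "C), rules:",
      if (nzchar(rules)) rules else "none",
      "| dE0 =", x$dE0, "dEf =", x$dEf, "\n")
  invisible(x)
}

#' Preset rule combinations for the temperature-compensation cases
#'
#' The four canonical combinations: Case A = Rules 1+2+3; Case B = Rules 1+3
#' with the KaiB fold-switch energies set to zero; Case C = Rules 1+2 with the
#' ATPase rates carrying the common activation energy; Case D = Rules 2+3 with
#' `dEf = 0` so the coupling energies are temperature independent.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param T_c,T0_c Temperatures in degrees C.
#' @param dE0 Common activation energy (kB*T0).
#' @param dEf Structural-fluctuation activation energy used where the case
#'   leaves it free (Cases A-C; Case D forces 0).
#' @return A `kai_thermo` object.
#' @examples
#' kai_case("A", T_c = 25)
#' @export
kai_case <- function(name, T_c = 30, T0_c = 30, dE0 = 10, dEf = 7) {
  switch(toupper(name),
    A = kai_thermo(T_c, T0_c, rule1 = TRUE, rule2 = TRUE, rule3 = TRUE,
                   dE0 = dE0, dEf = dEf),
    B = kai_thermo(T_c, T0_c, rule1 = TRUE, rule2 = FALSE, rule3 = TRUE,
                   dE0 = dE0, dEf = dEf, dE_gs_fs = 0, dE_fs_gs_p = 0),
    C = kai_thermo(T_c, T0_c, rule1 = TRUE, rule2 = TRUE, rule3 = FALSE,
                   dE0 = dE0, dEf = dEf),
    D = kai_thermo(T_c, T0_c, rule1 = FALSE, rule2 = TRUE, rule3 = TRUE,
                   dE0 = dE0, dEf = 0),
    stop("unknown case '", name, "' (expected A, B, C or D)", call. = FALSE)
  )
}

#' Parameter set at temperature T
#'
#' Applies the temperature model to a base parameter set defined at the
#' reference temperature and returns the effective parameters at `thermo$T_c`.
#'
#' @param params Base [kai_params()] at `T0`.
#' @param thermo A [kai_thermo()] object.
#' @return A `kai_params` object with temperature-scaled entries.
#' @examples
#' effective_params(kai_params(N = 10), kai_case("A", T_c = 35))
#' @export
effective_params <- function(params, thermo) {
  stopifnot(inherits(params, "kai_params"), inherits(thermo, "kai_thermo"))
  s <- function(dE) arrhenius_factor(dE, thermo$T_c, thermo$T0_c)
  s0 <- s(thermo$dE0)
  p <- unclass(params)

  for (nm in c("hA0", "fA0", "hAB", "fAB", "kp", "kdp")) p[[nm]] <- p[[nm]] * s0

  if (thermo$rule2) {
    p$hB0 <- p$hB0 * s0 * s(thermo$dE_gs_fs)
    p$fB0 <- p$fB0 * s0 * s(thermo$dE_fs_gs_p)
  } else {
    p$hB0 <- p$hB0 * s0
    p$fB0 <- p$fB0 * s0
  }

  if (thermo$rule1) {
    att <- s(thermo$dEf)
    p$d3 <- p$d3 / att
    p$d4 <- p$d4 / att
  }

  if (!is.null(thermo$dEa) || !is.null(thermo$dEb)) {
    dEa <- if (is.null(thermo$dEa)) 0 else thermo$dEa
    dEb <- if (is.null(thermo$dEb)) 0 else thermo$dEb
    p$dADP0 <- p$dADP0 / s(dEa)
    p$f_hyd <- p$f_hyd * s(dEb)
  } else if (!thermo$rule3) {
    p$dADP0 <- p$dADP0 / s0
    p$f_hyd <- p$f_hyd * s0
  }

  structure(p, class = "kai_params")
}
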