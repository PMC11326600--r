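#' Model parameters for the half-sarcomere
#'
#' Builds the single source of truth for the model's physical constants:
#' lattice rest lengths, spring stiffnesses, the free-energy landscape of the
#' three-state cross-bridge cycle, kinetic prefactors, and metabolite
#' concentrations. Defaults are the published parameter set for a one-myosin
#' system; energies are accepted in units of `kBT` (as they are usually
#' quoted) and stored internally in pN nm.
#'
#' Reference concentrations for ATP, ADP and Pi are fixed at 1 M and are not
#' configurable; `conc_atp`, `conc_adp` and `conc_pi` are expressed in molar.
#'
#' The external-substrate stiffness `k_f` has no published value. The package
#' default of 0.5 pN/nm is derived in closed form from the one-myosin series
#' compliance: a post-stroke cross-bridge relaxes to an extension
#' `e = d_ps * k_net / (k_xb + k_net)` against the external spring, so
#' requiring the reported 1 nm residual extension (and hence a 3 pN holding
#' force) gives `k_net ~ k_f = 0.5` pN/nm. See the methods vignette.
#'
#' @param a0 Actin node spacing / actin spring rest length, nm.
#' @param m0 Myosin node spacing / myosin spring rest length, nm.
#' @param b0 Cross-bridge rest length, nm.
#' @param d_ps Unloaded power-stroke distance, nm (must be smaller than `b0`).
#' @param k_a,k_m,k_xb,k_t,k_f Stiffnesses of the actin segments, myosin
#'   segments, cross-bridge, titin and external substrate springs, pN/nm.
#' @param x_f0 Rest length of the external spring (M-line to anchor), nm.
#' @param kbt Thermal energy, pN nm.
#' @param dg_bind Free-energy drop of myosin binding to actin, in `kBT` units.
#' @param dg_stroke Free-energy drop of the power-stroke conformational
#'   change, in `kBT` units.
#' @param dg_hyd Standard free energy of ATP hydrolysis at 1 M reference
#'   concentrations, in `kBT` units.
#' @param dg_dpi_rel Free energy of ADP and Pi release from the actomyosin
#'   complex, in `kBT` units.
#' @param k_bind Attachment rate at zero cross-bridge distortion, 1/s.
#' @param k23_cap Power-stroke rate (strain-independent), 1/s.
#' @param k_atp0 Reverse-hydrolysis / ATP-detachment rate, 1/s.
#' @param conc_atp,conc_adp,conc_pi Metabolite concentrations, molar.
#'   Defaults are the standard physiological conditions 5 mM, 0.03 mM, 3 mM.
#'
#' @return An object of class `sarcomere_params`: a named list with energies
#'   converted to pN nm (fields `dG_bind`, `dG_stroke`, `dG_hyd`, `dG_dpi`)
#'   alongside the geometric, elastic and kinetic constants.
#' @examples
#' p <- sarcomere_params()
#' p$kbt
#' validate_params(sarcomere_params(k_xb = 0))
#' @export
sarcomere_params <- function(a0 = 12.3, m0 = 14.3, b0 = 10, d_ps = 7,
                             k_a = 5230, k_m = 6060, k_xb = 3, k_t = 10,
                             k_f = 0.5, x_f0 = 100, kbt = 4.14,
                             dg_bind = -4, dg_stroke = -4.5, dg_hyd = 13,
                             dg_dpi_rel = -14,
                             k_bind = 800, k23_cap = 30, k_atp0 = 1e-2,
                             conc_atp = 5e-3, conc_adp = 3e-5, conc_pi = 3e-3) {
  p <- list(
    a0 = a0, m0 = m0, b0 = b0, d_ps = d_ps,
    k_a = k_a, k_m = k_m, k_xb = k_xb, k_t = k_t, k_f = k_f,
    x_f0 = x_f0, kbt = kbt,
    # energies accepted in kBT multiples, stored once in pN nm
    dG_bind = dg_bind * kbt,
    dG_stroke = dg_stroke * kbt,
    dG_hyd = dg_hyd * kbt,
    dG_dpi = dg_dpi_rel * kbt,
    k_bind = k_bind, k23_cap = k23_cap, k_atp0 = k_atp0,
    conc_atp = conc_atp, conc_adp = conc_adp, conc_pi = conc_pi
  )
  class(p) <- "sarcomere_params"
  p
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set and reports findings instead of
#' erroring, so configuration problems can be collected and shown together.
#'
#' @param params A [sarcomere_params()] object.
#' @return A tibble with columns `field` and `rule`, one row per violated
#'   invariant; zero rows when the set is valid.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "sarcomere_params"))
  bad <- list()
  note <- function(field, rule) tibble::tibble(field = field, rule = rule)

  for (f in c("k_a", "k_m", "k_xb", "k_t", "k_f")) {
    if (!is.finite(params[[f]]) || params[[f]] <= 0) {
      bad[[length(bad) + 1L]] <- note(f, "stiffness must be > 0")
    }
  }
  for (f in c("k_bind", "k23_cap", "k_atp0")) {
    if (!is.finite(params[[f]]) || params[[f]] <= 0) {
      bad[[length(bad) + 1L]] <- note(f, "rate prefactor must be > 0")
    }
  }
  for (f in c("conc_atp", "conc_adp", "conc_pi")) {
    if (!is.finite(params[[f]]) || params[[f]] <= 0) {
      bad[[length(bad) + 1L]] <- note(f, "concentration must be > 0 (molar)")
    }
  }
  if (!is.finite(params$kbt) || params$kbt <= 0) {
    bad[[length(bad) + 1L]] <- note("kbt", "thermal energy must be > 0")
  }
  for (f in c("a0", "m0", "b0", "x_f0")) {
    if (!is.finite(params[[f]]) || params[[f]] <= 0) {
      bad[[length(bad) + 1L]] <- note(f, "rest length must be > 0")
    }
  }
  if (is.finite(params$d_ps) && is.finite(params$b0) &&
      params$d_ps >= params$b0) {
    bad[[length(bad) + 1L]] <- note("d_ps", "power-stroke distance must be < b0")
  }
  if (length(bad) == 0L) {
    tibble::tibble(field = character(), rule = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' @export
print.sarcomere_params <- function(x, ...) {
  cat("<sarcomere_params>\n")
  cat(sprintf("  lattice: a0 = %.3g nm, m0 = %.3g nm, b0 = %.3g nm, d_ps = %.3g nm\n",
              x$a0, x$m0, x$b0, x$d_ps))
  cat(sprintf("  springs (pN/nm): k_a = %g, k_m = %g, k_xb = %g, k_t = %g, k_f = %g\n",
              x$k_a, x$k_m, x$k_xb, x$k_t, x$k_f))
  cat(sprintf("  energies (kBT): bind = %.3g, stroke = %.3g, hyd* = %.3g, D/Pi rel = %.3g\n",
              x$dG_bind / x$kbt, x$dG_stroke / x$kbt, x$dG_hyd / x$kbt,
              x$dG_dpi / x$kbt))
  cat(sprintf("  rates (1/s): k_bind = %g, k23_cap = %g, k_ATP0 = %g\n",
              x$k_bind, x$k23_cap, x$k_atp0))
  cat(sprintf("  [ATP] = %g M, [ADP] = %g M, [Pi] = %g M\n",
              x$conc_atp, x$conc_adp, x$conc_pi))
  invisible(x)
}

#' Replace metabolite concentrations in a parameter set
#'
#' Convenience for concentration sweeps: returns a copy of `params` with new
#' concentrations. When only the product `[ADP][Pi]` is of interest it can be
#' supplied via `adppi` and is split evenly as `[ADP] = [Pi] = sqrt(adppi)`;
#' only the product enters any rate, so the split is immaterial.
#'
#' @param params A [sarcomere_params()] object.
#' @param atp ATP concentration, M (optional).
#' @param adp,pi ADP and Pi concentrations, M (optional).
#' @param adppi Product concentration, M^2 (optional; ignored when both `adp`
#'   and `pi` are given).
#' @return A `sarcomere_params` object.
#' @export
set_concentrations <- function(params, atp = NULL, adp = NULL, pi = NULL,
                               adppi = NULL) {
  stopifnot(inherits(params, "sarcomere_params"))
  if (!is.null(atp)) params$conc_atp <- atp
  if (!is.null(adp) && !is.null(pi)) {
    params$conc_adp <- adp
    params$conc_pi <- pi
  } else if (!is.null(adppi)) {
    params$conc_adp <- sqrt(adppi)
    params$conc_pi <- sqrt(adppi)
  } else {
    if (!is.null(adp)) params$conc_adp <- adp
    if (!is.null(pi)) params$conc_pi <- pi
  }
  params
}
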