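#' Free energies of the three cross-bridge states
#'
#' Evaluates the free-energy landscape of the cycle at a given cross-bridge
#' distortion. State 1 (M.ADP.Pi, detached) is the reference at zero; state 2
#' (A.M.ADP.Pi, pre-stroke) adds the binding drop plus the elastic energy of
#' the cross-bridge spring; state 3 (A.M, post-stroke) additionally carries
#' the stroke drop, the product-release term, the elastic energy at the
#' shortened rest length, and the chemical potential of the released ADP and
#' Pi. State 1' is the baseline of the next cycle, one full hydrolysis below
#' state 1; it is independent of strain.
#'
#' @param strain Cross-bridge distortion `x_m - x_a - b0`, nm (vectorised).
#' @param params A [sarcomere_params()] object.
#' @return Tibble with columns `strain`, `G1`, `G2`, `G3`, `G1_prime`
#'   (energies in pN nm).
#' @examples
#' state_energies(0, sarcomere_params())
#' @export
state_energies <- function(strain, params) {
  stopifnot(inherits(params, "sarcomere_params"))
  ln_adppi <- log(params$conc_adp * params$conc_pi) # reference 1 M^2
  ln_atp <- log(params$conc_atp)                    # reference 1 M
  g2 <- params$dG_bind + 0.5 * params$k_xb * strain^2
  g3 <- params$dG_bind + params$dG_stroke - params$dG_dpi +
    0.5 * params$k_xb * (strain + params$d_ps)^2 +
    params$kbt * ln_adppi
  g1p <- -params$dG_hyd - params$kbt * (ln_atp - ln_adppi)
  tibble::tibble(
    strain = strain,
    G1 = rep(0, length(strain)),
    G2 = g2,
    G3 = g3,
    G1_prime = rep(g1p, length(strain))
  )
}

#' Strain- and concentration-dependent rate constants
#'
#' Computes the six transition rates of the cycle and the three equilibrium
#' constants at a given cross-bridge distortion. Attachment places the
#' transition state halfway up the elastic well: the forward rate carries a
#' quarter of the elastic penalty while the equilibrium constant carries the
#' full half-k-x-squared, so detachment picks up the remainder through
#' detailed balance. The power stroke runs at a flat capped rate; its
#' reverse carries the `[ADP][Pi]` dependence. ATP-driven detachment (3 to 1)
#' carries the `[ATP]` dependence; its reverse is the constant
#' reverse-hydrolysis rate.
#'
#' @inheritParams state_energies
#' @return Tibble with columns `strain`, `k12`, `k21`, `k23`, `k32`, `k31`,
#'   `k13` (1/s) and `K12`, `K23`, `K31` (dimensionless).
#' @examples
#' rate_set(0, sarcomere_params())
#' @export
rate_set <- function(strain, params) {
  stopifnot(inherits(params, "sarcomere_params"))
  beta <- 1 / params$kbt
  kxb <- params$k_xb
  dps <- params$d_ps
  ln_adppi <- log(params$conc_adp * params$conc_pi)
  ln_atp <- log(params$conc_atp)

  k12 <- params$k_bind * exp(-beta * 0.25 * kxb * strain^2)
  K12 <- exp(-beta * (params$dG_bind + 0.5 * kxb * strain^2))
  k21 <- k12 / K12

  K23 <- exp(-beta * (params$dG_stroke - params$dG_dpi +
                        0.5 * kxb * (2 * strain * dps + dps^2) +
                        params$kbt * ln_adppi))
  k23 <- rep(params$k23_cap, length(strain))
  k32 <- k23 / K23

  K31 <- exp(-beta * (-params$dG_bind - params$dG_stroke - params$dG_hyd +
                        params$dG_dpi -
                        0.5 * kxb * (strain + dps)^2 -
                        params$kbt * ln_atp))
  k13 <- rep(params$k_atp0, length(strain))
  k31 <- K31 * k13

  tibble::tibble(
    strain = strain,
    k12 = k12, k21 = k21, k23 = k23, k32 = k32, k31 = k31, k13 = k13,
    K12 = K12, K23 = K23, K31 = K31
  )
}

#' Reaction quotient of one full cycle
#'
#' The product of forward over backward rates around the cycle. The elastic
#' contributions cancel exactly, so the quotient is strain independent and
#' equals `[ATP] / ([ADP][Pi]) * exp(dG_hyd / kBT)` (concentrations relative
#' to 1 M references) -- the thermodynamic-consistency check of the rate set.
#'
#' @param rates A tibble from [rate_set()] (or any data frame with the six
#'   rate columns).
#' @return Numeric vector of quotients, one per row of `rates`.
#' @examples
#' q <- reaction_quotient(rate_set(c(0, 2), sarcomere_params()))
#' @export
reaction_quotient <- function(rates) {
  (rates$k12 * rates$k23 * rates$k31) / (rates$k21 * rates$k32 * rates$k13)
}

# Closed form of the Eq-15 right-hand side, used as the oracle in tests and
# exposed for convenience.
#' Closed-form value of the cycle reaction quotient
#'
#' @param params A [sarcomere_params()] object.
#' @return The quotient `[ATP]/([ADP][Pi]) * exp(dG_hyd/kBT)` implied by the
#'   parameter set.
#' @export
quotient_closed_form <- function(params) {
  stopifnot(inherits(params, "sarcomere_params"))
  params$conc_atp / (params$conc_adp * params$conc_pi) *
    exp(params$dG_hyd / params$kbt)
}
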