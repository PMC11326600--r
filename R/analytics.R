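#' Closed-form one-myosin steady state
#'
#' Steady state of the three-state cycle for a single myosin head, written
#' as unnormalized weights
#' `P1 = k23*k31 + k21*(k32 + k31)`,
#' `P2 = k31*k12 + k32*(k12 + k13)`,
#' `P3 = k12*k23 + k13*(k21 + k23)`,
#' with duty ratio `P3 / (P1 + P2 + P3)`, average force
#' `duty_ratio * peak_force_ref`, and ATP consumption rate
#' `(k31*P3 - k13*P1) / (P1 + P2 + P3)`.
#'
#' The strain dependence follows the effective-sliding-distance (ESD)
#' surrogate: attachment happens near zero cross-bridge distortion, so `k12`
#' and `k21` are evaluated at zero strain, while the post-stroke rates `k32`
#' and `k31` are evaluated at the surrogate strain `-esd` (the distortion a
#' bound post-stroke head actually holds). `k23` and `k13` are
#' strain-independent constants.
#'
#' @param params A [sarcomere_params()] object (concentrations included).
#' @param esd Effective sliding distance, nm (>= 0).
#' @param peak_force_ref One-myosin simulated peak force used as the force
#'   scale, pN (default 3, itself a simulation output).
#' @param rates Optional test hook: a named list/row with all six rates
#'   (`k12`, `k21`, `k23`, `k32`, `k31`, `k13`), bypassing their evaluation.
#' @return One-row tibble with `P1`, `P2`, `P3` (unnormalized), `p1`, `p2`,
#'   `p3` (normalized), `duty_ratio`, `avg_force` (pN), `atp_rate` (1/s),
#'   `esd_used`, `peak_force_ref`.
#' @examples
#' steady_state(sarcomere_params(), esd = 6)
#' @export
steady_state <- function(params, esd, peak_force_ref = 3, rates = NULL) {
  if (is.null(rates)) {
    stopifnot(inherits(params, "sarcomere_params"), esd >= 0)
    attach_r <- rate_set(0, params)
    stroke_r <- rate_set(-esd, params)
    rates <- list(k12 = attach_r$k12, k21 = attach_r$k21,
                  k23 = attach_r$k23, k32 = stroke_r$k32,
                  k31 = stroke_r$k31, k13 = stroke_r$k13)
  }
  P1 <- rates$k23 * rates$k31 + rates$k21 * (rates$k32 + rates$k31)
  P2 <- rates$k31 * rates$k12 + rates$k32 * (rates$k12 + rates$k13)
  P3 <- rates$k12 * rates$k23 + rates$k13 * (rates$k21 + rates$k23)
  tot <- P1 + P2 + P3
  duty <- P3 / tot
  tibble::tibble(
    P1 = P1, P2 = P2, P3 = P3,
    p1 = P1 / tot, p2 = P2 / tot, p3 = P3 / tot,
    duty_ratio = duty,
    avg_force = duty * peak_force_ref,
    atp_rate = (rates$k31 * P3 - rates$k13 * P1) / tot,
    esd_used = esd,
    peak_force_ref = peak_force_ref
  )
}

#' Analytic steady state over a concentration grid
#'
#' Evaluates [steady_state()] on the outer product of `[ATP]` values and
#' `[ADP][Pi]` product values. The product is split evenly into
#' `[ADP] = [Pi] = sqrt(product)`; only the product enters any rate, so the
#' split is immaterial.
#'
#' @param params A [sarcomere_params()] object (its concentrations are
#'   overridden point-wise).
#' @param atp_values ATP concentrations, M.
#' @param adppi_values `[ADP][Pi]` products, M^2.
#' @inheritParams steady_state
#' @return Long tibble with one row per grid point: `atp`, `adppi` and the
#'   [steady_state()] columns.
#' @export
concentration_grid <- function(params, atp_values, adppi_values, esd,
                               peak_force_ref = 3) {
  stopifnot(length(atp_values) > 0, length(adppi_values) > 0)
  grid <- tidyr::expand_grid(atp = atp_values, adppi = adppi_values)
  res <- purrr::pmap(grid, function(atp, adppi) {
    steady_state(set_concentrations(params, atp = atp, adppi = adppi),
                 esd = esd, peak_force_ref = peak_force_ref)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Fit the effective sliding distance to a reference duty-ratio grid
#'
#' Finds the scalar ESD whose analytic one-myosin steady state best matches
#' a reference duty-ratio grid (normally simulated), by minimizing the mean
#' squared difference of log duty ratio over the grid. The log scale is used
#' because duty ratios span many orders of magnitude across a concentration
#' grid; a plain squared error would fit only the rigor corner.
#'
#' @param reference Data frame with columns `atp`, `adppi`, `duty_ratio`
#'   (one row per grid point; replicate-averaged).
#' @param params A [sarcomere_params()] object.
#' @param lower,upper Search bracket for the ESD, nm (default `[0, d_ps]`).
#' @return List of class `esd_fit`: `esd` (nm), `objective` (mean squared
#'   log difference at the optimum), `n_cells` used.
#' @export
fit_esd <- function(reference, params, lower = 0, upper = params$d_ps) {
  stopifnot(all(c("atp", "adppi", "duty_ratio") %in% names(reference)))
  ref <- reference[is.finite(reference$duty_ratio) & reference$duty_ratio > 0, ]
  if (nrow(ref) < 2L) {
    stop("reference grid has fewer than two usable duty-ratio cells", call. = FALSE)
  }
  if (diff(range(log(ref$duty_ratio))) < 1e-8) {
    stop("reference duty ratios are constant; the ESD is not identifiable",
         call. = FALSE)
  }
  obj <- function(esd) {
    an <- concentration_grid(params, unique(ref$atp), unique(ref$adppi), esd)
    key <- paste(signif(ref$atp, 12), signif(ref$adppi, 12))
    akey <- paste(signif(an$atp, 12), signif(an$adppi, 12))
    duty_an <- an$duty_ratio[match(key, akey)]
    mean((log(ref$duty_ratio) - log(duty_an))^2)
  }
  opt <- stats::optimize(obj, lower = lower, upper = upper, tol = 1e-4)
  structure(
    list(esd = opt$minimum, objective = opt$objective, n_cells = nrow(ref)),
    class = "esd_fit"
  )
}

#' @export
print.esd_fit <- function(x, ...) {
  cat(sprintf("<esd_fit> ESD = %.3f nm (mean squared log-duty error %.4g over %d cells)\n",
              x$esd, x$objective, x$n_cells))
  invisible(x)
}
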