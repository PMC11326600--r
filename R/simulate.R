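#' Simulation controls
#'
#' Controls for the fixed-step kinetic Monte Carlo run. The chemical step
#' `dt` defaults to 1e-5 s so that the fastest routinely visited rate (the
#' ATP-driven detachment at the relaxed post-stroke strain, ~8e3 1/s under
#' standard concentrations) keeps `k * dt` below 0.1. Per-myosin transition
#' probabilities are additionally capped at `p_cap` with a logged count, so
#' rare excursions to fast-rate strains degrade gracefully rather than
#' misbehaving.
#'
#' @param duration Simulated time, s.
#' @param dt Chemical sampling step, s.
#' @param seed Integer seed for the run.
#' @param record_stride Steps between recorded samples.
#' @param p_cap Cap on the per-myosin per-step total transition probability.
#' @param strain_cutoff Binding attempts are suppressed beyond this absolute
#'   cross-bridge distortion, nm (numerical guard only; the attachment
#'   Boltzmann factor suppresses distant binding long before this).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 1, dt = 1e-5, seed = 1L,
                       record_stride = 100L, p_cap = 0.95,
                       strain_cutoff = 20) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(record_stride) || record_stride < 1) {
    stop("record_stride must be >= 1", call. = FALSE)
  }
  structure(
    list(duration = duration, dt = dt, seed = as.integer(seed),
         record_stride = as.integer(record_stride), p_cap = p_cap,
         strain_cutoff = strain_cutoff,
         n_steps = round(duration / dt)),
    class = "sim_config"
  )
}

# flattened views handed to the compiled core (0-based node indices)
lattice_spec_for_core <- function(lattice) {
  idx <- lattice_indices(lattice)
  list(
    n_nodes = nrow(lattice$nodes),
    n_actin = lattice$n_actin,
    n_myosin = lattice$n_myosin,
    zline = idx$zline - 1L,
    mline = idx$mline - 1L,
    actin = as.integer(idx$actin - 1L),
    myosin = as.integer(idx$myosin - 1L),
    x_anchor = lattice$x_anchor,
    gamma0 = lattice$gamma0,
    x0 = lattice$nodes$x0
  )
}

kinetic_spec_for_core <- function(params) {
  list(
    k_a = params$k_a, k_m = params$k_m, k_t = params$k_t, k_f = params$k_f,
    k_xb = params$k_xb, a0 = params$a0, m0 = params$m0, b0 = params$b0,
    d_ps = params$d_ps, x_f0 = params$x_f0, kbt = params$kbt,
    dG_bind = params$dG_bind, dG_stroke = params$dG_stroke,
    dG_hyd = params$dG_hyd, dG_dpi = params$dG_dpi,
    k_bind = params$k_bind, k23_cap = params$k23_cap, k_atp0 = params$k_atp0,
    ln_atp = log(params$conc_atp),
    ln_adppi = log(params$conc_adp * params$conc_pi)
  )
}

# startup check of the fixed-step validity: rates the run will actually
# visit, evaluated at the rest geometry (binding strains for attachment and
# pre-stroke rates; the fully relaxed post-stroke strain for detachment)
dt_validity <- function(lattice, params, dt) {
  idx <- lattice_indices(lattice)
  x <- lattice$nodes$x0
  s0 <- vapply(idx$myosin, function(mi) {
    d <- x[mi] - x[idx$actin] - params$b0
    d[which.min(abs(d))]
  }, numeric(1))
  r_attach <- rate_set(s0, params)
  r_detach <- rate_set(s0 - params$d_ps, params)
  kmax <- max(r_attach$k12, r_attach$k21, params$k23_cap, params$k_atp0,
              r_detach$k31)
  tibble::tibble(k_max = kmax, k_dt = kmax * dt, ok = kmax * dt <= 0.1)
}

#' Run a half-sarcomere simulation
#'
#' Advances the coupled chemo-mechanical system: every myosin head starts
#' detached (state 1) with the lattice at rest; each chemical step samples at
#' most one stochastic transition per head and the spring network is brought
#' back to mechanical equilibrium after every step containing a transition.
#' ATP-hydrolysing detachments (3 to 1) and their reversals (1 to 3) are
#' logged with timestamps. Runs are bit-reproducible given the seed.
#'
#' @param lattice A [build_lattice()] object.
#' @param params A [sarcomere_params()] object.
#' @param config A [sim_config()] object.
#' @param quiet Suppress the fixed-step validity warning.
#' @param rate_override Test hook: a named numeric vector
#'   `c(k12, k21, k23, k32, k31, k13)` of constant rates that replaces the
#'   strain- and concentration-dependent kinetics, for degenerate and
#'   synthetic-kinetics checks. `NULL` (default) uses the physical rate set.
#' @return An object of class `sarcomere_trace`: list with a `samples`
#'   tibble (time, external force, internal/external elastic energy), a
#'   per-sample `state`/`strain`/`partner` matrix (one column per myosin),
#'   node `positions` per sample, an `events` tibble of hydrolysis and
#'   reverse events, exact per-myosin time-in-state (`state_time`), the
#'   transition count matrix, step-level effective-sliding-distance
#'   accumulators, and echoes of the configuration, parameters and seed.
#' @examples
#' p <- sarcomere_params()
#' lat <- build_lattice(p, n_actin = 2, n_myosin = 1)
#' tr <- simulate_sarcomere(lat, p, sim_config(duration = 0.05, seed = 7))
#' glance(tr)
#' @export
simulate_sarcomere <- function(lattice, params, config = sim_config(),
                               quiet = FALSE, rate_override = NULL) {
  stopifnot(inherits(lattice, "sarcomere_lattice"),
            inherits(params, "sarcomere_params"),
            inherits(config, "sim_config"))
  bad <- validate_params(params)
  if (nrow(bad) > 0L) {
    stop("invalid parameters: ", paste(bad$field, collapse = ", "), call. = FALSE)
  }
  if (!is.null(rate_override)) {
    need <- c("k12", "k21", "k23", "k32", "k31", "k13")
    stopifnot(all(need %in% names(rate_override)))
    rate_override <- as.numeric(rate_override[need])
  }
  chk <- dt_validity(lattice, params, config$dt)
  if (is.null(rate_override) && !chk$ok && !quiet) {
    warning(sprintf(
      "fixed-step validity: max rate %.3g 1/s gives k*dt = %.3g > 0.1; per-step probabilities will be capped at %.2f",
      chk$k_max, chk$k_dt, config$p_cap
    ), call. = FALSE)
  }

  control <- list(
    dt = config$dt, n_steps = config$n_steps,
    record_stride = config$record_stride, p_cap = config$p_cap,
    strain_cutoff = config$strain_cutoff,
    rate_override = !is.null(rate_override),
    override_rates = if (is.null(rate_override)) numeric(6) else rate_override
  )
  set.seed(config$seed)
  raw <- simulate_core(lattice_spec_for_core(lattice),
                       kinetic_spec_for_core(params), control)
  new_trace(raw, lattice, params, config)
}

new_trace <- function(raw, lattice, params, config) {
  samples <- tibble::tibble(
    time = raw$time,
    force = raw$force,
    energy_internal = raw$energy_internal,
    energy_external = raw$energy_external
  )
  events <- dplyr::bind_rows(
    tibble::tibble(time = raw$hydrolysis_times,
                   myosin = raw$hydrolysis_myosin, type = "hydrolysis"),
    tibble::tibble(time = raw$reverse_times,
                   myosin = raw$reverse_myosin, type = "reverse")
  )
  events <- dplyr::arrange(events, .data$time)
  structure(
    list(
      samples = samples,
      state = raw$state,
      strain = raw$strain,
      partner = raw$partner,
      positions = raw$positions,
      events = events,
      state_time = raw$state_time,
      transition_counts = raw$transition_counts,
      esd_sum = raw$esd_sum,
      esd_n = raw$esd_n,
      cap_events = raw$cap_events,
      rejected_claims = raw$rejected_claims,
      lattice = lattice,
      params = params,
      config = config
    ),
    class = "sarcomere_trace"
  )
}

#' @export
print.sarcomere_trace <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_trace> %d myosin / %d actin nodes, %.3g s at dt = %.1g s (seed %d)\n",
    x$lattice$n_myosin, x$lattice$n_actin, x$config$duration, x$config$dt,
    x$config$seed
  ))
  cat(sprintf("  %d recorded samples, %d hydrolysis / %d reverse events\n",
              nrow(x$samples), sum(x$events$type == "hydrolysis"),
              sum(x$events$type == "reverse")))
  invisible(x)
}
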