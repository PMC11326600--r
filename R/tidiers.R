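#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trace
#'
#' Long format: one row per recorded sample per myosin head, carrying the
#' head's chemical state, bound partner, cross-bridge strain and the
#' sarcomere-level force and elastic energies.
#'
#' @param x A [simulate_sarcomere()] result.
#' @param ... Unused.
#' @return A tibble with columns `time`, `myosin`, `state`, `partner`,
#'   `strain`, `force`, `energy_internal`, `energy_external`.
#' @export
tidy.sarcomere_trace <- function(x, ...) {
  nm <- ncol(x$state)
  long <- tidyr::expand_grid(i = seq_len(nrow(x$samples)), myosin = seq_len(nm))
  tibble::tibble(
    time = x$samples$time[long$i],
    myosin = long$myosin,
    state = x$state[cbind(long$i, long$myosin)],
    partner = x$partner[cbind(long$i, long$myosin)],
    strain = x$strain[cbind(long$i, long$myosin)],
    force = x$samples$force[long$i],
    energy_internal = x$samples$energy_internal[long$i],
    energy_external = x$samples$energy_external[long$i]
  )
}

#' One-row summary of a simulation trace
#'
#' @param x A [simulate_sarcomere()] result.
#' @param ... Passed to [trace_summary()].
#' @return The [trace_summary()] tibble.
#' @export
glance.sarcomere_trace <- function(x, ...) trace_summary(x, ...)

#' Tidy a sweep
#'
#' @param x A [run_sweep()] result.
#' @param ... Unused.
#' @return The per-replicate rows.
#' @export
tidy.sarcomere_sweep <- function(x, ...) x$replicates

#' Aggregated sweep table
#'
#' @param x A [run_sweep()] result.
#' @param ... Unused.
#' @return The per-point aggregate tibble.
#' @export
glance.sarcomere_sweep <- function(x, ...) x$points

#' Tidy an ESD fit
#'
#' @param x A [fit_esd()] result.
#' @param ... Unused.
#' @return One-row tibble with `esd`, `objective`, `n_cells`.
#' @export
tidy.esd_fit <- function(x, ...) {
  tibble::tibble(esd = x$esd, objective = x$objective, n_cells = x$n_cells)
}
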