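#' Reference lattices
#'
#' The two study geometries: the minimal one-myosin system (one myosin node
#' flanked by two actin binding nodes) and the 16-myosin, 24-actin-node
#' half-sarcomere.
#'
#' @param params A [sarcomere_params()] object.
#' @param geometry `"one-myosin"` or `"16-myosin"`.
#' @return A [build_lattice()] object.
#' @export
reference_lattice <- function(params, geometry = c("one-myosin", "16-myosin")) {
  geometry <- match.arg(geometry)
  if (geometry == "one-myosin") {
    build_lattice(params, n_actin = 2, n_myosin = 1)
  } else {
    build_lattice(params, n_actin = 24, n_myosin = 16)
  }
}

#' Replicate simulations over a concentration grid
#'
#' Runs `replicates` seeded simulations at every `([ATP], [ADP][Pi])` grid
#' point and aggregates duty ratio, average force, plateau ATP rate and
#' effective sliding distance into point means with standard errors.
#' Replicate seeds are derived deterministically from the master seed as
#' `master_seed + (point - 1) * replicates + (replicate - 1)`, so the whole
#' table reproduces from one integer. Individual replicate failures are
#' caught, logged and excluded; a point is flagged when more than 20% of its
#' replicates fail.
#'
#' @param params A [sarcomere_params()] object (point concentrations are
#'   substituted; its other constants, including any `k_atp0` override, are
#'   used as-is).
#' @param atp_values ATP concentrations, M.
#' @param adppi_values `[ADP][Pi]` products, M^2 (split evenly between ADP
#'   and Pi; only the product matters).
#' @param geometry `"one-myosin"`, `"16-myosin"`, or a
#'   [build_lattice()] object.
#' @param replicates Seeded replicates per grid point.
#' @param config A [sim_config()] template; its seed is replaced per
#'   replicate.
#' @param master_seed Integer master seed.
#' @return Object of class `sarcomere_sweep`: list with `replicates`
#'   (per-run rows), `points` (aggregated, with `*_se` columns, `n_ok` and
#'   `flagged`), `failures`, and a provenance `echo` (master seed, geometry,
#'   configuration, package version).
#' @export
run_sweep <- function(params, atp_values, adppi_values,
                      geometry = "one-myosin", replicates = 10,
                      config = sim_config(), master_seed = 1L) {
  stopifnot(replicates >= 1, length(atp_values) > 0, length(adppi_values) > 0)
  lattice <- if (inherits(geometry, "sarcomere_lattice")) {
    geometry
  } else {
    reference_lattice(params, geometry)
  }
  grid <- tidyr::expand_grid(atp = atp_values, adppi = adppi_values)
  grid$point <- seq_len(nrow(grid))

  run_one <- function(point, atp, adppi, rep) {
    seed <- as.integer(master_seed + (point - 1L) * replicates + (rep - 1L))
    cfg <- config
    cfg$seed <- seed
    p <- set_concentrations(params, atp = atp, adppi = adppi)
    tr <- simulate_sarcomere(lattice, p, cfg, quiet = TRUE)
    dplyr::bind_cols(
      tibble::tibble(point = point, atp = atp, adppi = adppi,
                     replicate = rep, seed = seed),
      trace_summary(tr)
    )
  }

  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      res <- tryCatch(
        run_one(grid$point[i], grid$atp[i], grid$adppi[i], r),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- tibble::tibble(
          point = grid$point[i], atp = grid$atp[i], adppi = grid$adppi[i],
          replicate = r, message = conditionMessage(res)
        )
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(point = integer(), atp = numeric(), adppi = numeric(),
                   replicate = integer(), message = character())

  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  }
  points <- reps |>
    dplyr::group_by(.data$point, .data$atp, .data$adppi) |>
    dplyr::summarise(
      n_ok = dplyr::n(),
      duty_ratio = mean(.data$duty_ratio),
      duty_ratio_se = se(.data$duty_ratio),
      average_force = mean(.data$average_force),
      average_force_se = se(.data$average_force),
      peak_force_raw = mean(.data$peak_force_raw),
      peak_force_smooth = mean(.data$peak_force_smooth),
      plateau_atp_rate = mean(.data$plateau_atp_rate, na.rm = TRUE),
      plateau_atp_rate_se = se(.data$plateau_atp_rate),
      esd = mean(.data$esd, na.rm = TRUE),
      esd_se = se(.data$esd),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = (replicates - .data$n_ok) / replicates > 0.2)

  structure(
    list(
      replicates = reps,
      points = points,
      failures = failures,
      echo = list(
        master_seed = as.integer(master_seed),
        replicates = replicates,
        geometry = list(n_actin = lattice$n_actin, n_myosin = lattice$n_myosin),
        config = unclass(config),
        params = unclass(params),
        version = as.character(utils::packageVersion("sarcosim"))
      )
    ),
    class = "sarcomere_sweep"
  )
}

#' @export
print.sarcomere_sweep <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_sweep> %d grid points x %d replicates (%d failures); geometry %d myosin / %d actin\n",
    nrow(x$points), x$echo$replicates, nrow(x$failures),
    x$echo$geometry$n_myosin, x$echo$geometry$n_actin
  ))
  print(x$points)
  invisible(x)
}

#' Compare a simulated grid against the analytic surrogate
#'
#' Joins a simulated duty-ratio grid with an analytic [concentration_grid()]
#' on the shared `(atp, adppi)` points, reports the per-point log duty-ratio
#' difference and its root mean square, and (when `params` is supplied) the
#' best-fit effective sliding distance via [fit_esd()].
#'
#' @param sim Data frame with `atp`, `adppi`, `duty_ratio` (e.g. the
#'   `points` table of a [run_sweep()]).
#' @param analytic A [concentration_grid()] table on the same grid.
#' @param params Optional [sarcomere_params()] to refit the ESD.
#' @return List of class `sweep_comparison`: `points` (with `log_ratio`),
#'   `rms_log_ratio`, and `esd_fit` (or `NULL`).
#' @export
compare_sim_vs_analytic <- function(sim, analytic, params = NULL) {
  key <- function(d) paste(signif(d$atp, 12), signif(d$adppi, 12))
  if (nrow(sim) != nrow(analytic) || !setequal(key(sim), key(analytic))) {
    stop("simulated and analytic grids do not match", call. = FALSE)
  }
  m <- match(key(sim), key(analytic))
  pts <- tibble::tibble(
    atp = sim$atp, adppi = sim$adppi,
    duty_sim = sim$duty_ratio,
    duty_analytic = analytic$duty_ratio[m],
    log_ratio = log(sim$duty_ratio) - log(analytic$duty_ratio[m])
  )
  ok <- is.finite(pts$log_ratio)
  fit <- if (!is.null(params)) fit_esd(sim, params) else NULL
  structure(
    list(points = pts,
         rms_log_ratio = sqrt(mean(pts$log_ratio[ok]^2)),
         esd_fit = fit),
    class = "sweep_comparison"
  )
}

#' @export
print.sweep_comparison <- function(x, ...) {
  cat(sprintf("<sweep_comparison> RMS log duty-ratio difference %.4g over %d points\n",
              x$rms_log_ratio, nrow(x$points)))
  if (!is.null(x$esd_fit)) print(x$esd_fit)
  invisible(x)
}

#' Write a trace to disk
#'
#' Writes the recorded samples (with per-myosin state and strain columns) as
#' CSV and a JSON summary carrying the observables, configuration echo and
#' seed, so every output directory is self-describing.
#'
#' @param trace A [simulate_sarcomere()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "sarcomere_trace"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- trace$samples
  st <- as.data.frame(trace$state)
  names(st) <- paste0("state_m", seq_len(ncol(st)))
  sn <- as.data.frame(trace$strain)
  names(sn) <- paste0("strain_m", seq_len(ncol(sn)))
  utils::write.csv(cbind(as.data.frame(samples), st, sn),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(trace$events),
                   file.path(dir, "events.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(summary = as.list(trace_summary(trace)),
           config = unclass(trace$config),
           params = unclass(trace$params),
           geometry = list(n_actin = trace$lattice$n_actin,
                           n_myosin = trace$lattice$n_myosin),
           version = as.character(utils::packageVersion("sarcosim"))),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
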