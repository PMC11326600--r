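#' Cross-bridge configuration
#'
#' A per-myosin record of chemical state and bound actin partner. State 1 is
#' detached (no partner); states 2 and 3 are bound pre- and post-stroke. A
#' bound actin node can be claimed by at most one myosin.
#'
#' @param states Integer vector in `{1, 2, 3}`, one per myosin node.
#' @param partners Integer vector of actin node indices (1-based within the
#'   thin filament), `NA` for detached myosins.
#' @return A tibble with columns `myosin`, `state`, `actin` and class
#'   `xb_config`.
#' @examples
#' xb_config(c(1L, 3L), c(NA, 1L))
#' @export
xb_config <- function(states, partners = rep(NA_integer_, length(states))) {
  stopifnot(length(states) == length(partners))
  states <- as.integer(states)
  partners <- as.integer(partners)
  if (!all(states %in% 1:3)) stop("states must be in {1,2,3}", call. = FALSE)
  if (any((states == 1L) != is.na(partners))) {
    stop("state 1 must be (and only be) unbound", call. = FALSE)
  }
  bound <- partners[!is.na(partners)]
  if (anyDuplicated(bound)) {
    stop("an actin node is claimed by more than one myosin", call. = FALSE)
  }
  out <- tibble::tibble(myosin = seq_along(states), state = states,
                        actin = partners)
  class(out) <- c("xb_config", class(out))
  out
}

check_xb_against <- function(xb, lattice) {
  if (nrow(xb) != lattice$n_myosin) {
    stop("cross-bridge configuration does not match myosin count", call. = FALSE)
  }
  bound <- xb$actin[!is.na(xb$actin)]
  if (any(bound < 1L | bound > lattice$n_actin)) {
    stop("cross-bridge references a nonexistent actin node", call. = FALSE)
  }
  invisible(TRUE)
}

# All springs for a configuration, including cross-bridges whose rest length
# is b0 in state 2 and b0 - d_ps in state 3.
configuration_springs <- function(lattice, params, xb, include_titin = TRUE) {
  idx <- lattice_indices(lattice)
  springs <- lattice_springs(lattice, params)
  if (!include_titin) springs <- springs[springs$type != "titin", ]
  bound <- xb[xb$state != 1L, , drop = FALSE]
  if (nrow(bound) > 0L) {
    xb_edges <- tibble::tibble(
      from = idx$actin[bound$actin],
      to = idx$myosin[bound$myosin],
      k = params$k_xb,
      rest = ifelse(bound$state == 3L, params$b0 - params$d_ps, params$b0),
      type = "crossbridge"
    )
    springs <- dplyr::bind_rows(springs, xb_edges)
  }
  springs
}

#' Assemble the linear force-balance system
#'
#' Builds the stiffness matrix `K` and load vector `V` whose solution
#' `P = K^-1 V` gives the equilibrium positions of all free nodes (every node
#' except the Z-line; the external anchor is a fixed boundary). Each spring
#' between nodes contributes its stiffness to the diagonal entries of its two
#' endpoints and minus the stiffness off-diagonal; rest lengths and fixed
#' endpoints enter `V`.
#'
#' @param lattice A [build_lattice()] object.
#' @param params A [sarcomere_params()] object.
#' @param xb A [xb_config()] (defaults to all-detached).
#' @param include_titin Include the titin spring in the system. Titin is
#'   slack under compression; [solve_positions()] handles that automatically,
#'   this switch exists so it can re-assemble both branches.
#' @return A list of class `mech_system` with elements `K`, `V`, `springs`,
#'   `free` (node rows of the free coordinates), plus the inputs.
#' @export
assemble_system <- function(lattice, params,
                            xb = xb_config(rep(1L, lattice$n_myosin)),
                            include_titin = TRUE) {
  stopifnot(inherits(lattice, "sarcomere_lattice"),
            inherits(params, "sarcomere_params"))
  check_xb_against(xb, lattice)
  springs <- configuration_springs(lattice, params, xb, include_titin)

  free <- which(!lattice$nodes$fixed)
  pos_fixed <- lattice$nodes$x0
  col_of <- match(seq_len(nrow(lattice$nodes)), free) # NA for fixed nodes
  n <- length(free)
  K <- matrix(0, n, n)
  V <- numeric(n)

  for (s in seq_len(nrow(springs))) {
    i <- springs$from[s]
    j <- springs$to[s]
    k <- springs$k[s]
    r <- springs$rest[s]
    x_j_fixed <- if (is.na(j)) lattice$x_anchor else pos_fixed[j]
    ci <- if (is.na(i)) NA_integer_ else col_of[i]
    cj <- if (is.na(j)) NA_integer_ else col_of[j]
    # equation for the Z-ward endpoint i: k*x_i - k*x_j = -k*r
    if (!is.na(ci)) {
      K[ci, ci] <- K[ci, ci] + k
      if (!is.na(cj)) K[ci, cj] <- K[ci, cj] - k else V[ci] <- V[ci] + k * x_j_fixed
      V[ci] <- V[ci] - k * r
    }
    # equation for the M-ward endpoint j: k*x_j - k*x_i = k*r
    if (!is.na(cj)) {
      K[cj, cj] <- K[cj, cj] + k
      if (!is.na(ci)) K[cj, ci] <- K[cj, ci] - k else V[cj] <- V[cj] + k * pos_fixed[i]
      V[cj] <- V[cj] + k * r
    }
  }

  structure(
    list(K = K, V = V, springs = springs, free = free,
         lattice = lattice, params = params, xb = xb,
         include_titin = include_titin),
    class = "mech_system"
  )
}

spring_energies <- function(positions, lattice, springs, slack_titin = TRUE) {
  x_of <- function(i) ifelse(is.na(i), lattice$x_anchor, positions[i])
  ext <- x_of(springs$to) - x_of(springs$from) - springs$rest
  e <- 0.5 * springs$k * ext^2
  if (slack_titin) {
    ti <- which(springs$type == "titin")
    if (length(ti) && ext[ti] < 0) e[ti] <- 0
  }
  tibble::tibble(type = springs$type, extension = ext, energy = e)
}

#' Solve the mechanical equilibrium
#'
#' Direct dense solve of the assembled system, with automatic handling of the
#' slack titin branch: titin bears force only when stretched beyond its rest
#' length, so the system is solved with titin engaged and re-solved without
#' it if the solution leaves titin compressed (and vice versa).
#'
#' @param system A [assemble_system()] object.
#' @return An object of class `sarcomere_solution`: list with `positions`
#'   (all nodes, fixed included, nm), `external_force` (pN, positive when the
#'   external spring is stretched by contraction), `residual_norm` (relative,
#'   of the engaged branch), `energy_internal`, `energy_external` (pN nm),
#'   per-spring `energies` tibble, and `titin_engaged`.
#' @export
solve_positions <- function(system) {
  stopifnot(inherits(system, "mech_system"))
  lattice <- system$lattice
  params <- system$params

  solve_branch <- function(sys) {
    p_free <- tryCatch(
      solve(sys$K, sys$V),
      error = function(e) stop("stiffness matrix is singular (disconnected lattice)",
                               call. = FALSE)
    )
    positions <- lattice$nodes$x0
    positions[sys$free] <- p_free
    resid <- sqrt(sum((sys$K %*% p_free - sys$V)^2)) /
      max(sqrt(sum(sys$V^2)), 1)
    list(positions = positions, resid = resid, sys = sys)
  }

  br <- solve_branch(system)
  titin_engaged <- system$include_titin
  if (system$include_titin) {
    m1 <- lattice_indices(lattice)$myosin[1L]
    if (br$positions[m1] - 0 < lattice$gamma0) {
      # titin compressed: it is slack, drop it and re-solve
      alt <- solve_branch(assemble_system(lattice, params, system$xb,
                                          include_titin = FALSE))
      if (alt$positions[m1] < lattice$gamma0) {
        br <- alt
        titin_engaged <- FALSE
      }
    }
  }

  positions <- br$positions
  mline <- lattice_indices(lattice)$mline
  external_force <- params$k_f *
    ((lattice$x_anchor - positions[mline]) - params$x_f0)
  en <- spring_energies(positions, lattice, system$springs,
                        slack_titin = TRUE)
  e_ext <- sum(en$energy[en$type == "external"])
  e_int <- sum(en$energy) - e_ext

  structure(
    list(positions = positions, external_force = external_force,
         residual_norm = br$resid, energy_internal = e_int,
         energy_external = e_ext, energies = en,
         titin_engaged = titin_engaged),
    class = "sarcomere_solution"
  )
}

#' @export
print.sarcomere_solution <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_solution> external force %.4g pN; elastic energy %.4g pN nm (internal) + %.4g pN nm (external)\n",
    x$external_force, x$energy_internal, x$energy_external
  ))
  invisible(x)
}

#' Internal/external elastic energy partition
#'
#' Fraction of the total elastic potential energy stored in springs internal
#' to the sarcomere (actin, myosin, titin, cross-bridges) versus the external
#' substrate spring. Both fractions are 0 at rest (total energy zero).
#'
#' @param solution A [solve_positions()] result.
#' @return Tibble with columns `internal_fraction` and `external_fraction`.
#' @export
energy_partition <- function(solution) {
  stopifnot(inherits(solution, "sarcomere_solution"))
  tot <- solution$energy_internal + solution$energy_external
  if (tot <= 1e-12) { # at rest the partition is 0/0; both fractions are 0
    tibble::tibble(internal_fraction = 0, external_fraction = 0)
  } else {
    tibble::tibble(
      internal_fraction = solution$energy_internal / tot,
      external_fraction = solution$energy_external / tot
    )
  }
}
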