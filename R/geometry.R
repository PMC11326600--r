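#' Build the one-dimensional two-filament lattice
#'
#' Lays out the half-sarcomere on a single axis with the Z-line fixed at
#' x = 0. Actin binding nodes sit at `a0 * i` (i = 1..n_actin) measured from
#' the Z-line; the thick filament is placed so that its most Z-proximal
#' myosin node rests one cross-bridge rest length `b0` beyond the first actin
#' node (zero distortion for that pair), with subsequent myosin nodes spaced
#' `m0` apart and the M-line one further `m0` beyond the last myosin node.
#' The external-substrate anchor sits `x_f0` beyond the M-line. Titin spans
#' the Z-line and the myosin node most distal from the M-line; its rest
#' length `gamma0` is the rest position of that node.
#'
#' Because `a0 != m0`, myosin nodes acquire heterogeneous offsets from their
#' nearest actin binding sites -- the only cross-bridge disorder mechanism
#' representable in one dimension. `overlap_shift` translates the whole thick
#' filament (and anchor) to explore other registrations.
#'
#' @param params A [sarcomere_params()] object.
#' @param n_actin Number of actin binding nodes (>= 1).
#' @param n_myosin Number of myosin nodes (>= 1).
#' @param overlap_shift Rigid translation of the thick filament, nm.
#' @return An object of class `sarcomere_lattice`: list with a `nodes` tibble
#'   (`node`, `filament`, `index`, `x0`, `fixed`), the anchor coordinate
#'   `x_anchor`, titin rest length `gamma0`, and the counts. Total node count
#'   is `n_actin + n_myosin + 2` (Z-line and M-line; the anchor is a fixed
#'   boundary, not a node).
#' @examples
#' lat <- build_lattice(sarcomere_params(), n_actin = 2, n_myosin = 2)
#' lat$nodes
#' @export
build_lattice <- function(params, n_actin, n_myosin, overlap_shift = 0) {
  stopifnot(inherits(params, "sarcomere_params"))
  if (length(n_actin) != 1L || !is.finite(n_actin) || n_actin < 1 ||
      n_actin != round(n_actin)) {
    stop("n_actin must be a positive integer", call. = FALSE)
  }
  if (length(n_myosin) != 1L || !is.finite(n_myosin) || n_myosin < 1 ||
      n_myosin != round(n_myosin)) {
    stop("n_myosin must be a positive integer", call. = FALSE)
  }
  n_actin <- as.integer(n_actin)
  n_myosin <- as.integer(n_myosin)

  x_actin <- params$a0 * seq_len(n_actin)
  m1 <- params$a0 + params$b0 + overlap_shift
  x_myosin <- m1 + params$m0 * (seq_len(n_myosin) - 1L)
  x_mline <- x_myosin[n_myosin] + params$m0
  x_anchor <- x_mline + params$x_f0

  nodes <- tibble::tibble(
    node = seq_len(n_actin + n_myosin + 2L),
    filament = c("zline", rep("actin", n_actin), rep("myosin", n_myosin), "mline"),
    index = c(0L, seq_len(n_actin), seq_len(n_myosin), 0L),
    x0 = c(0, x_actin, x_myosin, x_mline),
    fixed = c(TRUE, rep(FALSE, n_actin + n_myosin + 1L))
  )

  structure(
    list(
      nodes = nodes,
      n_actin = n_actin,
      n_myosin = n_myosin,
      x_anchor = x_anchor,
      gamma0 = m1,
      overlap_shift = overlap_shift
    ),
    class = "sarcomere_lattice"
  )
}

#' @export
print.sarcomere_lattice <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_lattice> %d actin + %d myosin nodes (+ Z-line, M-line); anchor at %.1f nm\n",
    x$n_actin, x$n_myosin, x$x_anchor
  ))
  cat(sprintf("  titin rest length gamma0 = %.2f nm\n", x$gamma0))
  invisible(x)
}

# Row indices into lattice$nodes for each node role.
lattice_indices <- function(lattice) {
  f <- lattice$nodes$filament
  list(
    zline = which(f == "zline"),
    actin = which(f == "actin"),
    myosin = which(f == "myosin"),
    mline = which(f == "mline")
  )
}

#' Enumerate the permanent springs of a lattice
#'
#' Lists every filament-backbone, titin and external spring as an oriented
#' edge (`from` is the Z-ward node). Cross-bridge springs are configuration
#' dependent and are added by [assemble_system()].
#'
#' @param lattice A [build_lattice()] object.
#' @param params A [sarcomere_params()] object.
#' @return Tibble with columns `from`, `to`, `k`, `rest`, `type`. The `to`
#'   value `NA` marks the fixed external anchor.
#' @export
lattice_springs <- function(lattice, params) {
  idx <- lattice_indices(lattice)
  za <- c(idx$zline, idx$actin)
  my <- c(idx$myosin, idx$mline)
  actin_edges <- tibble::tibble(
    from = za[-length(za)], to = za[-1L],
    k = params$k_a, rest = params$a0, type = "actin"
  )
  myosin_edges <- tibble::tibble(
    from = my[-length(my)], to = my[-1L],
    k = params$k_m, rest = params$m0, type = "myosin"
  )
  titin_edge <- tibble::tibble(
    from = idx$zline, to = idx$myosin[1L],
    k = params$k_t, rest = lattice$gamma0, type = "titin"
  )
  external_edge <- tibble::tibble(
    from = idx$mline, to = NA_integer_,
    k = params$k_f, rest = params$x_f0, type = "external"
  )
  dplyr::bind_rows(actin_edges, myosin_edges, titin_edge, external_edge)
}
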