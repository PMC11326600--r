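# Shared fixtures and independent oracles.

std_params <- function(...) sarcomere_params(...)

# Independent steady state of the three-state cycle: null space of the
# transposed generator, solved as a bordered linear system (two master
# equations plus normalisation) with iterative refinement. No use of the
# closed-form weights.
null_space_steady <- function(k12, k21, k23, k32, k31, k13) {
  G <- matrix(0, 3, 3)
  G[1, 2] <- k12; G[1, 3] <- k13
  G[2, 1] <- k21; G[2, 3] <- k23
  G[3, 2] <- k32; G[3, 1] <- k31
  diag(G) <- -rowSums(G)
  A <- rbind(t(G)[1:2, ], c(1, 1, 1))
  b <- c(0, 0, 1)
  p <- solve(A, b)
  for (i in 1:3) p <- p + solve(A, b - A %*% p)
  p <- as.numeric(p)
  stopifnot(all(p > 0))
  p
}

# log-uniform random rate sets for property sweeps
rand_rate_sets <- function(n, lo = 1e-3, hi = 1e4) {
  m <- matrix(exp(runif(6 * n, log(lo), log(hi))), ncol = 6)
  colnames(m) <- c("k12", "k21", "k23", "k32", "k31", "k13")
  m
}

# brute-force elastic-energy minimisation, independent of the linear solver
minimise_energy <- function(lattice, params, xb) {
  springs <- sarcosim:::configuration_springs(lattice, params, xb,
                                              include_titin = TRUE)
  free <- which(!lattice$nodes$fixed)
  x_full <- lattice$nodes$x0
  energy_of <- function(xf) {
    x <- x_full
    x[free] <- xf
    pos_of <- function(i) ifelse(is.na(i), lattice$x_anchor, x[i])
    ext <- pos_of(springs$to) - pos_of(springs$from) - springs$rest
    e <- 0.5 * springs$k * ext^2
    ti <- which(springs$type == "titin")
    if (length(ti) && ext[ti] < 0) e[ti] <- 0
    sum(e)
  }
  fit <- optim(x_full[free], energy_of, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  x_full[free] <- fit$par
  x_full
}
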