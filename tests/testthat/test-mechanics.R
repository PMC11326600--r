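test_that("stiffness matrix is symmetric with stiffness-sum diagonal", {
  p <- std_params()
  lat <- build_lattice(p, 4, 3)
  xb <- xb_config(c(2L, 1L, 3L), c(2L, NA, 4L))
  sys <- assemble_system(lat, p, xb)
  expect_equal(sys$K, t(sys$K))

  # brute-force re-assembly of the diagonal: sum of stiffnesses incident to
  # each free node over an independent enumeration of the springs
  springs <- sarcosim:::configuration_springs(lat, p, xb)
  diag_expected <- vapply(sys$free, function(node) {
    sum(springs$k[springs$from %in% node | springs$to %in% node])
  }, numeric(1))
  expect_equal(diag(sys$K), diag_expected)
})

test_that("zero-distortion configurations leave the lattice at rest", {
  p <- std_params()
  lat <- build_lattice(p, 2, 1) # myosin rests exactly b0 from actin node 1
  # state-2 cross-bridge at rest length: V unchanged, rest positions exact
  sol <- solve_positions(assemble_system(lat, p, xb_config(2L, 1L)))
  expect_equal(sol$positions, lat$nodes$x0, tolerance = 1e-12)
  expect_equal(sol$external_force, 0, tolerance = 1e-10)
})

test_that("solver matches brute-force energy minimisation", {
  p <- std_params()
  cases <- list(
    list(lat = build_lattice(p, 2, 1), xb = xb_config(3L, 1L)),
    list(lat = build_lattice(p, 5, 3), xb = xb_config(c(3L, 2L, 1L), c(1L, 4L, NA))),
    list(lat = build_lattice(p, 24, 16),
         xb = xb_config(c(rep(3L, 4), rep(2L, 4), rep(1L, 8)),
                        c(1L, 5L, 9L, 13L, 3L, 7L, 11L, 15L, rep(NA, 8))))
  )
  for (cs in cases) {
    sol <- solve_positions(assemble_system(cs$lat, p, cs$xb))
    x_opt <- minimise_energy(cs$lat, p, cs$xb)
    expect_equal(sol$positions, x_opt, tolerance = 1e-5)
    expect_lt(sol$residual_norm, 1e-8)
  }
})

test_that("one-myosin state-3 equilibrium matches the series-compliance closed form", {
  # with rigid filaments the post-stroke cross-bridge relaxes against the
  # series combination of the filament and external springs:
  # extension e = d_ps * k_net / (k_xb + k_net), holding force k_xb * e
  p <- std_params()
  lat <- build_lattice(p, 2, 1)
  sol <- solve_positions(assemble_system(lat, p, xb_config(3L, 1L)))
  k_net <- 1 / (1 / p$k_a + 1 / p$k_m + 1 / p$k_f) # titin slack under compression
  e_expected <- p$d_ps * k_net / (p$k_xb + k_net)
  idx <- sarcosim:::lattice_indices(lat)
  strain <- sol$positions[idx$myosin[1]] - sol$positions[idx$actin[1]] - p$b0
  expect_equal(strain + p$d_ps, e_expected, tolerance = 1e-9)
  expect_equal(sol$external_force, p$k_xb * e_expected, tolerance = 1e-9)
})

test_that("substituting d_ps -> 0 makes state 3 mechanically identical to state 2", {
  p0 <- sarcomere_params(d_ps = 1e-12) # d_ps must stay positive; limit case
  lat <- build_lattice(p0, 3, 2)
  s2 <- solve_positions(assemble_system(lat, p0, xb_config(c(2L, 2L), c(1L, 3L))))
  s3 <- solve_positions(assemble_system(lat, p0, xb_config(c(3L, 3L), c(1L, 3L))))
  expect_equal(s2$positions, s3$positions, tolerance = 1e-9)
  expect_equal(s2$external_force, s3$external_force, tolerance = 1e-9)
})

test_that("net force on every free node vanishes at the solution", {
  p <- std_params()
  lat <- build_lattice(p, 6, 4)
  xb <- xb_config(c(3L, 2L, 3L, 1L), c(2L, 4L, 6L, NA))
  sys <- assemble_system(lat, p, xb)
  sol <- solve_positions(sys)
  # residual of the engaged branch, recomputed directly
  if (sol$titin_engaged) {
    resid <- sys$K %*% sol$positions[sys$free] - sys$V
  } else {
    sys2 <- assemble_system(lat, p, xb, include_titin = FALSE)
    resid <- sys2$K %*% sol$positions[sys2$free] - sys2$V
  }
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("invalid cross-bridge configurations are rejected", {
  p <- std_params()
  lat <- build_lattice(p, 2, 2)
  expect_error(xb_config(c(2L, 2L), c(1L, 1L)), "claimed")
  expect_error(xb_config(2L, NA_integer_), "unbound")
  expect_error(assemble_system(lat, p, xb_config(c(2L, 1L), c(5L, NA))),
               "nonexistent")
})

test_that("energy partition is 0/0-safe at rest and normalised under load", {
  p <- std_params()
  lat <- build_lattice(p, 2, 1)
  ep0 <- energy_partition(solve_positions(assemble_system(lat, p)))
  expect_equal(unlist(ep0), c(internal_fraction = 0, external_fraction = 0))
  ep <- energy_partition(solve_positions(assemble_system(lat, p, xb_config(3L, 1L))))
  expect_equal(ep$internal_fraction + ep$external_fraction, 1)
  expect_true(all(unlist(ep) >= 0 & unlist(ep) <= 1))
})

test_that("a 16-myosin system stores a larger internal energy fraction than one myosin", {
  p <- std_params()
  cfg <- sim_config(duration = 0.5, seed = 21)
  frac_of <- function(geom) {
    tr <- simulate_sarcomere(reference_lattice(p, geom), p, cfg, quiet = TRUE)
    tot <- tr$samples$energy_internal + tr$samples$energy_external
    ok <- tot > 0
    mean(tr$samples$energy_internal[ok] / tot[ok])
  }
  expect_gt(frac_of("16-myosin"), frac_of("one-myosin"))
})

test_that("compiled mechanics agrees with the R implementation", {
  p <- std_params()
  lat <- build_lattice(p, 8, 5)
  withr::with_seed(11, {
    for (i in 1:10) {
      states <- sample(1:3, 5, replace = TRUE)
      partners <- rep(NA_integer_, 5)
      bound <- which(states != 1L)
      if (length(bound)) partners[bound] <- sample(1:8, length(bound))
      xb <- xb_config(states, partners)
      solR <- solve_positions(assemble_system(lat, p, xb))
      solC <- sarcosim:::mechanics_core(
        sarcosim:::lattice_spec_for_core(lat),
        sarcosim:::kinetic_spec_for_core(p),
        as.integer(states), as.integer(partners)
      )
      expect_equal(solC$positions, solR$positions, tolerance = 1e-10)
      expect_equal(solC$external_force, solR$external_force, tolerance = 1e-10)
      expect_equal(solC$energy_internal, solR$energy_internal, tolerance = 1e-8)
      expect_equal(solC$energy_external, solR$energy_external, tolerance = 1e-8)
    }
  })
})
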