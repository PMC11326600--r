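test_that("identical seeds give bit-identical traces", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  cfg <- sim_config(duration = 0.1, seed = 123)
  a <- simulate_sarcomere(lat, p, cfg, quiet = TRUE)
  b <- simulate_sarcomere(lat, p, cfg, quiet = TRUE)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$state, b$state)
  expect_identical(a$positions, b$positions)
})

test_that("all-zero rates freeze the system with no events", {
  p <- std_params()
  lat <- reference_lattice(p, "16-myosin")
  zero <- c(k12 = 0, k21 = 0, k23 = 0, k32 = 0, k31 = 0, k13 = 0)
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 0.02, seed = 1),
                           quiet = TRUE, rate_override = zero)
  expect_true(all(tr$state == 1L))
  expect_equal(nrow(tr$events), 0L)
  expect_equal(max(abs(tr$samples$force)), 0)
  expect_equal(max(tr$samples$energy_internal + tr$samples$energy_external), 0)
})

test_that("binding probability approaches one for large k12*dt", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  only12 <- c(k12 = 1e9, k21 = 0, k23 = 0, k32 = 0, k31 = 0, k13 = 0)
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 1e-3, seed = 3),
                           quiet = TRUE, rate_override = only12)
  # the head binds essentially immediately and stays bound in state 2
  expect_equal(tr$state_time[1, 2] / sum(tr$state_time[1, ]), 1,
               tolerance = 2e-3)
})

test_that("a permanently post-stroke head has duty ratio one", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  to3 <- c(k12 = 0, k21 = 0, k23 = 0, k32 = 0, k31 = 0, k13 = 1e9)
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 1e-3, seed = 5),
                           quiet = TRUE, rate_override = to3)
  expect_equal(glance(tr)$duty_ratio, 1, tolerance = 2e-3)
  expect_gt(glance(tr)$esd, 0)
})

test_that("eligible-node ties break toward the Z-line", {
  p <- std_params()
  # shift the thick filament by half an actin spacing: the head sits exactly
  # between its two flanking binding sites (strains +a0/2 and -a0/2)
  lat <- build_lattice(p, 2, 1, overlap_shift = p$a0 / 2)
  only12 <- c(k12 = 1e9, k21 = 0, k23 = 0, k32 = 0, k31 = 0, k13 = 0)
  tr <- simulate_sarcomere(lat, p,
                           sim_config(duration = 1e-4, seed = 2,
                                      record_stride = 1),
                           quiet = TRUE, rate_override = only12)
  bound_partner <- tr$partner[nrow(tr$partner), 1]
  expect_equal(bound_partner, 1L)
})

test_that("bound-partner map is injective at every sample", {
  p <- std_params()
  lat <- reference_lattice(p, "16-myosin")
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 0.3, seed = 17),
                           quiet = TRUE)
  for (i in seq_len(nrow(tr$partner))) {
    bound <- tr$partner[i, !is.na(tr$partner[i, ])]
    expect_equal(anyDuplicated(bound), 0L)
  }
  # and states always in {1,2,3}, consistent with partners
  expect_true(all(tr$state %in% 1:3))
  expect_true(all((tr$state == 1L) == is.na(tr$partner)))
})

test_that("sliding window reproduces direct convolution", {
  x <- c(rep(0, 20), 1, rep(0, 20))
  t_ <- seq_along(x)
  w <- 7
  sw <- sliding_window(x, w, t_)
  # direct oracle
  direct <- vapply(t_, function(ti) {
    sel <- abs(t_ - ti) <= w / 2
    mean(x[sel])
  }, numeric(1))
  expect_equal(sw, direct)
  expect_equal(max(sw), 1 / 7)
  # constant series unchanged; full-length window collapses to the mean
  expect_equal(sliding_window(rep(3.2, 10), 4, 1:10), rep(3.2, 10))
  expect_equal(sliding_window(1:10, 1e6, 1:10), rep(5.5, 10))
  expect_error(sliding_window(1:10, 0.5, 1:10), "spacing")
})

test_that("plateau rate recovers a constant event rate", {
  withr::with_seed(31, ev <- cumsum(rexp(2000, rate = 100)))
  ev <- ev[ev < 15]
  times <- seq(0, 15, by = 0.01)
  pl <- plateau_rate(ev, times, window = 0.5, t_end = 15)
  expect_equal(pl$plateau, 100, tolerance = 0.1)
  expect_identical(plateau_rate(numeric(0), times)$plateau, NA_real_)
})

test_that("single-myosin occupancies agree with the analytic steady state", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  # 5 x 2e5 steps; blocks give an empirical standard error
  reps <- lapply(1:5, function(s) {
    tr <- simulate_sarcomere(lat, p, sim_config(duration = 2, seed = 400 + s),
                             quiet = TRUE)
    c(occ = tr$state_time[1, ] / sum(tr$state_time[1, ]),
      esd = glance(tr)$esd)
  })
  occ <- do.call(rbind, reps)
  occ_mean <- colMeans(occ[, 1:3])
  occ_se <- apply(occ[, 1:3], 2, sd) / sqrt(nrow(occ))
  an <- steady_state(p, esd = mean(occ[, "esd"]))
  expected <- c(an$p1, an$p2, an$p3)
  for (k in 1:3) {
    expect_lt(abs(occ_mean[k] - expected[k]), 3 * occ_se[k] + 1e-4)
  }
})

test_that("halving dt leaves the duty ratio within replicate error", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  duty_at <- function(dt, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_sarcomere(lat, p,
                               sim_config(duration = 1.5, dt = dt, seed = s),
                               quiet = TRUE)
      glance(tr)$duty_ratio
    }, numeric(1))
  }
  d1 <- duty_at(1e-5, 501:504)
  d2 <- duty_at(5e-6, 601:604)
  se <- sqrt(sd(d1)^2 / length(d1) + sd(d2)^2 / length(d2))
  expect_lt(abs(mean(d1) - mean(d2)), 3 * se)
})

test_that("energy ledgers behave physically", {
  p <- std_params()
  lat <- reference_lattice(p, "one-myosin")
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 1, seed = 77),
                           quiet = TRUE)
  au <- energy_audit(tr)
  # elastic energy never exceeds the full chemical ledger
  expect_true(all(au$energy_elastic <= au$input_total + 1e-9))
  # each net turnover supplies |G1'| of free energy
  g1p <- abs(state_energies(0, p)$G1_prime)
  last <- nrow(au)
  expect_equal(au$input_hydrolysis[last], au$net_events[last] * g1p)
  expect_equal(g1p / p$kbt, 23.925, tolerance = 1e-3)
  # without any transitions there is no work source at all
  zero <- c(k12 = 0, k21 = 0, k23 = 0, k32 = 0, k31 = 0, k13 = 0)
  tr0 <- simulate_sarcomere(lat, p, sim_config(duration = 0.01, seed = 1),
                            quiet = TRUE, rate_override = zero)
  au0 <- energy_audit(tr0)
  expect_equal(max(au0$energy_elastic), 0)
})

test_that("tidiers expose the trace in long and summary form", {
  p <- std_params()
  lat <- reference_lattice(p, "16-myosin")
  tr <- simulate_sarcomere(lat, p, sim_config(duration = 0.05, seed = 8),
                           quiet = TRUE)
  td <- tidy(tr)
  expect_equal(nrow(td), nrow(tr$samples) * 16L)
  expect_true(all(c("time", "myosin", "state", "strain", "force") %in% names(td)))
  g <- glance(tr)
  expect_equal(nrow(g), 1L)
  expect_true(g$duty_ratio >= 0 && g$duty_ratio <= 1)
  expect_gte(g$peak_force_raw, max(0, g$average_force))
  p1 <- autoplot(tr)
  expect_s3_class(p1, "ggplot")
})
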