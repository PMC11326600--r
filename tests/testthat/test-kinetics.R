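test_that("published rate constants are recovered at zero distortion", {
  p <- std_params()
  r <- rate_set(0, p)
  expect_equal(r$k12, 800)                    # attachment prefactor
  expect_equal(r$k23, 30)                     # capped power stroke
  expect_equal(r$k13, 1e-2)                   # reverse hydrolysis
  expect_equal(r$k21, 800 * exp(-4), tolerance = 1e-12)
  # strain-independent rates stay put at any distortion
  r5 <- rate_set(5.3, p)
  expect_equal(r5$k23, 30)
  expect_equal(r5$k13, 1e-2)
})

test_that("state free energies match independent evaluation", {
  # at reference concentrations (1 M) and zero strain:
  # G2 = dG_bind; G3 = dG_bind + dG_stroke - dG_DPi,rel + kxb*d_ps^2/2
  p_ref <- sarcomere_params(conc_atp = 1, conc_adp = 1, conc_pi = 1)
  se <- state_energies(0, p_ref)
  expect_equal(se$G1, 0)
  expect_equal(se$G2 / p_ref$kbt, -4)
  g3_expected <- (-4 - 4.5 + 14) + 0.5 * 3 * 49 / 4.14   # 23.2536... kBT
  expect_equal(se$G3 / p_ref$kbt, g3_expected, tolerance = 1e-12)

  # standard concentrations: G1' = -dG_hyd - kBT ln([ATP]/([ADP][Pi]))
  p <- std_params()
  g1p_expected <- -13 - log(5e-3 / (3e-5 * 3e-3))        # -23.925... kBT
  expect_equal(state_energies(2, p)$G1_prime / p$kbt, g1p_expected,
               tolerance = 1e-12)
  # G1' is strain independent
  expect_equal(state_energies(-5, p)$G1_prime,
               state_energies(9, p)$G1_prime)
})

test_that("rates satisfy detailed balance against the energy landscape", {
  p <- std_params()
  withr::with_seed(42, strains <- runif(50, -12, 12))
  r <- rate_set(strains, p)
  se <- state_energies(strains, p)
  beta <- 1 / p$kbt
  expect_equal(r$k12 / r$k21, exp(-beta * (se$G2 - se$G1)), tolerance = 1e-12)
  expect_equal(r$k23 / r$k32, exp(-beta * (se$G3 - se$G2)), tolerance = 1e-12)
  expect_equal(r$k31 / r$k13, exp(-beta * (se$G1_prime - se$G3)),
               tolerance = 1e-12)
  # the attachment barrier sits halfway up the elastic well: forward rate
  # carries a quarter of the elastic penalty
  expect_equal(r$k12, p$k_bind * exp(-beta * 0.25 * p$k_xb * strains^2),
               tolerance = 1e-12)
})

test_that("cycle reaction quotient is strain independent and closed form", {
  p_ref <- sarcomere_params(conc_atp = 1, conc_adp = 1, conc_pi = 1)
  q_ref <- reaction_quotient(rate_set(0, p_ref))
  expect_equal(q_ref, exp(13), tolerance = 1e-12)

  p <- std_params()
  expect_equal(reaction_quotient(rate_set(0, p)),
               5e-3 / (3e-5 * 3e-3) * exp(13), tolerance = 1e-12)

  withr::with_seed(7, strains <- runif(100, -15, 15))
  q <- reaction_quotient(rate_set(strains, p))
  expect_lt(diff(range(q)) / mean(q), 1e-10)

  # linear in [ATP]
  p10 <- set_concentrations(p, atp = p$conc_atp * 10)
  expect_equal(reaction_quotient(rate_set(1.3, p10)),
               10 * reaction_quotient(rate_set(1.3, p)), tolerance = 1e-12)
})

test_that("each rate depends only on its relevant metabolite", {
  p <- std_params()
  p_atp <- set_concentrations(p, atp = p$conc_atp * 7)
  p_adppi <- set_concentrations(p, adppi = 10 * p$conc_adp * p$conc_pi)
  s <- 2.4
  r <- rate_set(s, p); r_atp <- rate_set(s, p_atp); r_pp <- rate_set(s, p_adppi)
  # k31 responds to [ATP] only, linearly
  expect_equal(r_atp$k31, 7 * r$k31, tolerance = 1e-12)
  expect_equal(r_atp[c("k12", "k21", "k23", "k32", "k13")],
               r[c("k12", "k21", "k23", "k32", "k13")])
  # k32 responds to the [ADP][Pi] product only, linearly
  expect_equal(r_pp$k32, 10 * r$k32, tolerance = 1e-12)
  expect_equal(r_pp[c("k12", "k21", "k23", "k31", "k13")],
               r[c("k12", "k21", "k23", "k31", "k13")])
  # doubling ADP at fixed Pi and vice versa act identically
  ra <- rate_set(s, set_concentrations(p, adp = 2 * p$conc_adp))
  rb <- rate_set(s, set_concentrations(p, pi = 2 * p$conc_pi))
  expect_equal(ra$k32, rb$k32, tolerance = 1e-12)
})

test_that("equilibrium constants are consistent with the rate ratios", {
  p <- std_params()
  r <- rate_set(c(-6, 0, 3.7), p)
  expect_equal(r$K12, r$k12 / r$k21, tolerance = 1e-12)
  expect_equal(r$K23, r$k23 / r$k32, tolerance = 1e-12)
  expect_equal(r$K31, r$k31 / r$k13, tolerance = 1e-12)
})
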