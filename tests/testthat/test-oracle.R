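test_that("well-mixed oracle matches closed-form first-order decay", {
  times <- seq(0, 2e-6, length.out = 11)
  only_o <- pick_reactions("O- + H2O -> OH + OH-")
  out <- integrate_wellmixed(c("O-" = 1e-6), only_o, reg_fix, times)
  o <- out$concentration[out$species == "O-"]
  expect_equal(o, 1e-6 * exp(-1.36e6 * times), tolerance = 1e-6)
  # products appear with matching stoichiometry
  oh <- out$concentration[out$species == "OH"]
  expect_equal(oh, 1e-6 - o, tolerance = 1e-6)
})

test_that("well-mixed oracle matches closed-form second-order decay under the A+A convention", {
  rxx <- pick_reactions("OH + OH -> H2O2")
  a0 <- 1e-3
  times <- seq(0, 3e-7, length.out = 13)
  out <- integrate_wellmixed(c(OH = a0), rxx, reg_fix, times)
  oh <- out$concentration[out$species == "OH"]
  # d[A]/dt = -2k[A]^2  =>  [A](t) = A0 / (1 + 2 k A0 t)
  expect_equal(oh, a0 / (1 + 2 * 5.5e9 * a0 * times), tolerance = 1e-6)
  h2o2 <- out$concentration[out$species == "H2O2"]
  expect_equal(h2o2, (a0 - oh) / 2, tolerance = 1e-6)

  # the alternative convention halves the event rate
  rxk1 <- reaction_table(reg_fix, aa_convention = "k1")
  rxk1 <- rxk1[rxk1$reaction == "OH + OH -> H2O2", ]
  attr(rxk1, "aa_convention") <- "k1"
  out2 <- integrate_wellmixed(c(OH = a0), rxk1, reg_fix, times)
  oh2 <- out2$concentration[out2$species == "OH"]
  expect_equal(oh2, a0 / (1 + 5.5e9 * a0 * times), tolerance = 1e-6)
})

test_that("oracle edge cases: zero state stays zero; bad input is rejected", {
  times <- seq(0, 1e-6, length.out = 5)
  out <- integrate_wellmixed(c(OH = 0), rx_fix, reg_fix, times)
  expect_true(all(out$concentration == 0))
  expect_error(integrate_wellmixed(c(Nope = 1e-3), rx_fix, reg_fix, times),
               "unknown species")
  expect_error(integrate_wellmixed(c(OH = -1), rx_fix, reg_fix, times),
               ">= 0")
})

test_that("full-network oracle conserves charge and stays non-negative", {
  times <- c(0, 10^seq(-12, -6, length.out = 25))
  init <- c("e_aq-" = 2e-4, "OH" = 2.4e-4, "H3O+" = 2e-4, "H" = 2e-5,
            "H2" = 1e-5, "OH-" = 1e-5)
  out <- integrate_wellmixed(init, rx_fix, reg_fix, times)
  expect_true(all(out$concentration >= 0))
  charge <- reg_fix$charge[match(out$species, reg_fix$species)]
  net <- tapply(out$concentration * charge, out$time, sum)
  expect_equal(max(abs(net - net[1])), 0, tolerance = 1e-10)
})

test_that("uniformly seeded BD matches the oracle trajectory in the well-mixed limit", {
  set.seed(31)
  rxx <- pick_reactions("OH + OH -> H2O2")
  bp <- box_pop("OH", 1200, 1e-3)
  times <- seq(0, 1e-7, length.out = 9)
  res <- simulate_bd(bp$pop, rxx, reg_fix, times,
                     config = chem_config(dt_min = 8e-12, dt_max = 8e-12,
                                          box_nm = bp$box_nm,
                                          adaptive = FALSE))
  cc <- res$counts[res$counts$species == "OH", ]
  oracle <- integrate_wellmixed(c(OH = 1e-3), rxx, reg_fix, times)
  o <- oracle$concentration[oracle$species == "OH"]
  sim_conc <- cc$count / (6.02214076e23 * bp$volume_dm3)
  # Monte-Carlo error ~ sqrt(count); allow 4 sigma plus 5% discretization
  tol <- 4 * sqrt(cc$count) / (6.02214076e23 * bp$volume_dm3) + 0.05 * o
  expect_true(all(abs(sim_conc - o) < tol))
})
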