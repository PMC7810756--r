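test_that("default network has every tabulated reaction with its rate constant", {
  expect_equal(nrow(rx_fix), 33L)
  expect_equal(sum(rx_fix$order == 1L), 2L)
  k_of <- function(lbl) rx_fix$k[rx_fix$reaction == lbl]
  expect_equal(k_of("OH + OH -> H2O2"), 5.5e9)
  expect_equal(k_of("e_aq- + O2 -> O2-"), 1.74e10)
  expect_equal(k_of("O- + H2O -> OH + OH-"), 1.36e6)
  expect_equal(k_of("HO2- + H2O -> H2O2 + OH-"), 1.36e6)
  expect_equal(k_of("H3O+ + OH- -> (H2O)"), 1.13e11)
  expect_equal(k_of("HO2 + HO2 -> O2 + H2O2"), 8.3e5)
})

test_that("every reaction balances charge and atoms via an integer water ledger", {
  bal <- check_balance(rx_fix, reg_fix)
  expect_true(all(bal$balanced))
  w_of <- function(lbl) bal$implicit_water[bal$reaction == lbl]
  # H + OH -> nothing: one water produced
  expect_equal(w_of("H + OH -> (H2O)"), 1L)
  # e_aq- + e_aq- -> 2 OH- + H2: two waters consumed
  expect_equal(w_of("e_aq- + e_aq- -> OH- + OH- + H2"), -2L)
  # H + O2 -> HO2: no implicit water
  expect_equal(w_of("H + O2 -> HO2"), 0L)
  # first-order entries consume exactly their one implicit water
  expect_equal(w_of("O- + H2O -> OH + OH-"), -1L)
})

test_that("check_balance flags an unbalanceable reaction", {
  broken <- tibble::tibble(reactant1 = "H", reactant2 = "H",
                           products = "H2O2", k = 1e9, order = 2L,
                           reaction = "H + H -> H2O2")
  bal <- check_balance(broken, reg_fix)
  expect_false(bal$balanced)
})

test_that("encounter radii invert the Smoluchowski relation", {
  r_of <- function(lbl) rx_fix$encounter_radius[rx_fix$reaction == lbl]
  # H + OH: k = 1.55e10, D' = 9.8e-9 m^2/s -> 0.209 nm (direct arithmetic)
  k_pair <- 1.55e10 / (1e3 * 6.02214076e23) * 1e27   # nm^3/s
  expect_equal(r_of("H + OH -> (H2O)"), k_pair / (4 * pi * 9.8e9),
               tolerance = 1e-12)
  expect_equal(round(r_of("H + OH -> (H2O)"), 3), 0.209)
  # slow partially diffusion-controlled reaction gets a much smaller radius
  expect_lt(r_of("OH + H2O2 -> HO2"), r_of("H + OH -> (H2O)") * 1e-2)
  # monotone in k at fixed diffusion coefficients
  fake <- rx_fix[rep(which(rx_fix$reaction == "H + OH -> (H2O)"), 3), ]
  fake$k <- c(1e8, 1e9, 1e10)
  rr <- encounter_radii(fake, reg_fix)$encounter_radius
  expect_true(all(diff(rr) > 0))
  expect_equal(encounter_radii(dplyr::mutate(fake[1, ], k = 0),
                               reg_fix)$encounter_radius, 0)
  # first-order entries have no radius
  expect_true(all(is.na(rx_fix$encounter_radius[rx_fix$order == 1L])))
})

test_that("identical-reactant convention switches the radius consistently", {
  rx2 <- reaction_table(reg_fix, aa_convention = "k1")
  lbl <- "OH + OH -> H2O2"
  expect_equal(rx2$encounter_radius[rx2$reaction == lbl] * 2,
               rx_fix$encounter_radius[rx_fix$reaction == lbl])
  # distinct pairs unaffected
  lbl2 <- "H + O2 -> HO2"
  expect_equal(rx2$encounter_radius[rx2$reaction == lbl2],
               rx_fix$encounter_radius[rx_fix$reaction == lbl2])
})

test_that("reaction table rejects unknown species and mismatched orders", {
  bad <- trackchem:::default_reactions()
  bad$reactant1[1] <- "Xx"
  expect_error(trackchem:::validate_reactions(bad, reg_fix), "unknown species")
  bad2 <- trackchem:::default_reactions()
  bad2$order[1] <- 1L
  expect_error(trackchem:::validate_reactions(bad2, reg_fix), "order")
})
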