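test_that("branching probabilities are the tabulated ones and normalize per event type", {
  p_of <- function(tp, prods) {
    br_fix$probability[br_fix$event_type == tp & br_fix$products == prods]
  }
  expect_equal(p_of("ionization", "H3O+,OH,e_aq-"), 1)
  expect_equal(p_of("excitation_a1b1", "OH,H"), 0.65)
  expect_equal(p_of("excitation_a1b1", ""), 0.35)
  expect_equal(p_of("excitation_b1a1", "H3O+,OH,e_aq-"), 0.55)
  expect_equal(p_of("excitation_b1a1", "OH,OH,H2"), 0.15)
  expect_equal(p_of("excitation_b1a1", ""), 0.30)
  expect_equal(p_of("excitation_rydberg", "H3O+,OH,e_aq-"), 0.5)
  expect_equal(p_of("attachment", "OH,OH-,H2"), 1)
  sums <- tapply(br_fix$probability, br_fix$event_type, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("sampled channel frequencies match the branching ratios within binomial error", {
  set.seed(101)
  n <- 20000L
  cases <- list(
    c("excitation_a1b1", "OH,H", 0.65),
    c("excitation_b1a1", "H3O+,OH,e_aq-", 0.55),
    c("excitation_b1a1", "", 0.30),
    c("excitation_rydberg", "H3O+,OH,e_aq-", 0.50)
  )
  for (cs in cases) {
    p <- as.numeric(cs[3])
    frac <- mean(sample_channel(cs[1], n, br_fix) == cs[2])
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_true(all(sample_channel("ionization", 100) == "H3O+,OH,e_aq-"))
  expect_true(all(sample_channel("attachment", 100) == "OH,OH-,H2"))
  expect_error(sample_channel("nope", 1), "unknown event type")
})

test_that("product placement follows the configured displacement rules", {
  set.seed(5)
  ev <- tibble::tibble(x = 1, y = 2, z = 3, event_type = "ionization")
  # degenerate zero-displacement rule puts everything at the event position
  cfg0 <- track_config(thermalization_mean_nm = 0, fragment_sep_nm = 0)
  pop0 <- place_products(ev[rep(1, 20), ], reg_fix, br_fix, cfg0)
  expect_true(all(pop0$x == 1 & pop0$y == 2 & pop0$z == 3))

  # hydrated electrons thermalize at the configured mean distance
  cfg <- track_config(thermalization_mean_nm = 5, fragment_sep_nm = 0.3)
  pope <- place_products(ev[rep(1, 4000), ], reg_fix, br_fix, cfg)
  e <- pope[pope$species == "e_aq-", ]
  d <- sqrt((e$x - 1)^2 + (e$y - 2)^2 + (e$z - 3)^2)
  expect_equal(mean(d), 5, tolerance = 0.1)
  # heavy fragments sit at the fixed sub-nanometer separation
  h <- pope[pope$species == "OH", ]
  dh <- sqrt((h$x - 1)^2 + (h$y - 2)^2 + (h$z - 3)^2)
  expect_true(all(abs(dh - 0.3) < 1e-9))

  # relaxation channels produce nothing
  evr <- tibble::tibble(x = 0, y = 0, z = 0,
                        event_type = "excitation_a1b1")
  set.seed(1)
  popr <- place_products(evr[rep(1, 500), ], reg_fix, br_fix, cfg)
  expect_lt(nrow(popr) / 2, 500)  # some A1B1 events relax to water
  expect_setequal(unique(popr$species), c("OH", "H"))
})

test_that("initial populations contain only species producible by the dissociation table", {
  set.seed(42)
  seg <- generate_segment(ion_spec("C", let = 50))
  pop <- initial_population(seg, reg_fix, br_fix)
  expect_true(all(pop$species %in%
                    c("e_aq-", "OH", "H", "H2", "H3O+", "OH-")))
  # no secondary products (O2, HO2, ...) exist at 1 ps
  expect_false(any(pop$species %in% c("O2", "O2-", "HO2", "HO2-", "O-")))
})
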