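test_that("gvalue implements molecules per 100 eV", {
  expect_equal(gvalue(7, 100), 7)
  expect_equal(gvalue(0, 5000), 0)
  expect_equal(gvalue(250, 10000), 2.5)
  expect_error(gvalue(1, 0), "> 0")
})

test_that("track-yield series start at 100 * initial count / deposit and carry SEMs", {
  set.seed(41)
  ion <- ion_spec("C", let = 400)
  gs <- simulate_track_yields(ion, n_tracks = 6, engine = "irt",
                              times = c(1e-12, 1e-8, 1e-6),
                              keep_results = TRUE)
  expect_s3_class(gs, "gvalue_series")
  expect_true(all(gs$g >= 0))
  # G at 1 ps equals the initial population scaled by the deposit
  results <- attr(gs, "results")
  g_oh_1ps <- mean(vapply(results, function(r) {
    100 * sum(r$initial$species == "OH") / attr(gs, "e_dep")
  }, numeric(1)))
  expect_equal(gs$g[gs$species == "OH" & gs$time == 1e-12], g_oh_1ps,
               tolerance = 0.02)
  expect_true(all(is.finite(gs$sem)))
})

test_that("yield-curve accumulation integrates a synthetic constant G' exactly", {
  ion <- ion_spec("H", let = 26)
  curve <- integrate_segment_yields(ion, e_max = 10, de = 0.25,
                                    times = 1e-7,
                                    yield_fn = function(e, t) 2.5)
  # N(E_max) = G'/100 * E_max_in_eV = 2.5e-2 * 1e7 = 2.5e5 molecules
  expect_equal(max(curve$n), 2.5 / 100 * 10 * 1e6, tolerance = 1e-12)
  # single step: N(de) is that step's dN
  expect_equal(curve$n[curve$energy == 0.25], 2.5 / 100 * 0.25e6)
  # linearity: doubling G' doubles N everywhere
  curve2 <- integrate_segment_yields(ion, e_max = 10, de = 0.25,
                                     times = 1e-7,
                                     yield_fn = function(e, t) 5)
  expect_equal(curve2$n, 2 * curve$n)
  expect_error(integrate_segment_yields(ion, e_max = 1.1, de = 0.25,
                                        yield_fn = function(e, t) 1),
               "multiple")
})

test_that("differentiation recovers G' from N(E): linear, round-trip and quadratic cases", {
  ion <- ion_spec("H", let = 26)
  # constant G' -> exact recovery by central differences
  curve <- integrate_segment_yields(ion, e_max = 6, de = 0.25, times = 1e-7,
                                    yield_fn = function(e, t) 2.5)
  rt <- differentiate_to_gprime(curve)
  expect_equal(rt$gprime_est, rep(2.5, nrow(rt)), tolerance = 1e-9)
  # quadratic N <=> linear G': interior points exact for central scheme
  curveq <- integrate_segment_yields(ion, e_max = 6, de = 0.25, times = 1e-7,
                                     yield_fn = function(e, t) 1 + 0.5 * e)
  rtq <- differentiate_to_gprime(curveq)
  inner <- rtq$energy > 0.25 & rtq$energy < 6
  # N accumulates g at the right edge of each 0.25 MeV/u step, so central
  # differences recover the integrand half a step above the grid point
  expect_equal(rtq$gprime_est[inner], 1 + 0.5 * (rtq$energy[inner] + 0.125),
               tolerance = 1e-6)
  # spline variant agrees with the central scheme away from the ends
  rts <- differentiate_to_gprime(curveq, method = "spline")
  expect_equal(rts$gprime_est[inner], rtq$gprime_est[inner], tolerance = 0.05)
  expect_error(differentiate_to_gprime(curve[curve$energy < 0.6, ]),
               "3 energy points")
})

test_that("differentiation warns on non-monotone N", {
  ion <- ion_spec("H", let = 26)
  curve <- integrate_segment_yields(ion, e_max = 2, de = 0.25, times = 1e-7,
                                    yield_fn = function(e, t) 1)
  curve$n[5] <- curve$n[5] * 0.5
  expect_warning(differentiate_to_gprime(curve), "decreases")
})

test_that("reaction-count profiles respond to LET and vanish without reactions", {
  set.seed(43)
  prof0 <- reaction_count_profile("C", lets = c(50), n_tracks = 2,
                                  reactions = no_reactions())
  expect_true(all(prof0$count == 0))
  prof <- reaction_count_profile("C", lets = c(10, 300), n_tracks = 4)
  ohoh <- prof[prof$reaction == "OH + OH -> H2O2", ]
  expect_gte(ohoh$count[ohoh$let == 300], ohoh$count[ohoh$let == 10])
})

test_that("rate-fit objects expose broom-style tidy and glance", {
  set.seed(44)
  df <- tibble::tibble(time = seq(0, 1e-6, length.out = 10))
  df$survival <- exp(-1.5e6 * df$time) * exp(rnorm(10, 0, 0.01))
  f <- fit_first_order(df)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate, 1.5e6, tolerance = 0.05)
  gl <- glance(f)
  expect_true(all(c("estimate", "r.squared", "nobs") %in% names(gl)))
  # second-order fit on exact analytic counts
  v <- 1e-18
  a0 <- 500 / (6.02214076e23 * v)
  tt <- seq(0, 1e-7, length.out = 8)
  counts <- 500 / (1 + 2 * 5.5e9 * a0 * tt) * exp(rnorm(8, 0, 1e-4))
  f2 <- fit_second_order(tibble::tibble(time = tt, count = counts), v)
  expect_equal(f2$k, 5.5e9, tolerance = 1e-3)
})

test_that("autoplot methods return ggplot objects", {
  set.seed(45)
  gs <- simulate_track_yields(ion_spec("C", let = 400), n_tracks = 2,
                              times = c(1e-12, 1e-6))
  expect_s3_class(autoplot(gs), "ggplot")
  curve <- integrate_segment_yields(ion_spec("H", let = 26), e_max = 2,
                                    de = 0.25, times = 1e-7,
                                    yield_fn = function(e, t) 2)
  expect_s3_class(autoplot(curve), "ggplot")
  pop <- isolated_pop("O-", 5)
  res <- simulate_irt(pop, pick_reactions("O- + H2O -> OH + OH-"), reg_fix)
  expect_s3_class(autoplot(res), "ggplot")
})
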