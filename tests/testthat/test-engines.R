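test_that("diffusion-only BD reproduces MSD = 6 D tau for every species", {
  set.seed(21)
  n_per <- 120L
  pop <- tibble::tibble(species = rep(reg_fix$species, each = n_per),
                        x = 0, y = 0, z = 0)
  tau <- 1e-9
  res <- simulate_bd(pop, no_reactions(), reg_fix, times = c(1e-12, tau),
                     config = chem_config(dt_min = 1e-11, dt_max = 1e-11,
                                          record_positions = TRUE))
  snap <- res$snapshots[[length(res$snapshots)]]
  sp_names <- reg_fix$species[snap$species + 1]
  for (sp in reg_fix$species) {
    idx <- sp_names == sp
    msd <- mean(rowSums(snap$pos[idx, , drop = FALSE]^2))
    d <- reg_fix$diff_coef[reg_fix$species == sp] * 1e9
    # mean of n_per chi2-ish terms: ~sqrt(2/3/n) relative sd
    expect_equal(msd, 6 * d * tau, tolerance = 4 * sqrt(2 / (3 * n_per)))
  }
  # counts constant with no reactions
  cc <- res$counts
  expect_true(all(tapply(cc$count, cc$species, function(x)
    length(unique(x))) == 1))
})

test_that("both engines reproduce a first-order survival law", {
  set.seed(22)
  only_o <- pick_reactions("O- + H2O -> OH + OH-")
  n <- 4000L
  pop <- isolated_pop("O-", n)
  times <- c(1e-12, 5e-7)
  for (sim in list(simulate_irt,
                   function(...) simulate_bd(...))) {
    res <- sim(pop, only_o, reg_fix, times)
    surv <- count_at(res, "O-", 5e-7) / n
    p <- exp(-1.36e6 * 5e-7)
    expect_equal(surv, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
  }
})

test_that("distant pairs never react and contact pairs react immediately (IRT)", {
  set.seed(23)
  rxx <- pick_reactions("OH + OH -> H2O2")
  r_enc <- rxx$encounter_radius
  # far beyond the 1 us diffusion length
  far <- tibble::tibble(species = c("OH", "OH"), x = c(0, 5e4), y = 0, z = 0)
  hits <- 0
  for (i in 1:200) {
    hits <- hits + nrow(simulate_irt(far, rxx, reg_fix,
                                     times = c(1e-12, 1e-6))$events)
  }
  expect_equal(hits, 0)
  # in contact: reaction probability 1, at essentially t_start
  touch <- tibble::tibble(species = c("OH", "OH"),
                          x = c(0, 0.5 * r_enc), y = 0, z = 0)
  res <- simulate_irt(touch, rxx, reg_fix, times = c(1e-12, 1e-6))
  expect_equal(nrow(res$events), 1L)
  expect_lt(res$events$time, 2e-12)
})

test_that("species counts are exactly the initial population plus fired stoichiometry", {
  set.seed(24)
  seg <- generate_segment(ion_spec("C", let = 200))
  pop <- initial_population(seg, reg_fix, br_fix)
  res <- simulate_irt(pop, rx_fix, reg_fix)
  # independent reconstruction at the final time
  ev <- res$events
  prods <- trackchem:::split_products(res$reactions$products)
  delta <- setNames(numeric(nrow(reg_fix)), reg_fix$species)
  for (r in seq_len(nrow(ev))) {
    i <- ev$reaction[r]
    delta[res$reactions$reactant1[i]] <- delta[res$reactions$reactant1[i]] - 1
    if (!is.na(res$reactions$reactant2[i])) {
      delta[res$reactions$reactant2[i]] <- delta[res$reactions$reactant2[i]] - 1
    }
    for (p in prods[[i]]) delta[p] <- delta[p] + 1
  }
  init <- table(factor(pop$species, levels = reg_fix$species))
  expected <- as.numeric(init) + delta
  got <- species_counts(res, 1e-6)
  expect_equal(got$count, unname(expected[got$species]))
  # and the ledger matches the surviving molecules
  alive <- table(factor(res$final$species[res$final$alive],
                        levels = reg_fix$species))
  expect_equal(got$count, as.numeric(alive[got$species]))
  # reaction counts never decrease
  rc <- reaction_counts(res, res$times)
  expect_true(all(tapply(rc$count, rc$reaction,
                         function(x) all(diff(x) >= 0))))
})

test_that("total charge is conserved through the full network", {
  set.seed(25)
  seg <- generate_segment(ion_spec("He", let = 80))
  pop <- initial_population(seg, reg_fix, br_fix)
  for (res in list(simulate_irt(pop, rx_fix, reg_fix),
                   simulate_bd(pop, rx_fix, reg_fix,
                               times = c(1e-12, 1e-9, 1e-6)))) {
    cc <- res$counts
    charge <- reg_fix$charge[match(cc$species, reg_fix$species)]
    net <- tapply(cc$count * charge, cc$time, sum)
    expect_equal(unname(diff(range(net))), 0)
  }
})

test_that("scavenging follows the exponential capacity law and its limits", {
  set.seed(26)
  n <- 3000L
  pop <- isolated_pop("OH", n)
  # capacity 0 == no scavenging
  res0 <- simulate_irt(pop, no_reactions(), reg_fix,
                       scavengers = scavenger_config("OH", 0))
  expect_equal(nrow(res0$scavenged), 0L)
  # finite capacity: scavenged fraction = 1 - exp(-s t)
  s <- 2e7
  res <- simulate_irt(pop, no_reactions(), reg_fix, times = c(1e-12, 1e-6),
                      scavengers = scavenger_config("OH", s))
  for (tt in c(5e-8, 2e-7)) {
    frac <- scavenged_counts(res, tt)
    frac <- frac$count[frac$species == "OH"] / n
    p <- 1 - exp(-s * tt)
    expect_equal(frac, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
  }
  # huge capacity: everything is scavenged almost immediately
  resb <- simulate_irt(pop, no_reactions(), reg_fix, times = c(1e-12, 1e-6),
                       scavengers = scavenger_config("OH", 1e12))
  expect_equal(count_at(resb, "OH", 1e-9), 0)
  expect_error(scavenger_config("OH", -1), "capacity")
})

test_that("runs are reproducible under a fixed seed", {
  seg <- withr::with_seed(27, generate_segment(ion_spec("C", let = 300)))
  pop <- withr::with_seed(27, initial_population(seg, reg_fix, br_fix))
  r1 <- withr::with_seed(99, simulate_irt(pop, rx_fix, reg_fix))
  r2 <- withr::with_seed(99, simulate_irt(pop, rx_fix, reg_fix))
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
  b1 <- withr::with_seed(98, simulate_bd(pop, rx_fix, reg_fix,
                                         times = c(1e-12, 1e-8)))
  b2 <- withr::with_seed(98, simulate_bd(pop, rx_fix, reg_fix,
                                         times = c(1e-12, 1e-8)))
  expect_identical(b1$events, b2$events)
})

test_that("engine argument checking catches malformed input", {
  pop <- isolated_pop("OH", 2)
  raw <- trackchem:::default_reactions()
  expect_error(simulate_irt(pop, raw, reg_fix), "reaction_table")
  bad_pop <- pop
  bad_pop$species[1] <- "Qq"
  expect_error(simulate_irt(bad_pop, rx_fix, reg_fix), "unregistered")
  expect_error(simulate_irt(pop, rx_fix, reg_fix,
                            config = chem_config(box_nm = 10)), "box")
  inf_pop <- pop
  inf_pop$x[1] <- Inf
  expect_error(simulate_bd(inf_pop, rx_fix, reg_fix), "finite")
})
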