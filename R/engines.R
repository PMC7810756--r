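#' Logarithmic time grid for the chemical stage
#'
#' @param t_min,t_max Grid limits in seconds (default 1 ps to 1 us, the
#'   span of the simulated radical annihilation process).
#' @param points_per_decade Grid density.
#' @return Numeric vector of times (s), increasing, including both limits.
#' @export
time_grid <- function(t_min = 1e-12, t_max = 1e-6, points_per_decade = 8) {
  stopifnot(t_min > 0, t_max > t_min)
  n <- ceiling(log10(t_max / t_min) * points_per_decade) + 1
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

#' Chemistry engine configuration
#'
#' @param dt_min,dt_max,dt_growth Brownian-dynamics step schedule: the step
#'   at elapsed time t is `min(dt_max, max(dt_min, dt_growth * t))`, i.e.
#'   logarithmically growing from `dt_min` (default 0.1 ps) to `dt_max`
#'   (default 10 ns).  Pass `dt_min = dt_max` for a fixed step.
#' @param box_nm Periodic box edge in nm for homogeneous validation runs;
#'   `NULL` (default) simulates in open space, as appropriate for track
#'   segments.
#' @param bridge Apply the Brownian-bridge encounter test within each BD
#'   step (probability `exp(-(d0-R)(d1-R)/(D' dt))` of an unobserved
#'   crossing) in addition to the end-of-step overlap test.  Without it the
#'   growing step length systematically misses encounters.
#' @param adaptive Dynamically cap the BD step so that no reactive pair is
#'   likely to diffuse across its gap within one step (the step-by-step
#'   analogue of dynamic time stepping); essential for accuracy at late
#'   times when the schedule step is large.
#' @param adaptive_factor Safety factor C in the cap
#'   dt <= gap^2 / (C D'_max); larger is more conservative.
#' @param record_positions Record molecule positions at every output time
#'   (BD only); needed for displacement statistics, off by default.
#' @param step_warn_factor Warn when the BD step length exceeds this
#'   multiple of the largest encounter radius while the bridge correction is
#'   disabled.
#' @return List of class `chem_config`.
#' @export
chem_config <- function(dt_min = 1e-13, dt_max = 1e-8, dt_growth = 0.05,
                        box_nm = NULL, bridge = TRUE, adaptive = TRUE,
                        adaptive_factor = 16,
                        record_positions = FALSE, step_warn_factor = 1) {
  stopifnot(dt_min > 0, dt_max >= dt_min, dt_growth >= 0,
            adaptive_factor > 0)
  structure(list(dt_min = dt_min, dt_max = dt_max, dt_growth = dt_growth,
                 box_nm = box_nm, bridge = bridge, adaptive = adaptive,
                 adaptive_factor = adaptive_factor,
                 record_positions = record_positions,
                 step_warn_factor = step_warn_factor),
            class = "chem_config")
}

#' Scavenger configuration
#'
#' A scavenger at concentration \[S\] removing species X with rate constant
#' k acts as a first-order sink with scavenging capacity k\[S\] (s^-1); its
#' inverse is the mean scavenging time.  Scavenged molecules are recorded
#' separately so time-resolved scavenged yields can emulate probe
#' experiments.
#'
#' @param species Character vector of targeted species names.
#' @param capacity Scavenging capacities k\[S\] in s^-1 (recycled).
#' @return Tibble with columns `species`, `capacity`.
#' @export
scavenger_config <- function(species, capacity) {
  stopifnot(length(species) >= 1)
  if (any(capacity < 0)) stop("scavenging capacity must be >= 0",
                              call. = FALSE)
  tibble::tibble(species = species, capacity = as.double(capacity))
}

# Flatten population, registry, reactions and scavengers into the
# index-based vectors the C++ engines consume.
engine_inputs <- function(pop, reactions, registry, scavengers) {
  ns <- nrow(registry)
  sp_idx <- match(pop$species, registry$species)
  if (anyNA(sp_idx)) {
    stop("population contains unregistered species: ",
         paste(unique(pop$species[is.na(sp_idx)]), collapse = ", "),
         call. = FALSE)
  }
  pos <- cbind(pop$x, pop$y, pop$z)
  if (nrow(pop) > 0L && any(!is.finite(pos))) {
    stop("positions must be finite", call. = FALSE)
  }

  nrx <- nrow(reactions)
  pair_rx <- matrix(-1L, ns, ns)
  rx_radius <- numeric(nrx)
  rx_prod <- matrix(-1L, max(nrx, 1L), 3L)
  unary_rx <- vector("list", ns)
  unary_rate <- vector("list", ns)
  for (s in seq_len(ns)) {
    unary_rx[[s]] <- integer()
    unary_rate[[s]] <- numeric()
  }
  prods <- split_products(reactions$products)
  for (r in seq_len(nrx)) {
    pr <- match(prods[[r]], registry$species) - 1L
    if (length(pr) > 0L) rx_prod[r, seq_along(pr)] <- pr
    if (reactions$order[r] == 2L) {
      i <- match(reactions$reactant1[r], registry$species)
      j <- match(reactions$reactant2[r], registry$species)
      if (pair_rx[i, j] >= 0L) {
        stop("multiple reactions for species pair ",
             reactions$reactant1[r], " + ", reactions$reactant2[r],
             call. = FALSE)
      }
      pair_rx[i, j] <- r - 1L
      pair_rx[j, i] <- r - 1L
      rx_radius[r] <- reactions$encounter_radius[r]
    } else {
      i <- match(reactions$reactant1[r], registry$species)
      unary_rx[[i]] <- c(unary_rx[[i]], r - 1L)
      unary_rate[[i]] <- c(unary_rate[[i]], reactions$k[r])
    }
  }

  scav <- numeric(ns)
  if (!is.null(scavengers) && nrow(scavengers) > 0L) {
    i <- match(scavengers$species, registry$species)
    if (anyNA(i)) stop("scavenger targets unknown species", call. = FALSE)
    scav[i] <- scav[i] + scavengers$capacity
  }

  list(pos = pos, sp0 = sp_idx - 1L, D = registry$diff_coef * 1e9,
       pair_rx = pair_rx, rx_radius = rx_radius, rx_prod = rx_prod,
       unary_rx = unary_rx, unary_rate = unary_rate, scav = scav)
}

make_result <- function(raw, pop, reactions, registry, times, engine,
                        config) {
  final <- tibble::tibble(
    species = registry$species[raw$species + 1L],
    x = raw$pos[, 1], y = raw$pos[, 2], z = raw$pos[, 3],
    alive = raw$alive
  )
  res <- structure(list(
    engine = engine,
    times = times,
    initial = pop,
    events = tibble::tibble(time = raw$event_time,
                            reaction = raw$event_rx + 1L),
    scavenged = tibble::tibble(time = raw$scav_time,
                               species = registry$species[raw$scav_species + 1L]),
    final = final,
    snapshots = raw$snapshots,
    reactions = reactions,
    registry = registry,
    config = config
  ), class = "chemistry_result")
  res$counts <- species_counts(res)
  res
}

check_chem_args <- function(pop, reactions, registry, times) {
  stopifnot(is.data.frame(pop),
            all(c("species", "x", "y", "z") %in% names(pop)))
  if (is.null(attr(reactions, "aa_convention"))) {
    stop("reactions must come from reaction_table()", call. = FALSE)
  }
  if (length(times) < 1L || is.unsorted(times)) {
    stop("times must be an increasing vector", call. = FALSE)
  }
}

#' Step-by-step Brownian-dynamics chemistry engine
#'
#' Propagates the molecule population from `min(times)` to `max(times)`:
#' each step every molecule takes an isotropic Gaussian displacement with
#' per-axis variance 2 D dt, pairs ending the step inside their encounter
#' radius react (nearest partner wins; a Brownian-bridge test catches
#' crossings inside the step), and first-order channels fire with
#' probability 1 - exp(-k dt).  Products appear at the pair midpoint
#' (bimolecular) or parent position (unimolecular).  Randomness comes from
#' R's RNG, so results are reproducible under [set.seed()].
#'
#' @param pop Population tibble (`species`, `x`, `y`, `z` in nm), e.g. from
#'   [initial_population()].
#' @param reactions A [reaction_table()].
#' @param registry A [species_registry()].
#' @param times Output time grid (s), e.g. [time_grid()]; the first element
#'   is the simulation start (1 ps for track populations).
#' @param scavengers Optional [scavenger_config()].
#' @param config A [chem_config()].
#' @return Object of class `chemistry_result`: list with `counts` (tibble
#'   `time`, `species`, `count`), `events` (fired reactions), `scavenged`,
#'   `final` (positions and alive flags), `initial`, `snapshots` (when
#'   `record_positions`), plus the inputs.  Counts are reconstructed exactly
#'   from the initial population and the stoichiometry of fired reactions.
#' @export
simulate_bd <- function(pop, reactions, registry = species_registry(),
                        times = time_grid(), scavengers = NULL,
                        config = chem_config()) {
  check_chem_args(pop, reactions, registry, times)
  inp <- engine_inputs(pop, reactions, registry, scavengers)
  if (!config$bridge) {
    rmax <- suppressWarnings(max(inp$rx_radius, 0))
    step_len <- sqrt(2 * max(inp$D) * config$dt_max)
    if (rmax > 0 && step_len > config$step_warn_factor * rmax) {
      warning("BD step length ", signif(step_len, 3),
              " nm exceeds the largest encounter radius ", signif(rmax, 3),
              " nm and the bridge correction is off; encounters will be missed",
              call. = FALSE)
    }
  }
  raw <- bd_engine_cpp(inp$pos, inp$sp0, inp$D, inp$pair_rx, inp$rx_radius,
                       inp$rx_prod, inp$unary_rx, inp$unary_rate, inp$scav,
                       min(times), max(times),
                       config$dt_min, config$dt_max, config$dt_growth,
                       if (is.null(config$box_nm)) -1 else config$box_nm,
                       config$bridge, config$adaptive, config$adaptive_factor,
                       as.numeric(times), config$record_positions)
  make_result(raw, pop, reactions, registry, times, "bd", config)
}

#' Independent-reaction-times chemistry engine
#'
#' Samples, for every reactive pair, a reaction time from the
#' diffusion-controlled first-passage distribution
#' W(t | r0, R, D') = (R/r0) erfc((r0 - R)/sqrt(4 D' t)), and exponential
#' times for first-order channels; the earliest pending event fires and
#' consumed partners are invalidated.  Statistically equivalent to
#' [simulate_bd()] but orders of magnitude faster, at the cost of the
#' classical static-position approximation when sampling times for reaction
#' products.  Open-space only (no periodic box).
#'
#' @inheritParams simulate_bd
#' @return A `chemistry_result`, same contract as [simulate_bd()].
#' @export
simulate_irt <- function(pop, reactions, registry = species_registry(),
                         times = time_grid(), scavengers = NULL,
                         config = chem_config()) {
  check_chem_args(pop, reactions, registry, times)
  if (!is.null(config$box_nm)) {
    stop("the IRT engine does not support a periodic box", call. = FALSE)
  }
  inp <- engine_inputs(pop, reactions, registry, scavengers)
  raw <- irt_engine_cpp(inp$pos, inp$sp0, inp$D, inp$pair_rx, inp$rx_radius,
                        inp$rx_prod, inp$unary_rx, inp$unary_rate, inp$scav,
                        min(times), max(times))
  make_result(raw, pop, reactions, registry, times, "irt", config)
}

#' @export
print.chemistry_result <- function(x, ...) {
  cat(sprintf(
    "<chemistry_result> engine=%s  %d initial molecules  %d reactions fired  %d scavenged\n",
    x$engine, nrow(x$initial), nrow(x$events), nrow(x$scavenged)))
  cat(sprintf("  time span %.3g .. %.3g s\n", min(x$times), max(x$times)))
  invisible(x)
}

# Stoichiometry matrix (species x reactions): products minus explicit
# reactants; implicit water is not a tracked species.
stoich_matrix <- function(reactions, registry) {
  ns <- nrow(registry)
  nrx <- nrow(reactions)
  S <- matrix(0L, ns, nrx, dimnames = list(registry$species, NULL))
  prods <- split_products(reactions$products)
  for (r in seq_len(nrx)) {
    i <- match(reactions$reactant1[r], registry$species)
    S[i, r] <- S[i, r] - 1L
    if (!is.na(reactions$reactant2[r])) {
      j <- match(reactions$reactant2[r], registry$species)
      S[j, r] <- S[j, r] - 1L
    }
    for (p in prods[[r]]) {
      q <- match(p, registry$species)
      S[q, r] <- S[q, r] + 1L
    }
  }
  S
}

#' Species counts over time from the reaction ledger
#'
#' Reconstructs counts(t, species) exactly from the initial population plus
#' the stoichiometry of every reaction fired (and every scavenging event) up
#' to each requested time.
#'
#' @param result A `chemistry_result`.
#' @param times Times at which to evaluate counts (defaults to the result's
#'   grid).
#' @return Tibble with columns `time`, `species`, `count`.
#' @export
species_counts <- function(result, times = result$times) {
  registry <- result$registry
  ns <- nrow(registry)
  nt <- length(times)
  n0 <- tabulate(match(result$initial$species, registry$species), nbins = ns)
  S <- stoich_matrix(result$reactions, registry)
  nrx <- ncol(S)
  counts <- matrix(rep(n0, nt), nrow = ns)
  if (nrow(result$events) > 0L) {
    ev <- result$events[order(result$events$time), , drop = FALSE]
    # cumulative fired count per reaction at each time
    cum <- matrix(0, nrow = nrx, ncol = nt)
    upto <- findInterval(times, ev$time)
    for (ti in seq_len(nt)) {
      if (upto[ti] > 0L) {
        cum[, ti] <- tabulate(ev$reaction[seq_len(upto[ti])], nbins = nrx)
      }
    }
    counts <- counts + S %*% cum
  }
  if (nrow(result$scavenged) > 0L) {
    sc <- result$scavenged[order(result$scavenged$time), , drop = FALSE]
    sp <- match(sc$species, registry$species)
    upto <- findInterval(times, sc$time)
    for (ti in seq_len(nt)) {
      if (upto[ti] > 0L) {
        counts[, ti] <- counts[, ti] -
          tabulate(sp[seq_len(upto[ti])], nbins = ns)
      }
    }
  }
  tibble::tibble(
    time = rep(times, each = ns),
    species = rep(registry$species, nt),
    count = as.vector(counts)
  )
}

#' Cumulative reaction counts
#'
#' @param result A `chemistry_result`.
#' @param times Evaluation times (defaults to the end of the run).
#' @return Tibble `time`, `reaction` (label), `count` (cumulative fired
#'   count up to `time`).
#' @export
reaction_counts <- function(result, times = max(result$times)) {
  nrx <- nrow(result$reactions)
  ev <- result$events[order(result$events$time), , drop = FALSE]
  upto <- findInterval(times, ev$time)
  out <- lapply(seq_along(times), function(ti) {
    cnt <- if (upto[ti] > 0L) {
      tabulate(ev$reaction[seq_len(upto[ti])], nbins = nrx)
    } else {
      integer(nrx)
    }
    tibble::tibble(time = times[ti],
                   reaction = result$reactions$reaction,
                   count = cnt)
  })
  dplyr::bind_rows(out)
}

#' Scavenged counts over time
#'
#' @param result A `chemistry_result`.
#' @param times Evaluation times.
#' @return Tibble `time`, `species`, `count` of cumulatively scavenged
#'   molecules (the time-resolved scavenged yield).
#' @export
scavenged_counts <- function(result, times = result$times) {
  registry <- result$registry
  ns <- nrow(registry)
  sc <- result$scavenged[order(result$scavenged$time), , drop = FALSE]
  sp <- match(sc$species, registry$species)
  upto <- findInterval(times, sc$time)
  out <- lapply(seq_along(times), function(ti) {
    cnt <- if (upto[ti] > 0L) tabulate(sp[seq_len(upto[ti])], nbins = ns)
           else integer(ns)
    tibble::tibble(time = times[ti], species = registry$species, count = cnt)
  })
  dplyr::bind_rows(out)
}
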