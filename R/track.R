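ION_TABLE <- tibble::tribble(
  ~name, ~z,  ~a,
  "e-",   1L,  1L,
  "H",    1L,  1L,
  "He",   2L,  4L,
  "C",    6L,  12L,
  "Fe",   26L, 56L
)

#' Define an incoming ion (or electron)
#'
#' @param name One of `"e-"`, `"H"`, `"He"`, `"C"`, `"Fe"`, or a user-defined
#'   name if both `z` and `a` are supplied.
#' @param energy Kinetic energy in MeV/u (MeV for electrons); optional if
#'   `let` is given directly.
#' @param let Linear energy transfer in eV/nm; when `NULL` it is interpolated
#'   from the stopping table for `name` at `energy`.
#' @param z,a Atomic number and nucleon number for user-defined ions.
#' @param stopping Optional stopping table (tibble `energy`, `let`) replacing
#'   the built-in surrogate from [default_stopping_table()].
#' @return Object of class `ion_spec`.
#' @examples
#' ion_spec("C", energy = 0.83)$let   # ~690 eV/nm near the Bragg peak
#' @export
ion_spec <- function(name, energy = NULL, let = NULL, z = NULL, a = NULL,
                     stopping = NULL) {
  row <- ION_TABLE[ION_TABLE$name == name, , drop = FALSE]
  if (nrow(row) == 1L) {
    z <- z %||% row$z
    a <- a %||% row$a
  } else if (is.null(z) || is.null(a)) {
    stop("unknown ion '", name, "'; supply z and a", call. = FALSE)
  }
  if (is.null(let)) {
    if (is.null(energy)) stop("supply energy or let", call. = FALSE)
    let <- let_at_energy(name, energy, z = z, a = a, stopping = stopping)
  }
  if (!is.null(energy) && energy <= 0) stop("energy must be > 0", call. = FALSE)
  if (let <= 0) stop("let must be > 0", call. = FALSE)
  structure(list(name = name, z = as.integer(z), a = as.integer(a),
                 energy = energy, let = let, stopping = stopping),
            class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat(sprintf("<ion_spec> %s (Z=%d, A=%d)  E = %s MeV/u  LET = %.3g eV/nm\n",
              x$name, x$z, x$a,
              if (is.null(x$energy)) "?" else format(x$energy), x$let))
  invisible(x)
}

#' Surrogate stopping-power table for an ion in water
#'
#' Energy-to-LET mapping used when the user does not supply one.  A
#' Barkas-style effective-charge parameterization is used:
#' LET(E) = 26 * Zeff(E)^2 * E^(-0.8) eV/nm with
#' Zeff = Z (1 - exp(-125 beta Z^(-2/3))) and beta the ion velocity in units
#' of c.  This is an editable surrogate anchored to typical proton stopping
#' powers in water (26 eV/nm at 1 MeV), giving roughly 690 eV/nm for C at
#' 0.83 MeV/u and 120 eV/nm for He at 0.75 MeV/u; it is not a published
#' table.  Electrons get a flat 0.2 eV/nm.
#'
#' @param name Ion name (see [ion_spec()]).
#' @param energies Energy grid in MeV/u.
#' @param z Atomic number (required for user-defined ions).
#' @return Tibble with columns `energy` (MeV/u) and `let` (eV/nm).
#' @export
default_stopping_table <- function(name,
                                   energies = c(seq(0.25, 10, by = 0.25),
                                                seq(11, 30, by = 1),
                                                seq(35, 100, by = 5),
                                                seq(110, 400, by = 10)),
                                   z = NULL) {
  row <- ION_TABLE[ION_TABLE$name == name, , drop = FALSE]
  if (is.null(z)) {
    if (nrow(row) != 1L) stop("unknown ion '", name, "'; supply z",
                              call. = FALSE)
    z <- row$z
  }
  if (name == "e-") {
    return(tibble::tibble(energy = energies, let = 0.2))
  }
  gamma <- 1 + energies / 931.494
  beta <- sqrt(1 - 1 / gamma^2)
  zeff <- z * (1 - exp(-125 * beta / z^(2 / 3)))
  tibble::tibble(energy = energies,
                 let = 26 * zeff^2 * energies^(-0.8))
}

let_at_energy <- function(name, energy, z = NULL, a = NULL, stopping = NULL) {
  tab <- stopping %||% default_stopping_table(name, z = z)
  approx(tab$energy, tab$let, xout = energy, rule = 2)$y
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Configuration of the synthetic track-segment generator
#'
#' The generator is a parameterized stand-in for a full physical-stage
#' transport code: it emulates clusters of energy-deposition events along an
#' ion path whose longitudinal density is fixed by the LET and whose radial
#' spread emulates the penumbra.  All parameters are surrogate calibration
#' knobs, not published values.
#'
#' @param mean_event_energy_ev Mean energy per deposition event (eV).  Events
#'   draw from a shifted exponential with floor `min_event_energy_ev`.
#' @param min_event_energy_ev Lower bound of the event energy (eV),
#'   of the order of the lowest electronic excitation of water.
#' @param event_type_probs Named proportions over the five event types.
#' @param radial_mean_nm Either a number (nm) or a function of energy
#'   (MeV/u) giving the mean of the exponential radial offset; the default
#'   `2 sqrt(E)` nm (floor 0.5 nm) narrows the penumbra as the ion slows
#'   toward the Bragg peak.
#' @param segment_window_kev Two-element acceptance window for the total
#'   deposit per segment (keV); segments stop at the first event crossing
#'   the lower edge and are rejected and resampled past the upper edge.
#' @param thermalization_mean_nm Mean thermalization displacement of the
#'   ejected electron before it hydrates (nm).
#' @param fragment_sep_nm Separation applied to heavy dissociation fragments
#'   (nm).
#' @return List of class `track_config`.
#' @export
track_config <- function(mean_event_energy_ev = 40,
                         min_event_energy_ev = 8,
                         event_type_probs = c(ionization = 0.75,
                                              excitation_a1b1 = 0.09,
                                              excitation_b1a1 = 0.09,
                                              excitation_rydberg = 0.05,
                                              attachment = 0.02),
                         radial_mean_nm = NULL,
                         segment_window_kev = c(10, 10.1),
                         thermalization_mean_nm = 5,
                         fragment_sep_nm = 0.3) {
  stopifnot(mean_event_energy_ev > min_event_energy_ev,
            min_event_energy_ev > 0,
            length(segment_window_kev) == 2L,
            segment_window_kev[1] < segment_window_kev[2])
  p <- event_type_probs[event_types()]
  if (anyNA(p)) stop("event_type_probs must name all five event types",
                     call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("event_type_probs must sum to 1", call. = FALSE)
  }
  structure(list(mean_event_energy_ev = mean_event_energy_ev,
                 min_event_energy_ev = min_event_energy_ev,
                 event_type_probs = p,
                 radial_mean_nm = radial_mean_nm,
                 segment_window_kev = segment_window_kev,
                 thermalization_mean_nm = thermalization_mean_nm,
                 fragment_sep_nm = fragment_sep_nm),
            class = "track_config")
}

radial_mean_for <- function(config, energy) {
  rm <- config$radial_mean_nm
  if (is.null(rm)) {
    e <- energy %||% 1
    return(max(0.5, 2 * sqrt(e)))
  }
  if (is.function(rm)) return(rm(energy %||% 1))
  rm
}

#' Generate one synthetic track segment
#'
#' Energy-deposition events are laid down along the ion axis (z) with
#' exponential axial spacings of mean `mean_event_energy_ev / LET` so the
#' longitudinal event density is LET-consistent, and exponential radial
#' offsets emulating the penumbra.  Event energies accumulate until the
#' running total first exceeds the lower window edge (default 10 keV);
#' segments whose total passes the upper edge (10.1 keV) are rejected and
#' resampled, so every accepted segment deposits 10-10.1 keV.
#'
#' @param ion An [ion_spec()].
#' @param config A [track_config()].
#' @param max_attempts Resampling budget before giving up.
#' @return Object of class `track_segment`: list with `ion`, `events`
#'   (tibble `event`, `x`, `y`, `z`, `event_type`, `energy_ev`),
#'   `total_deposit` (eV) and `attempts`.
#' @examples
#' set.seed(1)
#' seg <- generate_segment(ion_spec("C", let = 100))
#' seg$total_deposit  # within [10000, 10100]
#' @export
generate_segment <- function(ion, config = track_config(),
                             max_attempts = 1000L) {
  stopifnot(inherits(ion, "ion_spec"))
  window_ev <- config$segment_window_kev * 1000
  if (config$mean_event_energy_ev > diff(window_ev)) {
    warning("mean event energy exceeds the acceptance window width; ",
            "expect a high rejection rate", call. = FALSE)
  }
  mu <- config$mean_event_energy_ev
  e0 <- config$min_event_energy_ev
  n_guess <- ceiling(window_ev[2] / mu * 1.2) + 20L
  for (attempt in seq_len(max_attempts)) {
    e <- e0 + rexp(n_guess, rate = 1 / (mu - e0))
    tot <- cumsum(e)
    while (tot[length(tot)] < window_ev[1]) {
      e2 <- e0 + rexp(50L, rate = 1 / (mu - e0))
      e <- c(e, e2)
      tot <- cumsum(e)
    }
    n_ev <- which(tot >= window_ev[1])[1]
    total <- tot[n_ev]
    if (total > window_ev[2]) next  # reject and resample
    e <- e[seq_len(n_ev)]
    spacing <- rexp(n_ev, rate = ion$let / mu)
    zpos <- cumsum(spacing)
    r <- rexp(n_ev, rate = 1 / radial_mean_for(config, ion$energy))
    phi <- runif(n_ev, 0, 2 * pi)
    types <- sample(names(config$event_type_probs), n_ev, replace = TRUE,
                    prob = config$event_type_probs)
    events <- tibble::tibble(
      event = seq_len(n_ev),
      x = r * cos(phi),
      y = r * sin(phi),
      z = zpos,
      event_type = types,
      energy_ev = e
    )
    return(structure(list(ion = ion, events = events, total_deposit = total,
                          attempts = attempt),
                     class = "track_segment"))
  }
  stop("failed to generate a segment inside the acceptance window after ",
       max_attempts, " attempts", call. = FALSE)
}

#' @export
print.track_segment <- function(x, ...) {
  cat(sprintf(
    "<track_segment> %s  LET = %.3g eV/nm  %d events  %.1f eV deposited\n",
    x$ion$name, x$ion$let, nrow(x$events), x$total_deposit))
  invisible(x)
}

#' Initial molecule population of a track segment
#'
#' Applies channel sampling and product placement to every event of the
#' segment, giving the positioned population at 1 ps from which the chemical
#' stage starts.
#'
#' @param segment A [generate_segment()] result.
#' @param registry,branching,config As in [place_products()].
#' @return Tibble with columns `species`, `x`, `y`, `z`, `event`.
#' @export
initial_population <- function(segment, registry = species_registry(),
                               branching = branching_table(),
                               config = track_config()) {
  stopifnot(inherits(segment, "track_segment"))
  place_products(segment$events, registry, branching, config)
}
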