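#' Dissociation channels of ionized and excited water
#'
#' Branching ratios used by the physicochemical stage.  Event types follow
#' the electronic states of the water molecule: single ionization, the A1B1
#' and B1A1 excitations, the Rydberg/diffuse bands, and dissociative
#' electron attachment.  `H2O + dE` relaxation channels carry an empty
#' product list.  For ionization the ejected electron thermalizes and becomes
#' the hydrated electron, so the channel products include `e_aq-`.
#'
#' @param file Optional branching table (TSV, columns `event_type`,
#'   `products`, `probability`).
#' @return Tibble of class `branching_table` with columns `event_type`,
#'   `products` (comma-separated, `""` for relaxation), `probability`.
#'   Probabilities sum to 1 within each event type.
#' @examples
#' br <- branching_table()
#' # A1B1 dissociates to OH + H with probability 0.65
#' br$probability[br$event_type == "excitation_a1b1" & br$products == "OH,H"]
#' @export
branching_table <- function(file = NULL) {
  br <- if (is.null(file)) default_branching() else read_branching(file)
  validate_branching(br)
  br
}

default_branching <- function() {
  br <- tibble::tribble(
    ~event_type,           ~products,         ~probability,
    "ionization",          "H3O+,OH,e_aq-",   1.00,
    "excitation_a1b1",     "OH,H",            0.65,
    "excitation_a1b1",     "",                0.35,
    "excitation_b1a1",     "H3O+,OH,e_aq-",   0.55,
    "excitation_b1a1",     "OH,OH,H2",        0.15,
    "excitation_b1a1",     "",                0.30,
    "excitation_rydberg",  "H3O+,OH,e_aq-",   0.50,
    "excitation_rydberg",  "",                0.50,
    "attachment",          "OH,OH-,H2",       1.00
  )
  class(br) <- c("branching_table", class(br))
  br
}

event_types <- function() {
  c("ionization", "excitation_a1b1", "excitation_b1a1",
    "excitation_rydberg", "attachment")
}

validate_branching <- function(br) {
  stopifnot(all(c("event_type", "products", "probability") %in% names(br)))
  if (any(br$probability < 0 | br$probability > 1)) {
    stop("branching probabilities must lie in [0, 1]", call. = FALSE)
  }
  sums <- tapply(br$probability, br$event_type, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0L) {
    stop("channel probabilities must sum to 1 per event type: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(br$event_type), event_types())
  if (length(unknown) > 0L) {
    stop("unknown event type: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(br)
}

#' Sample dissociation channels for one event type
#'
#' @param event_type One of `"ionization"`, `"excitation_a1b1"`,
#'   `"excitation_b1a1"`, `"excitation_rydberg"`, `"attachment"`.
#' @param n Number of independent draws.
#' @param branching A [branching_table()].
#' @return Character vector of length `n`: the comma-separated product list
#'   of each sampled channel (`""` for relaxation back to water).
#' @examples
#' set.seed(1)
#' draws <- sample_channel("excitation_a1b1", 1000)
#' mean(draws == "OH,H")   # ~0.65
#' @export
sample_channel <- function(event_type, n = 1L, branching = branching_table()) {
  if (!event_type %in% event_types()) {
    stop("unknown event type: ", event_type, call. = FALSE)
  }
  rows <- branching[branching$event_type == event_type, , drop = FALSE]
  idx <- sample.int(nrow(rows), size = n, replace = TRUE,
                    prob = rows$probability)
  rows$products[idx]
}

#' Convert physical events into initial positioned radiolysis products
#'
#' For every event a dissociation channel is sampled with the configured
#' branching ratios, and each product is placed relative to the event
#' position: hydrated electrons receive an isotropic displacement with an
#' exponential radial law (thermalization of the ejected electron, mean
#' `thermalization_mean_nm`); heavy fragments are displaced by a fixed
#' sub-nanometer separation `fragment_sep_nm` along independent random
#' directions.  Both distances are surrogate configuration values, not taken
#' from any published table; setting them to zero places all products at the
#' event position.
#'
#' @param events Tibble with columns `x`, `y`, `z` (nm) and `event_type`.
#' @param registry A [species_registry()].
#' @param branching A [branching_table()].
#' @param config A [track_config()]; fields `thermalization_mean_nm` and
#'   `fragment_sep_nm` control placement.
#' @return Tibble (a molecule population at 1 ps) with columns `species`,
#'   `x`, `y`, `z` (nm) and `event` (originating event row).
#' @export
place_products <- function(events, registry = species_registry(),
                           branching = branching_table(),
                           config = track_config()) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(species = character(), x = double(), y = double(),
                          z = double(), event = integer()))
  }
  channels <- vapply(events$event_type, function(tp) {
    sample_channel(tp, 1L, branching)
  }, character(1))
  prods <- split_products(channels)
  n_per <- vapply(prods, length, integer(1))
  if (sum(n_per) == 0L) {
    return(tibble::tibble(species = character(), x = double(), y = double(),
                          z = double(), event = integer()))
  }
  ev_idx <- rep(seq_len(nrow(events)), n_per)
  species <- unlist(prods, use.names = FALSE)
  unknown <- setdiff(unique(species), registry$species)
  if (length(unknown) > 0L) {
    stop("branching table yields unregistered species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- length(species)
  # isotropic unit vectors
  u <- matrix(rnorm(3L * m), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  dist <- ifelse(species == "e_aq-",
                 rexp(m, rate = 1 / max(config$thermalization_mean_nm, 1e-12)) *
                   (config$thermalization_mean_nm > 0),
                 config$fragment_sep_nm)
  tibble::tibble(
    species = species,
    x = events$x[ev_idx] + u[, 1] * dist,
    y = events$y[ev_idx] + u[, 2] * dist,
    z = events$z[ev_idx] + u[, 3] * dist,
    event = ev_idx
  )
}
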