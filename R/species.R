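#' Molecular species registry for water radiolysis
#'
#' Builds the default registry of the twelve molecular species tracked by the
#' simulator: the seven classic radiolysis products (`e_aq-`, `OH`, `H`, `H2`,
#' `H3O+`, `OH-`, `H2O2`) plus the five secondary products added to the
#' reaction scheme (`O2`, `O2-`, `HO2`, `HO2-`, `O-`).  Diffusion coefficients
#' for the five secondary products carry the published values; the base
#' species carry the canonical Frongillo-style defaults, overridable through
#' a species file.
#'
#' Naming uses plain ASCII: `OH` is the hydroxyl radical, `OH-` the hydroxide
#' anion, `O2-` the superoxide radical anion, `HO2` the hydroperoxyl radical,
#' `HO2-` its conjugate base and `O-` the oxide radical anion.
#'
#' @param file Optional path to a species table (TSV, columns `species`,
#'   `n_h`, `n_o`, `charge`, `diff_coef`, `radical`); when `NULL` the shipped
#'   defaults are used.
#' @return A tibble of class `species_registry` with columns `species`,
#'   `n_h`, `n_o`, `charge` (elementary charges), `diff_coef`
#'   (units of 1e-9 m^2/s), `radical`, and optional metadata columns
#'   `vdw_radius` (nm) and `mass` (u), unused by any computation.
#' @examples
#' reg <- species_registry()
#' species_lookup(reg, "O2")$diff_coef   # 2.4
#' @export
species_registry <- function(file = NULL) {
  reg <- if (is.null(file)) default_species() else read_species(file)
  validate_registry(reg)
  reg
}

default_species <- function() {
  reg <- tibble::tribble(
    ~species, ~n_h, ~n_o, ~charge, ~diff_coef, ~radical,
    "e_aq-",  0L,   0L,   -1L,     4.9,        TRUE,
    "OH",     1L,   1L,    0L,     2.8,        TRUE,
    "H",      1L,   0L,    0L,     7.0,        TRUE,
    "H2",     2L,   0L,    0L,     4.8,        FALSE,
    "H3O+",   3L,   1L,    1L,     9.46,       FALSE,
    "OH-",    1L,   1L,   -1L,     5.3,        FALSE,
    "H2O2",   2L,   2L,    0L,     2.3,        FALSE,
    "O2",     0L,   2L,    0L,     2.4,        FALSE,
    "O2-",    0L,   2L,   -1L,     1.75,       TRUE,
    "HO2",    1L,   2L,    0L,     2.3,        TRUE,
    "HO2-",   1L,   2L,   -1L,     1.4,        FALSE,
    "O-",     0L,   1L,   -1L,     2.0,        TRUE
  )
  reg$vdw_radius <- NA_real_
  reg$mass <- NA_real_
  class(reg) <- c("species_registry", class(reg))
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  needed <- c("species", "n_h", "n_o", "charge", "diff_coef", "radical")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0L) {
    stop("species registry is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$species)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (any(reg$diff_coef <= 0)) {
    stop("all diffusion coefficients must be positive", call. = FALSE)
  }
  if (any(reg$n_h < 0L) || any(reg$n_o < 0L)) {
    stop("atom counts must be non-negative", call. = FALSE)
  }
  atomless <- reg$species[reg$n_h == 0L & reg$n_o == 0L]
  if (!identical(atomless, "e_aq-")) {
    stop("the hydrated electron must be the unique species with zero atoms",
         call. = FALSE)
  }
  if (reg$charge[reg$species == "e_aq-"] != -1L) {
    stop("the hydrated electron must carry charge -1", call. = FALSE)
  }
  invisible(reg)
}

#' Look up one species record
#'
#' @param registry A [species_registry()] tibble.
#' @param species A single species name.
#' @return One-row tibble for the species; errors if unknown.
#' @export
species_lookup <- function(registry, species) {
  hit <- registry[registry$species == species, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("unknown species: ", species, call. = FALSE)
  }
  hit
}

#' Atom and charge bookkeeping for one species
#'
#' Returns the hydrogen count, oxygen count and charge used by the reaction
#' balance checks.
#'
#' @inheritParams species_lookup
#' @return Named integer vector `c(n_h, n_o, charge)`.
#' @examples
#' composition_vector(species_registry(), "H2O2")  # c(n_h = 2, n_o = 2, charge = 0)
#' @export
composition_vector <- function(registry, species) {
  hit <- species_lookup(registry, species)
  c(n_h = hit$n_h, n_o = hit$n_o, charge = hit$charge)
}
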