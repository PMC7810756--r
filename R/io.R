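#' Read and write configuration tables
#'
#' The species, reaction and branching tables round-trip through plain TSV
#' files; the shipped defaults live under `inst/extdata`.  Empty product
#' lists are written as empty strings.
#'
#' @param path File path.
#' @return The corresponding tibble.
#' @name config_io
NULL

#' @rdname config_io
#' @export
read_species <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          species = readr::col_character(),
                          n_h = readr::col_integer(),
                          n_o = readr::col_integer(),
                          charge = readr::col_integer(),
                          diff_coef = readr::col_double(),
                          radical = readr::col_logical(),
                          .default = readr::col_double()
                        ))
  reg <- tibble::as_tibble(df)
  if (!"vdw_radius" %in% names(reg)) reg$vdw_radius <- NA_real_
  if (!"mass" %in% names(reg)) reg$mass <- NA_real_
  class(reg) <- c("species_registry", class(reg))
  validate_registry(reg)
  reg
}

#' @rdname config_io
#' @param registry A [species_registry()].
#' @export
write_species <- function(registry, path) {
  readr::write_tsv(as.data.frame(registry), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_reactions <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                        col_types = readr::cols(
                          reactant1 = readr::col_character(),
                          reactant2 = readr::col_character(),
                          products = readr::col_character(),
                          k = readr::col_double(),
                          order = readr::col_integer()
                        ))
  df$products[is.na(df$products)] <- ""
  tibble::as_tibble(df)
}

#' @rdname config_io
#' @param reactions A reaction tibble.
#' @export
write_reactions <- function(reactions, path) {
  df <- as.data.frame(reactions)[, c("reactant1", "reactant2", "products",
                                     "k", "order")]
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_branching <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                        col_types = readr::cols(
                          event_type = readr::col_character(),
                          products = readr::col_character(),
                          probability = readr::col_double()
                        ))
  df$products[is.na(df$products)] <- ""
  br <- tibble::as_tibble(df)
  class(br) <- c("branching_table", class(br))
  br
}

#' @rdname config_io
#' @param branching A [branching_table()].
#' @export
write_branching <- function(branching, path) {
  readr::write_tsv(as.data.frame(branching), path)
  invisible(path)
}

#' Write a result table as TSV with a metadata header
#'
#' Plain TSV prefixed with `#` comment lines recording provenance (seed,
#' engine, package version, configuration hash), so every output is
#' self-describing and byte-reproducible under a fixed seed.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("trackchem ",
                                  as.character(utils::packageVersion("trackchem"))),
                 written = "fixed-seed-run"), meta)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " "))
  }, character(1))
  writeLines(hdr, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a result TSV written by [write_result_tsv()]
#'
#' @param path File path.
#' @return Tibble with attribute `meta` (named character vector parsed from
#'   the `#` header).
#' @export
read_result_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character()
  if (length(hdr) > 0L) {
    kv <- sub("^# *", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: *", "", kv)
    meta <- setNames(vals, keys)
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Stable hash of a configuration object
#'
#' Deterministic serialization-based hash used to stamp outputs; two runs
#' with identical configurations share a hash.
#'
#' @param x Any R object.
#' @return Character scalar.
#' @export
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # fold the byte stream into a 64-bit-ish hex digest (FNV-1a style)
  h <- 14695981039346656037
  for (chunk in split(as.integer(raw),
                      ceiling(seq_along(raw) / 4096))) {
    h <- (h + sum((chunk + 1) * seq_along(chunk))) %% 2^53
    h <- (h * 1099511) %% 2^53
  }
  sprintf("%015.0f", h)
}

#' Validate the shipped (or user-supplied) configuration
#'
#' Runs the registry, balance and branching checks the `validate` CLI
#' subcommand exposes: unique species with positive diffusion coefficients,
#' every reaction charge/atom balanced, channel probabilities normalized per
#' event type.
#'
#' @param registry A [species_registry()].
#' @param reactions A [reaction_table()].
#' @param branching A [branching_table()].
#' @return Invisibly, a list with counts of validated entries; errors on any
#'   violation.
#' @export
validate_configuration <- function(registry = species_registry(),
                                   reactions = reaction_table(registry),
                                   branching = branching_table()) {
  validate_registry(registry)
  validate_reactions(reactions, registry)
  validate_branching(branching)
  required <- default_species()$species
  missing <- setdiff(required, registry$species)
  if (length(missing) > 0L) {
    stop("registry is missing required species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(list(n_species = nrow(registry),
                 n_reactions = nrow(reactions),
                 n_first_order = sum(reactions$order == 1L),
                 n_event_types = length(unique(branching$event_type))))
}
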