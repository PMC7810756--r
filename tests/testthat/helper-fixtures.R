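# Shared fixtures: built once per test run, in code (no stored data).

reg_fix <- species_registry()
rx_fix <- reaction_table(reg_fix)
br_fix <- branching_table()

# subset a reaction table by label, keeping the attributes subsetting drops
pick_reactions <- function(labels, rx = rx_fix) {
  out <- rx[rx$reaction %in% labels, , drop = FALSE]
  attr(out, "aa_convention") <- attr(rx, "aa_convention")
  out
}

no_reactions <- function(rx = rx_fix) {
  out <- rx[0, , drop = FALSE]
  attr(out, "aa_convention") <- attr(rx, "aa_convention")
  out
}

# n molecules of one species, so far apart they can never meet by 1 us
isolated_pop <- function(species, n, spacing = 1e4) {
  tibble::tibble(species = rep(species, n),
                 x = seq_len(n) * spacing, y = 0, z = 0)
}

# uniformly seeded periodic-box population at a given molarity
box_pop <- function(species, n, conc_mol_dm3) {
  vol_dm3 <- n / (6.02214076e23 * conc_mol_dm3)
  l_nm <- (vol_dm3 * 1e24)^(1 / 3)
  list(pop = tibble::tibble(species = rep(species, n),
                            x = runif(n, 0, l_nm),
                            y = runif(n, 0, l_nm),
                            z = runif(n, 0, l_nm)),
       box_nm = l_nm, volume_dm3 = vol_dm3)
}

count_at <- function(result, species, time) {
  cc <- species_counts(result, time)
  cc$count[cc$species == species]
}
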