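# helpers for constructing small controlled states

# lattice with `n_cells` cells of species 1 at the first sites (deterministic)
single_species_lattice <- function(width, height, n_cells) {
  lat <- hex_lattice(width, height, n_species = 1)
  lat$occupancy[seq_len(n_cells)] <- 1L
  lat
}

# abundance vector straight from counts on a lattice of `total_sites` capacity
ab <- function(counts, total_sites) abundance_vector(counts, total_sites)

default_windows <- list(c(200, 400), c(600, 800))

# small-but-representative config for fast full-loop tests
small_config <- function(..., n_steps = 60) {
  ktw_config(width = 20, height = 20, n_steps = n_steps, seed = 42, ...)
}
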