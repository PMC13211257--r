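#' Construct a hexagonal lattice community state
#'
#' The lattice is a `width` x `height` rhombus in axial coordinates
#' `(col, row)`, `col` in `0..width-1`, `row` in `0..height-1`, with toroidal
#' (wrap-around) boundaries so every site is statistically equivalent. Each
#' site holds at most one cell; `0` marks an empty site.
#'
#' Site indices are 1-based and column-major in rows:
#' `site = col + row * width + 1`.
#'
#' @param width,height positive integers; number of axial columns / rows.
#' @param n_species number of species in the roster (ids `1..n_species`).
#' @param occupancy integer vector of length `width * height` with values in
#'   `0..n_species`, or `NULL` for an empty lattice.
#' @return An object of class `hex_lattice`: a list with fields `width`,
#'   `height`, `n_species` and `occupancy`.
#' @examples
#' lat <- hex_lattice(5, 5, n_species = 2)
#' hex_neighbors(lat, 1)
#' @export
hex_lattice <- function(width, height, n_species, occupancy = NULL) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L, width >= 1, height >= 1,
            width == as.integer(width), height == as.integer(height),
            is.numeric(n_species), n_species >= 1)
  width <- as.integer(width); height <- as.integer(height)
  n_species <- as.integer(n_species)
  nsites <- width * height
  if (is.null(occupancy)) {
    occupancy <- integer(nsites)
  } else {
    occupancy <- as.integer(occupancy)
    if (length(occupancy) != nsites)
      stop("`occupancy` must have length width * height = ", nsites)
    if (anyNA(occupancy) || any(occupancy < 0L) || any(occupancy > n_species))
      stop("`occupancy` values must be in 0..n_species")
  }
  structure(list(width = width, height = height, n_species = n_species,
                 occupancy = occupancy),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  ab <- count_abundances(x)
  cat(sprintf("<hex_lattice> %d x %d (%d sites), %d species\n",
              x$width, x$height, x$width * x$height, x$n_species))
  cat("  occupied:", sum(ab$counts), "  counts:",
      paste(ab$counts, collapse = " "), "\n")
  invisible(x)
}

n_sites <- function(lattice) lattice$width * lattice$height

#' Convert between site indices and axial coordinates
#'
#' @param lattice a [hex_lattice()].
#' @param site 1-based site index (vectorised).
#' @param col,row 0-based axial coordinates (vectorised).
#' @return `site_coords()` returns a data.frame with columns `col`, `row`;
#'   `site_index()` returns 1-based site indices.
#' @export
site_coords <- function(lattice, site) {
  check_site(lattice, site)
  s0 <- site - 1L
  data.frame(col = s0 %% lattice$width, row = s0 %/% lattice$width)
}

#' @rdname site_coords
#' @export
site_index <- function(lattice, col, row) {
  stopifnot(all(col >= 0), all(col < lattice$width),
            all(row >= 0), all(row < lattice$height))
  as.integer(col + row * lattice$width + 1L)
}

check_site <- function(lattice, site) {
  if (any(site < 1L) || any(site > n_sites(lattice)) ||
      any(site != as.integer(site)))
    stop("invalid site index: out of range 1..", n_sites(lattice))
  invisible(TRUE)
}

#' Six hexagonal neighbors of a site
#'
#' Uses the six standard axial offsets `(+1,0) (-1,0) (0,+1) (0,-1) (+1,-1)
#' (-1,+1)` with toroidal wrap-around. The neighbor relation is symmetric and
#' irreflexive. Lattices narrower than 3 in either dimension are rejected
#' because wrap-around would make some neighbors coincide.
#'
#' @param lattice a [hex_lattice()].
#' @param site 1-based site index.
#' @return Integer vector of the 6 distinct neighboring site indices, in fixed
#'   offset order.
#' @export
hex_neighbors <- function(lattice, site) {
  if (lattice$width < 3L || lattice$height < 3L)
    stop("neighborhoods require width >= 3 and height >= 3 ",
         "(wrap-around would duplicate neighbors)")
  check_site(lattice, site)
  hex_neighbors_cpp(as.integer(site) - 1L, lattice$width, lattice$height) + 1L
}

#' Seed a lattice with an equal-abundance random community
#'
#' Occupies `round(fraction * n_sites)` sites, sampled uniformly without
#' replacement, and splits them across the species roster as evenly as
#' possible (counts differ by at most 1; lower species ids receive the
#' remainder). Deterministic for a given `seed`.
#'
#' @param width,height lattice dimensions.
#' @param n_species number of species.
#' @param fraction initial occupancy fraction in (0, 1].
#' @param seed optional integer; when given, the placement is drawn from a
#'   fresh RNG stream seeded with it (the caller's stream is untouched).
#' @return A [hex_lattice()].
#' @examples
#' lat <- initialize_lattice(60, 60, 4, 0.10, seed = 1)
#' count_abundances(lat)$counts  # 90 90 90 90
#' @export
initialize_lattice <- function(width, height, n_species, fraction,
                               seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  lat <- hex_lattice(width, height, n_species)
  nsites <- n_sites(lat)
  total <- as.integer(round(fraction * nsites))
  if (total > nsites) stop("requested occupancy exceeds lattice size")
  draw <- function() sample.int(nsites, total)
  sites <- if (is.null(seed)) draw() else with_seed(seed, draw())
  base <- total %/% n_species
  counts <- rep(base, n_species)
  extra <- total - base * n_species
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  lat$occupancy[sites] <- rep.int(seq_len(n_species), counts)
  lat
}

#' Per-species abundance counts of a lattice state
#'
#' @param lattice a [hex_lattice()].
#' @param n_species number of species to tabulate; defaults to the roster size
#'   stored in the lattice.
#' @return An object of class `ktw_abundance`: list with `counts` (integer,
#'   length `n_species`) and `total_sites`.
#' @export
count_abundances <- function(lattice, n_species = lattice$n_species) {
  counts <- tabulate(lattice$occupancy, nbins = n_species)
  abundance_vector(counts, n_sites(lattice))
}

#' Build an abundance vector
#'
#' @param counts non-negative per-species counts.
#' @param total_sites positive lattice capacity; `sum(counts)` must not
#'   exceed it.
#' @return A `ktw_abundance` object.
#' @export
abundance_vector <- function(counts, total_sites) {
  counts <- as.integer(counts)
  total_sites <- as.integer(total_sites)
  stopifnot(total_sites >= 1L, all(counts >= 0L))
  if (sum(counts) > total_sites)
    stop("sum(counts) exceeds total_sites")
  structure(list(counts = counts, total_sites = total_sites),
            class = "ktw_abundance")
}

#' @export
print.ktw_abundance <- function(x, ...) {
  cat("<ktw_abundance>", paste(x$counts, collapse = " "),
      sprintf("(of %d sites)\n", x$total_sites))
  invisible(x)
}

# relative abundances over occupied cells; zero vector for empty community
rel_abundance <- function(ab) {
  s <- sum(ab$counts)
  if (s == 0L) return(rep(0, length(ab$counts)))
  ab$counts / s
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    return(NULL)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
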