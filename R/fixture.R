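#' Construct a lattice with prescribed occupancy and dominance
#'
#' Builds a community state whose measured occupancy fraction and dominant
#' species' share match the request to within one cell — useful for testing
#' the surveillance trigger and penalization operators on exactly controlled
#' states without running the dynamics.
#'
#' The dominant species receives `round(dominant_share * total)` cells and
#' the remaining cells are split as evenly as possible across the other
#' species; all occupied sites are placed uniformly at random without
#' replacement.
#'
#' @param width,height lattice dimensions.
#' @param occupancy target occupancy fraction of all sites, in (0, 1].
#' @param dominant_share target relative abundance of the dominant species,
#'   in (0, 1]; must be at least `1/n_species` (it is the maximum share).
#' @param n_species roster size (default 4).
#' @param dominant_id id of the dominant species (default 1).
#' @param seed optional integer for deterministic placement.
#' @return A [hex_lattice()].
#' @examples
#' lat <- make_fixture(20, 20, occupancy = 0.75, dominant_share = 0.40,
#'                     seed = 1)
#' surveillance_trigger(count_abundances(lat), surveillance_rule())$fired
#' @export
make_fixture <- function(width, height, occupancy, dominant_share,
                         n_species = 4, dominant_id = 1, seed = NULL) {
  if (!is.numeric(occupancy) || occupancy <= 0 || occupancy > 1)
    stop("infeasible fixture: `occupancy` must be in (0, 1]")
  if (!is.numeric(dominant_share) || dominant_share <= 0 || dominant_share > 1)
    stop("infeasible fixture: `dominant_share` must be in (0, 1]")
  stopifnot(n_species >= 1, dominant_id >= 1, dominant_id <= n_species)
  lat <- hex_lattice(width, height, n_species)
  nsites <- n_sites(lat)
  total <- as.integer(round(occupancy * nsites))
  if (total < 1L) stop("infeasible fixture: no occupied sites requested")
  dom <- as.integer(round(dominant_share * total))
  rest <- total - dom
  if (dom < 1L) stop("infeasible fixture: dominant species would be empty")
  others <- setdiff(seq_len(n_species), dominant_id)
  if (length(others) == 0L && rest > 0L)
    stop("infeasible fixture: single species but dominant_share < 1")
  if (length(others) > 0L && rest > 0L) {
    per <- rest %/% length(others)
    counts_o <- rep(per, length(others))
    extra <- rest - per * length(others)
    if (extra > 0L) counts_o[seq_len(extra)] <- counts_o[seq_len(extra)] + 1L
    if (max(counts_o) > dom)
      stop("infeasible fixture: requested dominant_share below another ",
           "species' share")
  } else {
    counts_o <- integer(0)
  }
  species <- c(rep.int(dominant_id, dom),
               if (rest > 0L) rep.int(others, counts_o))
  draw <- function() sample.int(nsites, total)
  sites <- if (is.null(seed)) draw() else with_seed(seed, draw())
  lat$occupancy[sites] <- species
  lat
}
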