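#' One stochastic update step of the lattice community
#'
#' Two phases, mortality strictly before replication:
#' \enumerate{
#'   \item every occupied cell is independently vacated with probability
#'     `mortality`;
#'   \item the surviving cells are visited in a uniformly random order; each
#'     replicates with its species' replication probability into one empty
#'     neighbor chosen uniformly. A cell with no empty neighbor cannot
#'     replicate (space limitation), and cells born within the step do not
#'     replicate until the next step.
#' }
#' Replication is sequential rather than synchronous so two cells can never
#' claim the same empty site. Draws come from the caller's RNG stream, so the
#' result is deterministic given the stream state.
#'
#' @param lattice a [hex_lattice()] with both dimensions >= 3.
#' @param replication_probs per-species replication probabilities, length
#'   `lattice$n_species`, values in `[0, 1]`.
#' @param mortality per-cell death probability in `[0, 1)`.
#' @return The updated lattice.
#' @export
ktw_step <- function(lattice, replication_probs, mortality = 0.05) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (lattice$width < 3L || lattice$height < 3L)
    stop("dynamics require width >= 3 and height >= 3")
  if (length(replication_probs) != lattice$n_species)
    stop("`replication_probs` must have one entry per species")
  check_range(replication_probs, "replication_probs", 0, 1)
  check_range(mortality, "mortality", 0, 1, hi_open = TRUE)
  lattice$occupancy <- ktw_step_cpp(lattice$occupancy, lattice$width,
                                    lattice$height,
                                    as.numeric(replication_probs),
                                    as.numeric(mortality))
  lattice
}

# expand the master seed into named substreams so that, e.g., penalization
# sampling never shifts the dynamics draws
derive_subseeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 3L)
    names(s) <- c("init", "dynamics", "penalization")
    s
  })
}

#' Run the full lattice simulation
#'
#' Initializes the lattice ([initialize_lattice()]) and iterates `n_steps`
#' cycles of \[dynamics step -> surveillance check -> record\]. The
#' surveillance trigger is evaluated once per step (after the dynamics
#' phases) and only on steps where the schedule is active; at most one
#' penalization event fires per step. Recording happens after the
#' surveillance check, so a penalization is visible in the same step's row.
#'
#' All randomness derives from `config$seed` through three named substreams
#' (initialization, dynamics, penalization sampling), so identical configs
#' give bit-identical trajectories and adding penalization events does not
#' shift the dynamics draws.
#'
#' @param config a [ktw_config()].
#' @return An object of class `ktw_run`: list with
#'   \describe{
#'     \item{trajectory}{`data.frame`, one row per completed step (0-based
#'       `step` column): `count_1..count_n`, `total`, `hill_q0`, `hill_q1`,
#'       `hill_q2`, `penalized`.}
#'     \item{final_lattice}{the [hex_lattice()] after the last step.}
#'     \item{config}{the resolved configuration.}
#'   }
#' @examples
#' run <- ktw_run(ktw_config(width = 20, height = 20, n_steps = 50, seed = 1))
#' head(run$trajectory)
#' @export
ktw_run <- function(config) {
  config <- validate_config(config)
  n <- length(config$replication_probs)
  rule <- as_rule(config)
  sched <- as_schedule(config)
  seeds <- derive_subseeds(config$seed)

  lat <- initialize_lattice(config$width, config$height, n,
                            config$init_occupancy, seed = seeds[["init"]])

  # two independent RNG states, swapped in and out of .Random.seed
  caller_state <- get_rng_state()
  on.exit(set_rng_state(caller_state), add = TRUE)
  set.seed(seeds[["dynamics"]]);     dyn_state <- get_rng_state()
  set.seed(seeds[["penalization"]]); pen_state <- get_rng_state()

  n_steps <- config$n_steps
  counts <- matrix(0L, nrow = n_steps, ncol = n)
  hill <- matrix(0, nrow = n_steps, ncol = 3L)
  fired <- logical(n_steps)

  for (t in seq_len(n_steps)) {
    set_rng_state(dyn_state)
    lat <- ktw_step(lat, config$replication_probs, config$mortality)
    dyn_state <- get_rng_state()

    step0 <- t - 1L  # 0-based step index, used by the schedule
    if (is_active(sched, step0)) {
      ab <- count_abundances(lat)
      trig <- surveillance_trigger(ab, rule)
      if (trig$fired) {
        set_rng_state(pen_state)
        lat <- penalize(lat, trig$target, rule)
        pen_state <- get_rng_state()
        fired[t] <- TRUE
      }
    }

    ab <- count_abundances(lat)
    counts[t, ] <- ab$counts
    hill[t, ] <- hill_number(ab, c(0, 1, 2))
  }

  traj <- data.frame(step = seq_len(n_steps) - 1L, counts,
                     total = rowSums(counts), hill,
                     penalized = fired)
  names(traj) <- c("step", paste0("count_", seq_len(n)), "total",
                   "hill_q0", "hill_q1", "hill_q2", "penalized")
  structure(list(trajectory = traj, final_lattice = lat, config = config),
            class = "ktw_run")
}

#' @export
print.ktw_run <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf("<ktw_run> %d steps on %dx%d, %d species, seed %d\n",
              nrow(tr), x$config$width, x$config$height,
              length(x$config$replication_probs), x$config$seed))
  cat(sprintf("  final: total %d, richness %g, hill_q1 %.3f, hill_q2 %.3f, %d penalization event(s)\n",
              last$total, last$hill_q0, last$hill_q1, last$hill_q2,
              sum(tr$penalized)))
  invisible(x)
}
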