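#' Parameters for the deterministic mean-field model
#'
#' The non-spatial counterpart of the lattice engine: `n` taxa with intrinsic
#' growth rates `r`, a shared carrying capacity `K` (logistic competition for
#' one resource pool), mortality `m`, and the same two-threshold suppression
#' rule, with the load threshold read against `K` and dominance against the
#' community share. Defaults align with the lattice roster: r = (0.3, 0.5,
#' 0.7, 0.9), m = 0.1, K = 1000, x(0) = 25 each, 1,000 steps.
#'
#' Mortality is what makes competitive exclusion strict here: with m = 0 the
#' shared-logistic equilibrium is neutral (any composition summing to K is a
#' fixed point), whereas with m > 0 only the fastest grower can persist at
#' the equilibrium load S* = K(1 - m/r_max).
#'
#' @param r per-taxon intrinsic growth rates, all > 0.
#' @param K carrying capacity (positive abundance scale).
#' @param m mortality rate in `[0, min(r))`.
#' @param x0 initial abundances (> 0); recycled to `length(r)`.
#' @param n_steps number of steps (>= 1).
#' @param rule a [surveillance_rule()]; thresholds are interpreted against
#'   `K` (load) and the community share (dominance).
#' @param mode surveillance activation: `"always"`, `"off"`, or `"windows"`.
#' @param windows step windows for `"windows"` mode (see [schedule()]).
#' @param euler_dt Euler step size in (0, 1]; the growth update is applied in
#'   `1/euler_dt` sub-steps per step, the suppression check once per step.
#' @return An object of class `meanfield_params`.
#' @export
meanfield_params <- function(r = c(0.3, 0.5, 0.7, 0.9), K = 1000, m = 0.1,
                             x0 = 25, n_steps = 1000,
                             rule = surveillance_rule(),
                             mode = c("always", "off", "windows"),
                             windows = NULL, euler_dt = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(r), length(r) >= 1L, all(r > 0),
            is.numeric(K), length(K) == 1L, K > 0,
            is.numeric(m), length(m) == 1L, m >= 0, m < min(r),
            is.numeric(x0), all(x0 > 0),
            is.numeric(n_steps), n_steps >= 1,
            inherits(rule, "surveillance_rule"),
            is.numeric(euler_dt), length(euler_dt) == 1L,
            euler_dt > 0, euler_dt <= 1)
  x0 <- rep_len(x0, length(r))
  structure(list(n = length(r), r = r, K = K, m = m, x0 = x0,
                 n_steps = as.integer(n_steps), rule = rule,
                 schedule = schedule(mode, windows), euler_dt = euler_dt),
            class = "meanfield_params")
}

#' One step of the mean-field map
#'
#' Growth update (Euler, step size `euler_dt`, repeated `1/euler_dt` times):
#' \deqn{x_i \leftarrow x_i + x_i\,(r_i (1 - S/K) - m)\,\Delta t,\quad
#'       S = \sum_j x_j,}
#' floored at 0. Then the suppression check, mirroring the lattice rule
#' deterministically: if `S/K` strictly exceeds the load threshold and the
#' maximum share `x_i/S` strictly exceeds the dominance threshold, the
#' dominant taxon (lowest index on ties) is multiplied by
#' `1 - removal_fraction`.
#'
#' @param x current abundance vector (all >= 0).
#' @param params a [meanfield_params()].
#' @param suppress whether the suppression rule is active this step.
#' @return The next abundance vector.
#' @export
meanfield_step <- function(x, params, suppress = TRUE) {
  stopifnot(inherits(params, "meanfield_params"),
            length(x) == params$n, all(x >= 0))
  dt <- params$euler_dt
  nsub <- as.integer(round(1 / dt))
  for (k in seq_len(nsub)) {
    S <- sum(x)
    x <- x + x * (params$r * (1 - S / params$K) - params$m) * dt
    x[x < 0] <- 0
  }
  if (suppress) {
    S <- sum(x)
    if (S / params$K > params$rule$load_threshold && S > 0) {
      share <- x / S
      if (max(share) > params$rule$dominance_threshold) {
        if (params$rule$target_policy == "whole_community") {
          x <- x * (1 - params$rule$removal_fraction)
        } else {
          i <- which.max(share)
          x[i] <- x[i] * (1 - params$rule$removal_fraction)
        }
        attr(x, "penalized") <- TRUE
      }
    }
  }
  x
}

#' Run the mean-field model
#'
#' Iterates [meanfield_step()] for `n_steps` steps, applying the suppression
#' check on steps where the schedule is active, and records abundances and
#' Hill numbers in the same trajectory schema as the lattice engine
#' (real-valued `x_i` in place of integer counts).
#'
#' @param params a [meanfield_params()].
#' @return An object of class `meanfield_run`: list with `trajectory`
#'   (`data.frame`: `step`, `x_1..x_n`, `total`, `hill_q0`, `hill_q1`,
#'   `hill_q2`, `penalized`) and `params`. The q = 0 column counts taxa above
#'   the extinction tolerance `1e-6 * K` (floating-point abundances never
#'   reach exact zero under a multiplicative map).
#' @examples
#' mf <- meanfield_run(meanfield_params(mode = "off", n_steps = 300))
#' tail(mf$trajectory, 1)  # fastest grower displaces the rest
#' @export
meanfield_run <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  n <- params$n
  x <- params$x0
  tol <- 1e-6 * params$K
  n_steps <- params$n_steps
  X <- matrix(0, nrow = n_steps, ncol = n)
  hill <- matrix(0, nrow = n_steps, ncol = 3L)
  fired <- logical(n_steps)
  for (t in seq_len(n_steps)) {
    x <- meanfield_step(x, params, suppress = is_active(params$schedule,
                                                        t - 1L))
    fired[t] <- isTRUE(attr(x, "penalized"))
    attr(x, "penalized") <- NULL
    X[t, ] <- x
    # richness under the extinction tolerance; q = 1, 2 from raw abundances
    alive <- x[x > tol]
    hill[t, 1L] <- length(alive)
    hill[t, 2L:3L] <- if (length(alive)) hill_number(alive, c(1, 2)) else 0
  }
  traj <- data.frame(step = seq_len(n_steps) - 1L, X, total = rowSums(X),
                     hill, penalized = fired)
  names(traj) <- c("step", paste0("x_", seq_len(n)), "total",
                   "hill_q0", "hill_q1", "hill_q2", "penalized")
  structure(list(trajectory = traj, params = params),
            class = "meanfield_run")
}

#' @export
print.meanfield_run <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf("<meanfield_run> %d taxa, %d steps, surveillance %s\n",
              x$params$n, nrow(tr), x$params$schedule$mode))
  cat("  final abundances:",
      paste(sprintf("%.2f", unlist(last[paste0("x_", seq_len(x$params$n))])),
            collapse = " "), "\n")
  invisible(x)
}

#' Survivors of a mean-field trajectory
#'
#' @param run a `meanfield_run`.
#' @param tol extinction tolerance; defaults to `1e-6 * K`.
#' @return Integer ids of taxa whose final abundance exceeds `tol`.
#' @export
meanfield_survivors <- function(run, tol = 1e-6 * run$params$K) {
  last <- run$trajectory[nrow(run$trajectory), ]
  x <- unlist(last[paste0("x_", seq_len(run$params$n))])
  which(unname(x) > tol)
}
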