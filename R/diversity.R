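#' Hill number (effective species number) of order q
#'
#' With relative abundances \eqn{p_i} over species with nonzero counts, the
#' Hill number of order \eqn{q \ge 0} is
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' with the \eqn{q = 1} case taken as its limit, the exponential of Shannon
#' entropy \eqn{\exp(-\sum_i p_i \ln p_i)}. Orders 0, 1 and 2 are species
#' richness, exponential Shannon diversity, and inverse Simpson diversity.
#' Zero-count species are excluded from all sums (so \eqn{0 \ln 0 = 0} never
#' arises); the empty community has diversity 0 by convention, so collapsed
#' trajectories remain representable. Richness (q = 0) is returned as an
#' exact integer count.
#'
#' @param x a `ktw_abundance` (see [count_abundances()]) or a non-negative
#'   numeric vector of counts/abundances.
#' @param q non-negative order(s); vectorised.
#' @return Numeric vector, one effective species number per `q`.
#' @examples
#' hill_number(c(70, 10, 10, 10), q = 2)  # 1 / 0.52
#' hill_number(c(90, 90, 90, 90), q = c(0, 1, 2))  # 4 4 4
#' @export
hill_number <- function(x, q) {
  counts <- as_count_vector(x)
  if (!is.numeric(q) || anyNA(q)) stop("`q` must be numeric")
  if (any(q < 0)) stop("`q` must be non-negative")
  p <- counts[counts > 0]
  if (length(p) == 0L) return(rep(0, length(q)))
  p <- p / sum(p)
  vapply(q, function(qq) {
    if (qq == 0) return(as.numeric(length(p)))
    if (qq == 1) return(exp(-sum(p * log(p))))
    sum(p^qq)^(1 / (1 - qq))
  }, numeric(1L))
}

as_count_vector <- function(x) {
  if (inherits(x, "ktw_abundance")) x <- x$counts
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("counts must be non-negative numbers")
  x
}

#' Hill diversity profile at a set of orders
#'
#' @inheritParams hill_number
#' @return Named numeric vector (`hill_q<q>`), non-increasing in `q`.
#' @export
hill_profile <- function(x, q = c(0, 1, 2)) {
  out <- hill_number(x, q)
  names(out) <- paste0("hill_q", q)
  out
}

#' Shannon entropy and Simpson concentration (secondary indices)
#'
#' The raw indices underlying the q = 1 and q = 2 Hill numbers:
#' `shannon_index()` returns \eqn{H = -\sum p_i \ln p_i} and
#' `simpson_index()` returns \eqn{\lambda = \sum p_i^2} (so the inverse
#' Simpson diversity is \eqn{1/\lambda}).
#'
#' @inheritParams hill_number
#' @return A single numeric value (0 for an empty community; `simpson_index`
#'   returns `NA` for an empty community since concentration is undefined).
#' @export
shannon_index <- function(x) {
  h1 <- hill_number(x, 1)
  if (h1 == 0) 0 else log(h1)
}

#' @rdname shannon_index
#' @export
simpson_index <- function(x) {
  h2 <- hill_number(x, 2)
  if (h2 == 0) NA_real_ else 1 / h2
}

#' Recompute the per-step Hill diversity series of a trajectory
#'
#' Computes `hill_q0`, `hill_q1`, `hill_q2` (or any requested orders) from the
#' per-step species counts of a trajectory table, independent of any diversity
#' columns already present.
#'
#' @param traj a trajectory `data.frame` with columns `count_1 .. count_n`
#'   (as produced by [ktw_run()] / [meanfield_run()] or read back by
#'   [read_trajectory()]), or a `ktw_run` object.
#' @param q diversity orders; default `c(0, 1, 2)`.
#' @return A `data.frame` with `step` and one `hill_q<q>` column per order.
#' @export
diversity_trajectory <- function(traj, q = c(0, 1, 2)) {
  if (inherits(traj, "ktw_run")) traj <- traj$trajectory
  stopifnot(is.data.frame(traj), nrow(traj) >= 1L)
  cc <- grep("^count_[0-9]+$", names(traj))
  if (length(cc) == 0L) cc <- grep("^x_[0-9]+$", names(traj))
  if (length(cc) == 0L)
    stop("no per-species count columns (count_* or x_*) found")
  counts <- as.matrix(traj[, cc, drop = FALSE])
  prof <- t(apply(counts, 1L, hill_number, q = q))
  out <- data.frame(step = if ("step" %in% names(traj)) traj$step
                    else seq_len(nrow(traj)) - 1L)
  out[paste0("hill_q", q)] <- as.data.frame(prof)
  out
}
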