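#' Two-threshold immune surveillance rule
#'
#' Surveillance fires when the community load (occupied sites as a share of
#' all lattice sites) strictly exceeds `load_threshold` AND the most abundant
#' species' relative abundance (share of occupied sites) strictly exceeds
#' `dominance_threshold`. When it fires, `removal_fraction` of the target's
#' cells are removed. With the default `dominant_taxon` policy the removal is
#' directed at the dominant species only; `whole_community` removes the same
#' fraction of every species (retained for sensitivity analysis).
#'
#' @param load_threshold fraction of all lattice sites in (0, 1]; default 0.70.
#' @param dominance_threshold relative-abundance fraction in (0, 1];
#'   default 0.30.
#' @param removal_fraction fraction of cells removed per event in (0, 1];
#'   default 0.80.
#' @param target_policy `"dominant_taxon"` (default) or `"whole_community"`.
#' @return An object of class `surveillance_rule`.
#' @export
surveillance_rule <- function(load_threshold = 0.70,
                              dominance_threshold = 0.30,
                              removal_fraction = 0.80,
                              target_policy = c("dominant_taxon",
                                                "whole_community")) {
  target_policy <- match.arg(target_policy)
  for (nm in c("load_threshold", "dominance_threshold", "removal_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stop("`", nm, "` must be a single value in (0, 1]")
  }
  structure(list(load_threshold = load_threshold,
                 dominance_threshold = dominance_threshold,
                 removal_fraction = removal_fraction,
                 target_policy = target_policy),
            class = "surveillance_rule")
}

#' Evaluate the surveillance trigger on an abundance vector
#'
#' Both comparisons are strict ("exceeded"): occupancy exactly at the load
#' threshold, or a share exactly at the dominance threshold, does not fire.
#' Ties for the dominant species are broken by the lowest species id.
#'
#' @param abundances a `ktw_abundance` (see [count_abundances()]).
#' @param rule a [surveillance_rule()].
#' @return List with `fired` (logical) and `target` (dominant species id when
#'   fired, otherwise `NA`).
#' @examples
#' ab <- abundance_vector(c(120, 60, 60, 60), total_sites = 400)
#' surveillance_trigger(ab, surveillance_rule())  # 75% load, 40% share: fires
#' @export
surveillance_trigger <- function(abundances, rule) {
  stopifnot(inherits(abundances, "ktw_abundance"),
            inherits(rule, "surveillance_rule"))
  occupied <- sum(abundances$counts)
  load <- occupied / abundances$total_sites
  if (occupied == 0L || load <= rule$load_threshold)
    return(list(fired = FALSE, target = NA_integer_))
  p <- rel_abundance(abundances)
  if (max(p) <= rule$dominance_threshold)
    return(list(fired = FALSE, target = NA_integer_))
  list(fired = TRUE, target = which.max(p))  # which.max: lowest id on ties
}

# round half away from zero; base round() is round-half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Apply a penalization event to a lattice
#'
#' Removes exactly `round(removal_fraction * count)` cells (rounding half away
#' from zero) of the target species, sampled uniformly without replacement;
#' all other species are untouched. Under the `whole_community` policy the
#' same fractional removal is applied to every species present and `target`
#' is ignored.
#'
#' Draws from the caller's RNG stream; [ktw_run()] manages a dedicated
#' penalization substream so events never perturb the dynamics draws.
#'
#' @param lattice a [hex_lattice()].
#' @param target species id to penalize (dominant taxon).
#' @param rule a [surveillance_rule()].
#' @return The lattice after removal.
#' @export
penalize <- function(lattice, target, rule) {
  stopifnot(inherits(lattice, "hex_lattice"),
            inherits(rule, "surveillance_rule"))
  if (rule$target_policy == "whole_community") {
    present <- sort(unique(lattice$occupancy[lattice$occupancy > 0L]))
    for (sp in present) lattice <- remove_fraction(lattice, sp,
                                                  rule$removal_fraction)
    return(lattice)
  }
  stopifnot(length(target) == 1L, !is.na(target))
  if (!any(lattice$occupancy == target))
    stop("target species ", target, " is absent from the lattice")
  remove_fraction(lattice, target, rule$removal_fraction)
}

remove_fraction <- function(lattice, sp, fraction) {
  sites <- which(lattice$occupancy == sp)
  k <- as.integer(round_half_up(fraction * length(sites)))
  if (k > 0L) {
    drop <- if (length(sites) == 1L) sites else sample(sites, k)
    lattice$occupancy[drop] <- 0L
  }
  lattice
}

#' Temporal activation schedule for surveillance
#'
#' @param mode `"always"`, `"off"`, or `"windows"`.
#' @param windows for `"windows"` mode, a list of `c(start, end)` pairs (or a
#'   two-column matrix) of half-open step intervals `[start, end)` in 0-based
#'   step indices; must be non-overlapping and sorted.
#' @return An object of class `ktw_schedule`.
#' @examples
#' sch <- schedule("windows", list(c(200, 400), c(600, 800)))
#' is_active(sch, 199); is_active(sch, 200)  # FALSE, TRUE
#' @export
schedule <- function(mode = c("always", "off", "windows"), windows = NULL) {
  mode <- match.arg(mode)
  if (mode == "windows") {
    if (is.null(windows)) stop("`windows` required for windows mode")
    if (is.list(windows)) windows <- do.call(rbind, windows)
    windows <- matrix(as.numeric(windows), ncol = 2L)
    if (any(is.na(windows)) || any(windows < 0) ||
        any(windows[, 1L] >= windows[, 2L]))
      stop("each window must satisfy 0 <= start < end")
    if (nrow(windows) > 1L) {
      o <- order(windows[, 1L])
      windows <- windows[o, , drop = FALSE]
      if (any(windows[-1L, 1L] < windows[-nrow(windows), 2L]))
        stop("windows must be non-overlapping")
    }
    colnames(windows) <- c("start", "end")
  } else {
    windows <- NULL
  }
  structure(list(mode = mode, windows = windows), class = "ktw_schedule")
}

#' @rdname schedule
#' @param x a `ktw_schedule`.
#' @param step 0-based step index (vectorised).
#' @return `is_active()`: logical, whether surveillance is active at `step`.
#' @export
is_active <- function(x, step) {
  stopifnot(inherits(x, "ktw_schedule"), all(step >= 0))
  switch(x$mode,
         off = rep(FALSE, length(step)),
         always = rep(TRUE, length(step)),
         windows = vapply(step, function(s) {
           any(s >= x$windows[, "start"] & s < x$windows[, "end"])
         }, logical(1L)))
}
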