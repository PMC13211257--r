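#' Build a full run configuration
#'
#' Collects every knob of the lattice engine with the model's default
#' parameter set: a 60 x 60 toroidal hexagonal lattice, four species with
#' replication probabilities (0.3, 0.5, 0.7, 0.9), per-cell mortality 0.05,
#' 10\% equal-abundance initial occupancy, 1,000 steps, and surveillance
#' thresholds 70\% load / 30\% dominance with 80\% removal of the dominant
#' taxon.
#'
#' @param width,height lattice dimensions (>= 3).
#' @param replication_probs per-species per-step replication probabilities in
#'   `[0, 1]`; the roster size is `length(replication_probs)`.
#' @param mortality per-cell per-step death probability in `[0, 1)`.
#' @param init_occupancy initial occupancy fraction in (0, 1].
#' @param n_steps number of update steps (>= 1).
#' @param surveillance a list with elements `mode` ("always", "off",
#'   "windows"), `windows`, `load_threshold`, `dominance_threshold`,
#'   `removal_fraction`, `target_policy`; missing elements take defaults.
#' @param seed master integer seed; all substreams (initialization, dynamics,
#'   penalization sampling) derive from it.
#' @return A validated object of class `ktw_config`.
#' @examples
#' cfg <- ktw_config(n_steps = 50, seed = 7)
#' @export
ktw_config <- function(width = 60, height = 60,
                       replication_probs = c(0.3, 0.5, 0.7, 0.9),
                       mortality = 0.05,
                       init_occupancy = 0.10,
                       n_steps = 1000,
                       surveillance = list(),
                       seed = 1L) {
  sdef <- list(mode = "always", windows = NULL,
               load_threshold = 0.70, dominance_threshold = 0.30,
               removal_fraction = 0.80, target_policy = "dominant_taxon")
  unknown <- setdiff(names(surveillance), names(sdef))
  if (length(unknown))
    stop("unknown surveillance key(s): ",
         paste0("surveillance.", unknown, collapse = ", "))
  surveillance <- modifyList(sdef, surveillance)
  cfg <- structure(list(width = width, height = height,
                        replication_probs = replication_probs,
                        mortality = mortality,
                        init_occupancy = init_occupancy,
                        n_steps = n_steps,
                        surveillance = surveillance,
                        seed = seed),
                   class = "ktw_config")
  validate_config(cfg)
}

#' @export
print.ktw_config <- function(x, ...) {
  cat(sprintf("<ktw_config> %dx%d lattice, %d species, %d steps, seed %d\n",
              x$width, x$height, length(x$replication_probs),
              x$n_steps, x$seed))
  cat("  replication:", paste(x$replication_probs, collapse = " "),
      " mortality:", x$mortality, " init:", x$init_occupancy, "\n")
  s <- x$surveillance
  cat(sprintf("  surveillance: %s load>%.2f dom>%.2f remove %.2f (%s)\n",
              s$mode, s$load_threshold, s$dominance_threshold,
              s$removal_fraction, s$target_policy))
  invisible(x)
}

check_range <- function(value, key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(value) || length(value) == 0L || anyNA(value) ||
    any(if (lo_open) value <= lo else value < lo) ||
    any(if (hi_open) value >= hi else value > hi)
  if (bad)
    stop(sprintf("`%s` must be in %s%g, %g%s", key,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  invisible(value)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ktw_config"))
  if (cfg$width < 3 || cfg$height < 3 ||
      cfg$width != as.integer(cfg$width) || cfg$height != as.integer(cfg$height))
    stop("`width` and `height` must be integers >= 3")
  cfg$width <- as.integer(cfg$width); cfg$height <- as.integer(cfg$height)
  check_range(cfg$replication_probs, "replication_probs", 0, 1)
  check_range(cfg$mortality, "mortality", 0, 1, hi_open = TRUE)
  check_range(cfg$init_occupancy, "init_occupancy", 0, 1, lo_open = TRUE)
  if (!is.numeric(cfg$n_steps) || length(cfg$n_steps) != 1L ||
      cfg$n_steps < 1 || cfg$n_steps != as.integer(cfg$n_steps))
    stop("`n_steps` must be a positive integer")
  cfg$n_steps <- as.integer(cfg$n_steps)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("`seed` must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  s <- cfg$surveillance
  # constructors re-validate thresholds/windows and report the offending key
  rule <- surveillance_rule(s$load_threshold, s$dominance_threshold,
                            s$removal_fraction, s$target_policy)
  sch <- schedule(s$mode, s$windows)
  if (sch$mode == "windows" && any(sch$windows > cfg$n_steps))
    stop("`surveillance.windows` must lie within [0, n_steps]")
  cfg
}

as_rule <- function(cfg) {
  s <- cfg$surveillance
  surveillance_rule(s$load_threshold, s$dominance_threshold,
                    s$removal_fraction, s$target_policy)
}

as_schedule <- function(cfg) schedule(cfg$surveillance$mode,
                                      cfg$surveillance$windows)

#' Read a run configuration from a YAML file
#'
#' The file mirrors the module structure with dotted sections:
#' `lattice` (`width`, `height`), `species` (`replication_probs`),
#' `dynamics` (`mortality`, `init_occupancy`, `n_steps`),
#' `surveillance` (`mode`, `windows`, `load_threshold`,
#' `dominance_threshold`, `removal_fraction`, `target_policy`), and a
#' top-level `seed`. Missing keys take the defaults of [ktw_config()];
#' unknown keys are an error naming the key. Resolution order is
#' defaults < file < `overrides`, so command-line flags win.
#'
#' An empty (or absent-section) file therefore resolves to the default model:
#' 4 species, 60 x 60, 1,000 steps, surveillance always with thresholds
#' 0.70 / 0.30 / 0.80.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides named list of flat overrides using dotted keys (e.g.
#'   `list("seed" = 42, "surveillance.mode" = "off")`).
#' @return A validated `ktw_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  sections <- list(lattice = c("width", "height"),
                   species = "replication_probs",
                   dynamics = c("mortality", "init_occupancy", "n_steps"),
                   surveillance = c("mode", "windows", "load_threshold",
                                    "dominance_threshold", "removal_fraction",
                                    "target_policy"))
  unknown <- setdiff(names(raw), c(names(sections), "seed"))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- list()
  for (sec in names(sections)) {
    got <- raw[[sec]]
    if (is.null(got)) next
    bad <- setdiff(names(got), sections[[sec]])
    if (length(bad)) stop("unknown config key(s): ",
                          paste0(sec, ".", bad, collapse = ", "))
    if (sec == "surveillance") {
      args$surveillance <- got
    } else {
      args <- c(args, got)
    }
  }
  if (!is.null(raw$seed)) args$seed <- raw$seed
  # flat dotted overrides (CLI flags) beat the file
  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (is.null(val)) next
    if (startsWith(key, "surveillance.")) {
      sub <- sub("^surveillance\\.", "", key)
      if (!sub %in% sections$surveillance)
        stop("unknown config key(s): ", key)
      if (is.null(args$surveillance)) args$surveillance <- list()
      args$surveillance[[sub]] <- val
    } else {
      key2 <- sub("^[a-z]+\\.", "", key)
      if (!key2 %in% c(unlist(sections[c("lattice", "species", "dynamics")]),
                       "seed"))
        stop("unknown config key(s): ", key)
      args[[key2]] <- val
    }
  }
  do.call(ktw_config, args)
}

# serializable plain-list view of a config (sidecar JSON / sidecar round-trip)
config_as_list <- function(cfg) {
  list(lattice = list(width = cfg$width, height = cfg$height),
       species = list(replication_probs = cfg$replication_probs),
       dynamics = list(mortality = cfg$mortality,
                       init_occupancy = cfg$init_occupancy,
                       n_steps = cfg$n_steps),
       surveillance = cfg$surveillance[!vapply(cfg$surveillance, is.null,
                                               logical(1L))],
       seed = cfg$seed)
}

config_from_list <- function(lst) {
  surv <- lst$surveillance
  if (!is.null(surv$windows) && !is.list(surv$windows) &&
      !is.matrix(surv$windows))
    surv$windows <- matrix(surv$windows, ncol = 2L)
  if (!is.null(surv$windows) && is.list(surv$windows))
    surv$windows <- do.call(rbind, lapply(surv$windows, unlist))
  ktw_config(width = lst$lattice$width, height = lst$lattice$height,
             replication_probs = unlist(lst$species$replication_probs),
             mortality = lst$dynamics$mortality,
             init_occupancy = lst$dynamics$init_occupancy,
             n_steps = lst$dynamics$n_steps,
             surveillance = surv,
             seed = lst$seed)
}
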