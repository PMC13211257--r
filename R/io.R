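#' Write / read a lattice snapshot TSV
#'
#' Long-format TSV with header `col<TAB>row<TAB>species_id` (0-based axial
#' coordinates); empty sites are omitted. Lattice dimensions and roster size
#' are carried in `#`-prefixed metadata lines before the header so a snapshot
#' round-trips exactly, including trailing empty columns/rows.
#'
#' @param lattice a [hex_lattice()].
#' @param path output file path.
#' @return `write_snapshot()`: `path`, invisibly. `read_snapshot()`: the
#'   reconstructed [hex_lattice()].
#' @export
write_snapshot <- function(lattice, path) {
  stopifnot(inherits(lattice, "hex_lattice"))
  occ <- which(lattice$occupancy > 0L)
  xy <- site_coords(lattice, occ)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# width=%d", lattice$width),
               sprintf("# height=%d", lattice$height),
               sprintf("# n_species=%d", lattice$n_species),
               "col\trow\tspecies_id"), con)
  if (length(occ))
    write.table(data.frame(col = xy$col, row = xy$row,
                           species_id = lattice$occupancy[occ]),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @param path path to a snapshot TSV written by [write_snapshot()].
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  getm <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) != 1L) stop("snapshot missing metadata line: ", key)
    as.integer(sub(paste0("^# ", key, "="), "", m))
  }
  width <- getm("width"); height <- getm("height")
  n_species <- getm("n_species")
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"))
  lat <- hex_lattice(width, height, n_species)
  if (nrow(df)) {
    if (any(df$species_id < 1L) || any(df$species_id > n_species))
      stop("snapshot species_id out of range 1..", n_species)
    lat$occupancy[site_index(lat, df$col, df$row)] <- as.integer(df$species_id)
  }
  lat
}

#' Write / read a trajectory TSV with a JSON metadata sidecar
#'
#' The trajectory table is written as plain TSV (`step`, per-species counts,
#' `total`, `hill_q0..q2`, `penalized`, one row per step; reals at full
#' precision). For a `ktw_run`, the fully resolved configuration, the master
#' seed and the package version are written to `<path>.json`, so the run is
#' reproducible from the sidecar alone (see [run_from_sidecar()]).
#'
#' @param x a `ktw_run`, `meanfield_run`, or bare trajectory `data.frame`.
#' @param path output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_trajectory()`: `path`, invisibly; `read_trajectory()`: the
#'   trajectory `data.frame`.
#' @export
write_trajectory <- function(x, path) {
  traj <- if (is.data.frame(x)) x else x$trajectory
  df <- traj
  if ("penalized" %in% names(df)) df$penalized <- as.integer(df$penalized)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "ktw_run")) {
    meta <- list(config = config_as_list(x$config),
                 artifact = list(package = "hexktw",
                                 version = as.character(packageVersion("hexktw"))))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if ("penalized" %in% names(df)) df$penalized <- as.logical(df$penalized)
  df
}

#' Re-run a simulation from a trajectory's JSON sidecar
#'
#' Reads the resolved config (including the seed) from the sidecar written by
#' [write_trajectory()] and replays the run; the result is bit-identical to
#' the original.
#'
#' @param sidecar_path path to the `<trajectory>.json` sidecar.
#' @return A `ktw_run`.
#' @export
run_from_sidecar <- function(sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  ktw_run(config_from_list(meta$config))
}
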