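#' Plot abundance and diversity panels of one or more runs
#'
#' For each run, draws a per-species abundance-over-time panel and a
#' Hill-number-over-time panel (q = 0, 1, 2), with active surveillance
#' windows shaded. Purely presentational: every number shown comes from the
#' trajectory itself.
#'
#' @param runs a `ktw_run` / `meanfield_run`, or a (optionally named) list of
#'   them; all trajectories must share the same step range.
#' @param file optional output path (`.png`, `.svg`, `.pdf`); when given the
#'   figure is written with `ggplot2::ggsave()`.
#' @param width,height,dpi device size passed to `ggsave()`.
#' @return The ggplot object, invisibly.
#' @export
plot_panels <- function(runs, file = NULL, width = 9, height = 3.2 * 2,
                        dpi = 150) {
  if (inherits(runs, c("ktw_run", "meanfield_run"))) runs <- list(runs)
  stopifnot(is.list(runs), length(runs) >= 1L)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run ", seq_along(runs))

  steps <- lapply(runs, function(r) r$trajectory$step)
  if (length(unique(vapply(steps, length, integer(1L)))) != 1L)
    stop("trajectories must share the same step range")
  if (any(vapply(runs, function(r) nrow(r$trajectory), integer(1L)) == 0L))
    stop("empty trajectory")

  longify <- function(run, label) {
    tr <- run$trajectory
    cc <- grep("^(count|x)_[0-9]+$", names(tr), value = TRUE)
    ab <- do.call(rbind, lapply(cc, function(col) {
      data.frame(run = label, step = tr$step,
                 series = paste("species", sub("^(count|x)_", "", col)),
                 value = tr[[col]], panel = "abundance")
    }))
    hv <- do.call(rbind, lapply(c("hill_q0", "hill_q1", "hill_q2"),
                                function(col) {
      data.frame(run = label, step = tr$step,
                 series = sub("hill_q", "q = ", col),
                 value = tr[[col]], panel = "Hill diversity")
    }))
    rbind(ab, hv)
  }
  dat <- do.call(rbind, Map(longify, runs, names(runs)))
  dat$panel <- factor(dat$panel, levels = c("abundance", "Hill diversity"))

  shade <- do.call(rbind, Map(function(run, label) {
    sch <- if (inherits(run, "ktw_run")) as_schedule(run$config)
           else run$params$schedule
    if (sch$mode != "windows") return(NULL)
    data.frame(run = label, start = sch$windows[, "start"],
               end = sch$windows[, "end"])
  }, runs, names(runs)))

  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$value,
                                         colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(panel ~ run, scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(shade) && nrow(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey40", alpha = 0.15)
  }
  if (!is.null(file))
    ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(p)
}
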