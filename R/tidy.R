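#' Tidiers and plots for simulation results
#'
#' `tidy()` returns the per-cycle work table of a work-loop trial; `glance()`
#' a one-row summary. `autoplot()` draws the stress-strain loop (work loop)
#' of the recorded cycles; `plot_phase_sweep()` and `plot_lattice_sweep()`
#' draw sweep tibbles with per-cycle standard error ribbons.
#'
#' @param x a `workloop_result`.
#' @param ... unused.
#' @name result-tidiers
NULL

#' @rdname result-tidiers
#' @export
tidy.workloop_result <- function(x, ...) {
  tibble::tibble(cycle = seq_along(x$per_cycle_work),
                 work = x$per_cycle_work)
}

#' @rdname result-tidiers
#' @export
glance.workloop_result <- function(x, ...) {
  tibble::tibble(phi = x$protocol$phi,
                 face_spacing = x$protocol$base_face_spacing,
                 lattice_mode = x$protocol$lattice_mode,
                 frequency = x$protocol$frequency,
                 n_cycles = length(x$per_cycle_work),
                 work_mean = x$work_mean, work_sd = x$work_sd,
                 work_se = x$work_sd / sqrt(length(x$per_cycle_work)),
                 seed = x$seed)
}

#' @rdname result-tidiers
#' @param object a `workloop_result`.
#' @export
autoplot.workloop_result <- function(object, ...) {
  pr <- object$protocol
  spc <- round(pr$period / pr$dt)
  tr <- object$trace
  tr <- tr[-seq_len(pr$warmup_cycles * spc), ]
  tr$cycle <- factor(ceiling(seq_len(nrow(tr)) / spc))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$strain, y = .data$stress,
                                   group = .data$cycle)) +
    ggplot2::geom_path(alpha = 0.35, colour = "steelblue4") +
    ggplot2::labs(
      x = "strain", y = expression(stress ~ (mN ~ mm^-2)),
      title = sprintf("Work loop: phi = %.2f, LS = %.1f nm (%s)",
                      pr$phi, pr$base_face_spacing, pr$lattice_mode),
      subtitle = sprintf("net work %.2f +/- %.2f J/kg over %d cycles",
                         object$work_mean, object$work_sd,
                         length(object$per_cycle_work)))
}

#' @rdname result-tidiers
#' @param sweep a tibble from [phase_sweep()] or [lattice_sweep()].
#' @export
plot_phase_sweep <- function(sweep, ...) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$phi, y = .data$work_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$work_mean - .data$work_se,
                                      ymax = .data$work_mean + .data$work_se),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "phase of activation", y = "net work (J/kg)")
}

#' @rdname result-tidiers
#' @export
plot_lattice_sweep <- function(sweep, ...) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$face_spacing,
                                      y = .data$work_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$work_mean - .data$work_se,
                                      ymax = .data$work_mean + .data$work_se),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "actin-myosin face spacing (nm)", y = "net work (J/kg)")
}
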