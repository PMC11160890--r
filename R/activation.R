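#' Actin permissiveness parameters
#'
#' The whole Ca2+/troponin/tropomyosin activation chain is lumped into one
#' 'actin permissiveness' signal in `[0, 1]`: the fraction of actin sites
#' available for myosin binding, which multiplies every binding probability.
#' The pulse is built from two exponentials: a saturating rise toward
#' `peak_level` with time constant `tau_rise` during the stimulus window
#' `[onset, onset + stim_duration]` (Ca2+ influx), then an exponential decay
#' with half-life `t_half_decay` (re-uptake).
#'
#' @param tau_rise rise time constant, ms.
#' @param t_half_decay decay half-life, ms.
#' @param stim_duration stimulus window length, ms (permissiveness peaks at
#'   its end).
#' @param onset stimulus start time, ms.
#' @param peak_level saturation level in `[0, 1]`.
#' @export
activation_params <- function(tau_rise = 5, t_half_decay = 10,
                              stim_duration = 13, onset = 0, peak_level = 1) {
  check_positive(tau_rise, "tau_rise")
  check_positive(t_half_decay, "t_half_decay")
  check_positive(stim_duration, "stim_duration")
  if (peak_level < 0 || peak_level > 1)
    abort_config("peak_level", "must lie in [0, 1]")
  structure(list(tau_rise = tau_rise, t_half_decay = t_half_decay,
                 stim_duration = stim_duration, onset = onset,
                 peak_level = peak_level), class = "activation_params")
}

#' Actin permissiveness at time t
#'
#' Single-pulse permissiveness: 0 before onset, a saturating exponential rise
#' during the stimulus window, then exponential decay. Continuous everywhere
#' and bounded in `[0, 1]`.
#'
#' @param t time, ms (vectorized).
#' @param params an [activation_params()].
#' @export
permissiveness <- function(t, params = activation_params()) {
  s <- t - params$onset
  v <- numeric(length(s))
  rising <- s >= 0 & s <= params$stim_duration
  v[rising] <- params$peak_level * (1 - exp(-s[rising] / params$tau_rise))
  decaying <- s > params$stim_duration
  v_end <- params$peak_level * (1 - exp(-params$stim_duration / params$tau_rise))
  v[decaying] <- v_end * 2^(-(s[decaying] - params$stim_duration) / params$t_half_decay)
  pmin(pmax(v, 0), 1)
}

#' Phase-locked periodic activation
#'
#' One twitch-shaped permissiveness pulse per strain cycle, with onset at
#' phase `phi` of the cycle (`phi = 0` is the start of shortening). Pulse
#' tails wrap across cycle boundaries.
#'
#' @param phi phase of activation, cycle fraction in `[0, 1)`.
#' @param period cycle period, ms.
#' @param params an [activation_params()].
#' @export
phased_activation <- function(phi, period, params = activation_params()) {
  if (phi < 0 || phi >= 1) abort_config("phi", "must lie in [0, 1)")
  check_positive(period, "period")
  structure(list(phi = phi, period = period, params = params),
            class = "phased_activation")
}

#' @rdname phased_activation
#' @param t time, ms (vectorized).
#' @param phased a [phased_activation()].
#' @export
periodic_permissiveness <- function(t, phased) {
  stopifnot(inherits(phased, "phased_activation"))
  p <- phased$params
  p0 <- activation_params(p$tau_rise, p$t_half_decay, p$stim_duration,
                          onset = 0, peak_level = p$peak_level)
  s <- (t - phased$phi * phased$period) %% phased$period
  # current pulse plus decaying tails of up to three earlier cycles
  v <- permissiveness(s, p0)
  for (k in 1:3) v <- v + permissiveness(s + k * phased$period, p0)
  pmin(v, 1)
}

#' Descriptors of an isometric twitch force trace
#'
#' @param trace a data frame with columns `time` (ms) and `force`.
#' @param tetanus_level plateau force of a sustained (tetanic) stimulus, same
#'   units as `force`.
#' @param baseline passive force to subtract before measuring, default the
#'   trace's first value.
#' @return list with `time_to_peak` (ms), `half_relaxation` (ms after the
#'   peak), and `peak_frac` (peak force over the tetanic plateau).
#' @export
twitch_descriptors <- function(trace, tetanus_level, baseline = NULL) {
  f <- trace$force
  if (is.null(baseline)) baseline <- f[1L]
  f <- f - baseline
  ipk <- which.max(f)
  pk <- f[ipk]
  after <- which(seq_along(f) > ipk & f <= pk / 2)
  half_rel <- if (length(after)) trace$time[after[1L]] - trace$time[ipk] else NA_real_
  list(time_to_peak = trace$time[ipk] - trace$time[1L],
       half_relaxation = half_rel,
       peak_frac = pk / (tetanus_level - baseline))
}

# cheap deterministic stand-in for a full isometric simulation: force follows
# the permissiveness through first-order dynamics with time constant tau_force
surrogate_twitch_force <- function(params, duration = 150, dt = 0.5,
                                   tau_force = 8) {
  tt <- seq(0, duration, by = dt)
  perm <- permissiveness(tt, params)
  f <- numeric(length(tt))
  for (i in seq_along(tt)[-1L])
    f[i] <- f[i - 1L] + dt * (perm[i - 1L] - f[i - 1L]) / tau_force
  tibble::tibble(time = tt, force = f)
}

#' Fit activation parameters to twitch descriptors
#'
#' Finds `tau_rise`, `stim_duration` and `t_half_decay` such that an
#' isometric twitch's time-to-peak, half-relaxation time and peak force
#' (as a fraction of the tetanic plateau) match the target descriptors.
#' By default a fast deterministic first-order force surrogate evaluates the
#' candidates; pass `simulate` to use the full stochastic simulator (see
#' [run_isometric()]), at a far higher cost.
#'
#' @param target list with `time_to_peak` (ms), `half_relaxation` (ms) and
#'   `peak_frac` in (0, 1].
#' @param init starting [activation_params()].
#' @param simulate function(params) returning a data frame with `time` and
#'   `force` columns for a single twitch; its tetanic plateau is taken from a
#'   long-stimulus variant of the same parameters.
#' @param control passed to [stats::optim()].
#' @return an [activation_params()] with attributes `convergence` and `value`.
#' @export
fit_twitch <- function(target, init = activation_params(), simulate = NULL,
                       control = list(maxit = 400, reltol = 1e-10)) {
  stopifnot(is.list(target),
            all(c("time_to_peak", "half_relaxation", "peak_frac") %in% names(target)))
  if (is.null(simulate)) simulate <- function(p) surrogate_twitch_force(p)
  descr_of <- function(p) {
    tw <- simulate(p)
    tet <- simulate(activation_params(p$tau_rise, p$t_half_decay,
                                      stim_duration = 1e4, onset = p$onset,
                                      peak_level = p$peak_level))
    twitch_descriptors(tw, tetanus_level = max(tet$force))
  }
  obj <- function(par) {
    p <- activation_params(tau_rise = exp(par[1L]), t_half_decay = exp(par[2L]),
                           stim_duration = exp(par[3L]),
                           onset = init$onset, peak_level = init$peak_level)
    d <- descr_of(p)
    if (is.na(d$half_relaxation)) return(1e3)
    (d$time_to_peak / target$time_to_peak - 1)^2 +
      (d$half_relaxation / target$half_relaxation - 1)^2 +
      (d$peak_frac / target$peak_frac - 1)^2
  }
  start <- log(c(init$tau_rise, init$t_half_decay, init$stim_duration))
  fit <- stats::optim(start, obj, method = "Nelder-Mead", control = control)
  if (fit$convergence != 0 && fit$value > 1e-4)
    rlang::warn("fit_twitch: optimizer did not fully converge; returning best-so-far")
  out <- activation_params(tau_rise = exp(fit$par[1L]),
                           t_half_decay = exp(fit$par[2L]),
                           stim_duration = exp(fit$par[3L]),
                           onset = init$onset, peak_level = init$peak_level)
  attr(out, "convergence") <- fit$convergence
  attr(out, "value") <- fit$value
  out
}
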