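#' Work-loop protocol
#'
#' Defines the imposed strain and lattice-spacing trajectories for a
#' periodically driven half sarcomere: sinusoidal strain of given frequency
#' and peak-to-peak amplitude, a phase of activation, and one of three
#' lattice modes: `isolattice` (constant face spacing), `poisson` (spacing
#' follows length with Poisson ratio `nu`; `nu = 0.5` is isovolumetric), or
#' `prescribed` (a user/fixture time series of d10 changes).
#'
#' @param frequency cycle frequency, Hz.
#' @param peak_to_peak_strain total strain excursion (0.10 = 10%).
#' @param phi phase of activation, cycle fraction from the start of
#'   shortening, in `[0, 1)`.
#' @param n_cycles recorded cycles (after warmup).
#' @param warmup_cycles cycles discarded before work is measured.
#' @param dt timestep, ms; must divide the period.
#' @param lattice_mode `"isolattice"`, `"poisson"` or `"prescribed"`.
#' @param nu Poisson ratio coupling d10 to strain, in `[0, 0.5]`.
#' @param base_face_spacing face spacing at zero strain, nm.
#' @param prescribed_trace data frame with columns `time` (ms) and
#'   `delta_d10` (nm), periodic over one cycle; required when
#'   `lattice_mode = "prescribed"`.
#' @export
workloop_protocol <- function(frequency = 25, peak_to_peak_strain = 0.10,
                              phi = 0, n_cycles = 16L, warmup_cycles = 1L,
                              dt = 1,
                              lattice_mode = c("isolattice", "poisson", "prescribed"),
                              nu = 0.5, base_face_spacing = 15,
                              prescribed_trace = NULL) {
  lattice_mode <- match.arg(lattice_mode)
  check_positive(frequency, "frequency")
  check_positive(peak_to_peak_strain, "peak_to_peak_strain")
  if (phi < 0 || phi >= 1) abort_config("phi", "must lie in [0, 1)")
  check_positive(dt, "dt")
  check_positive(base_face_spacing, "base_face_spacing")
  if (nu < 0 || nu > 0.5) abort_config("nu", "must lie in [0, 0.5]")
  period <- 1000 / frequency
  if (abs(period / dt - round(period / dt)) > 1e-6)
    abort_config("dt", "must divide the cycle period 1000/frequency")
  if (lattice_mode == "prescribed") {
    if (is.null(prescribed_trace))
      abort_config("prescribed_trace", "is required when lattice_mode = 'prescribed'")
    stopifnot(all(c("time", "delta_d10") %in% names(prescribed_trace)))
  }
  structure(list(frequency = frequency, peak_to_peak_strain = peak_to_peak_strain,
                 phi = phi, n_cycles = as.integer(n_cycles),
                 warmup_cycles = as.integer(warmup_cycles), dt = dt,
                 lattice_mode = lattice_mode, nu = nu,
                 base_face_spacing = base_face_spacing,
                 prescribed_trace = prescribed_trace,
                 period = period), class = "workloop_protocol")
}

#' Stress and mass scaling
#'
#' Converts the per-thick-filament M-line force to tissue stress using the
#' areal density of thick filaments implied by the hexagonal lattice at the
#' reference d10, and mass-specific work using the muscle density. The
#' conversion constants are exposed because published work-loop results are
#' reported in mN/mm^2 and J/kg.
#'
#' @param muscle_density muscle density, kg/m^3.
#' @export
scaling_params <- function(muscle_density = 1060) {
  check_positive(muscle_density, "muscle_density")
  structure(list(muscle_density = muscle_density), class = "scaling_params")
}

#' @rdname scaling_params
#' @param d10 reference d10 spacing, nm.
#' @return thick filaments per square metre of cross-section.
#' @export
thick_filament_density <- function(d10) {
  2 / (sqrt(3) * (sqrt(3) * d10 * 1e-9)^2)
}

# per-thick-filament force (pN) -> stress (mN/mm^2) at reference d10 (nm)
force_to_stress <- function(force_per_filament, d10) {
  force_per_filament * thick_filament_density(d10) * 1e-15
}

#' Imposed strain waveform
#'
#' `eps(t) = (peak_to_peak/2) * cos(2 pi f t / 1000)`: time zero is maximum
#' length, i.e. the start of shortening (phase 0).
#'
#' @param t time, ms (vectorized).
#' @param protocol a [workloop_protocol()].
#' @export
strain_waveform <- function(t, protocol) {
  protocol$peak_to_peak_strain / 2 *
    cos(2 * pi * protocol$frequency * t / 1000)
}

#' Prescribed lattice-spacing trajectory
#'
#' Face spacing at time `t` given the protocol's lattice mode. In `poisson`
#' mode the d10 spacing follows `d10(t) = d10_0 * (1 + dL/L)^(-nu)`, which
#' for `nu = 0.5` keeps `d10^2 * L` exactly constant (isovolumetric); the
#' result is converted back to face spacing. In `prescribed` mode the
#' d10-change trace is linearly interpolated periodically and added on top of
#' the base spacing.
#'
#' @param t time, ms (vectorized).
#' @param strain strain at `t` (same length).
#' @param protocol a [workloop_protocol()].
#' @param lattice a [lattice_state()] supplying the class and radii.
#' @export
lattice_trajectory <- function(t, strain, protocol, lattice) {
  ls0 <- protocol$base_face_spacing
  switch(protocol$lattice_mode,
    isolattice = rep(ls0, length(t)),
    poisson = {
      d10_0 <- face_spacing_to_d10(ls0, lattice$lattice_class, lattice$r_sum)
      d10 <- d10_0 * (1 + strain)^(-protocol$nu)
      lattice$geometry_factor * d10 - lattice$r_sum
    },
    prescribed = {
      tr <- protocol$prescribed_trace
      dd <- stats::approx(tr$time, tr$delta_d10, xout = t %% protocol$period,
                          rule = 2)$y
      ls0 + lattice$geometry_factor * dd
    })
}

#' Synthetic in-vivo-like lattice-spacing trace
#'
#' Builds a periodic d10-change trace emulating the qualitative features of
#' in vivo hawkmoth lattice dynamics during work loops: a sinusoid at the
#' cycle frequency whose amplitude is a fraction of the isovolumetric
#' fundamental and whose peak is phase-advanced relative to it. This is a
#' synthetic fixture, not measured data.
#'
#' @param frequency cycle frequency, Hz.
#' @param peak_to_peak_strain strain amplitude used to derive the
#'   isovolumetric reference.
#' @param base_face_spacing face spacing at zero strain, nm.
#' @param amplitude_factor amplitude relative to the isovolumetric
#'   fundamental (0 gives a flat, isolattice-equivalent trace).
#' @param phase_lead cycle fraction by which the trace leads the
#'   isovolumetric trajectory.
#' @param lattice a [lattice_state()] for the d10 conversion.
#' @param n samples per period.
#' @return tibble with `time` (ms) and `delta_d10` (nm) over one period.
#' @export
make_invivo_trace <- function(frequency = 25, peak_to_peak_strain = 0.10,
                              base_face_spacing = 15, amplitude_factor = 0.75,
                              phase_lead = 0.1, lattice = lattice_state(),
                              n = 200L) {
  stopifnot(amplitude_factor >= 0)
  period <- 1000 / frequency
  tt <- seq(0, period, length.out = n + 1L)[-(n + 1L)]
  w <- 2 * pi * tt / period
  d10_0 <- face_spacing_to_d10(base_face_spacing, lattice$lattice_class, lattice$r_sum)
  eps <- peak_to_peak_strain / 2 * cos(w)
  iso <- d10_0 * ((1 + eps)^(-0.5) - 1)
  # fundamental Fourier component of the isovolumetric trace
  c1 <- 2 * mean(iso * cos(w))
  s1 <- 2 * mean(iso * sin(w))
  amp <- sqrt(c1^2 + s1^2)
  ph0 <- atan2(s1, c1)
  dd <- amplitude_factor * amp * cos(w - ph0 + 2 * pi * phase_lead)
  tibble::tibble(time = tt, delta_d10 = dd)
}

#' Net mass-specific work of one closed stress-strain cycle
#'
#' Trapezoidal loop integral `W = -closed-loop integral of sigma d eps / rho`, signed so that
#' higher stress during shortening (counter-clockwise traversal in the
#' stress-strain plane as simulated) gives positive, motor-like work.
#'
#' @param stress stress trace over exactly one period, mN/mm^2 (= kPa).
#' @param strain strain trace, same length; first and last strain must agree.
#' @param muscle_density muscle density, kg/m^3.
#' @param closure_tol tolerated strain gap between the endpoints.
#' @return net work, J/kg.
#' @export
net_work_per_cycle <- function(stress, strain, muscle_density = 1060,
                               closure_tol = 1e-6) {
  stopifnot(length(stress) == length(strain), length(stress) >= 3L)
  if (abs(strain[1L] - strain[length(strain)]) > closure_tol)
    rlang::abort("strain trajectory is not closed over the cycle",
                 class = "myolattice_contract_error")
  n <- length(strain)
  area <- sum((stress[-1L] + stress[-n]) / 2 * diff(strain))
  -area * 1e3 / muscle_density
}

# ---------------------------------------------------------------------------
# core stepping engine shared by work loops and isometric runs

run_engine <- function(state, times, dt, strain_fn, spacing_fn, perm_fn) {
  n <- length(times)
  force <- numeric(n)
  strain <- numeric(n)
  perm <- numeric(n)
  fs <- numeric(n)
  n_bound <- integer(n)
  n_strong <- integer(n)
  K <- state$solver$kinetic_substeps
  thin_ids <- (state$geometry$n_thick * state$geometry$crowns_per_thick + 1L):state$n_free
  # start from the passively balanced configuration at the initial strain
  state <- balance(apply_axial_strain(state, strain_fn(times[1L])))
  for (i in seq_len(n)) {
    t <- times[i]
    eps <- strain_fn(t)
    L_new <- state$L0 * (1 + eps)
    dZ <- (L_new - state$L) / K
    spacing <- spacing_fn(t, eps)
    state <- set_lattice_spacing(state, spacing)
    # kinetic subcycle: translate the thin filaments with the Z-disk in
    # substep increments so transition hazards track the sliding geometry
    for (k in seq_len(K)) {
      state$L <- state$L + dZ
      state$x[thin_ids] <- state$x[thin_ids] + dZ
      state <- thermal_diffuse(state)
      pm <- perm_fn(t - dt + dt * k / K)
      state <- step_states(state, pm, dt / K)
    }
    state$balanced <- FALSE
    state <- balance(state)
    state$time <- t
    pm <- perm_fn(t)
    force[i] <- net_axial_force(state)
    strain[i] <- eps
    perm[i] <- pm
    fs[i] <- spacing
    n_bound[i] <- sum(state$head_state > 0L)
    n_strong[i] <- sum(state$head_state == 2L)
  }
  list(state = state,
       trace = tibble::tibble(time = times, strain = strain, force = force,
                              permissiveness = perm, face_spacing = fs,
                              n_bound = n_bound, n_strong = n_strong))
}

#' Simulate a work loop
#'
#' Drives the half sarcomere through `warmup_cycles + n_cycles` sinusoidal
#' strain cycles with phase-locked periodic activation and the protocol's
#' lattice-spacing trajectory. Each timestep performs the model loop:
#' thermal forcing of unbound heads, stochastic state transitions, and force
#' balancing; the M-line force is converted to stress and net work computed
#' for each recorded cycle.
#'
#' @param state a `half_sarcomere` from [build_half_sarcomere()].
#' @param protocol a [workloop_protocol()].
#' @param activation an [activation_params()].
#' @param scaling a [scaling_params()].
#' @param seed integer seed; every source of randomness in the trial derives
#'   from it.
#' @return a `workloop_result`: list with the per-timestep `trace` tibble
#'   (time, strain, stress, permissiveness, face spacing, bound-head counts),
#'   `per_cycle_work` (J/kg, length `n_cycles`), `work_mean`, `work_sd`, and
#'   the run configuration.
#' @export
run_workloop <- function(state, protocol = workloop_protocol(),
                         activation = activation_params(),
                         scaling = scaling_params(), seed = 1L) {
  stopifnot(inherits(state, "half_sarcomere"), inherits(protocol, "workloop_protocol"))
  set.seed(seed)
  dt <- protocol$dt
  spc <- round(protocol$period / dt)
  n_steps <- (protocol$warmup_cycles + protocol$n_cycles) * spc + 1L
  times <- (seq_len(n_steps) - 1L) * dt
  phased <- phased_activation(protocol$phi, protocol$period, activation)
  lat <- state$lattice
  d10_ref <- face_spacing_to_d10(protocol$base_face_spacing, lat$lattice_class, lat$r_sum)

  out <- run_engine(state, times, dt,
                    strain_fn = function(t) strain_waveform(t, protocol),
                    spacing_fn = function(t, eps) lattice_trajectory(t, eps, protocol, lat),
                    perm_fn = function(t) periodic_permissiveness(t, phased))
  trace <- out$trace
  trace$stress <- force_to_stress(trace$force / state$geometry$n_thick, d10_ref)

  works <- vapply(seq_len(protocol$n_cycles), function(cc) {
    rows <- protocol$warmup_cycles * spc + (cc - 1L) * spc + seq_len(spc + 1L)
    net_work_per_cycle(trace$stress[rows], trace$strain[rows],
                       scaling$muscle_density)
  }, numeric(1))

  structure(list(trace = trace, per_cycle_work = works,
                 work_mean = mean(works), work_sd = stats::sd(works),
                 protocol = protocol, activation = activation,
                 scaling = scaling, seed = seed,
                 n_heads = state$n_heads, final_state = out$state),
            class = "workloop_result")
}

#' @export
print.workloop_result <- function(x, ...) {
  cat(sprintf("<workloop_result> phi = %.2f, LS0 = %.2f nm (%s), f = %g Hz\n",
              x$protocol$phi, x$protocol$base_face_spacing,
              x$protocol$lattice_mode, x$protocol$frequency))
  cat(sprintf("  net work over %d cycles: %.3f +/- %.3f J/kg (mean +/- s.d.)\n",
              length(x$per_cycle_work), x$work_mean, x$work_sd))
  invisible(x)
}

#' Simulate an isometric contraction
#'
#' Holds the half sarcomere at zero strain and constant lattice spacing and
#' applies a permissiveness time course: a single twitch pulse, a sustained
#' tetanus, or any function of time.
#'
#' @param state a `half_sarcomere`.
#' @param activation an [activation_params()] (single pulse) or a
#'   `function(t)` returning permissiveness.
#' @param duration total simulated time, ms.
#' @param dt timestep, ms.
#' @param scaling a [scaling_params()].
#' @param seed integer seed.
#' @return an `isometric_result` with the force trace (pN and mN/mm^2),
#'   bound-head counts, and the titin passive preload in `passive_force`.
#' @export
run_isometric <- function(state, activation = activation_params(),
                          duration = 200, dt = 1, scaling = scaling_params(),
                          seed = 1L) {
  stopifnot(inherits(state, "half_sarcomere"))
  set.seed(seed)
  times <- seq(0, duration, by = dt)
  perm_fn <- if (is.function(activation)) activation else
    function(t) permissiveness(t, activation)
  ls0 <- state$lattice$face_spacing
  out <- run_engine(state, times, dt,
                    strain_fn = function(t) 0,
                    spacing_fn = function(t, eps) ls0,
                    perm_fn = perm_fn)
  trace <- out$trace
  d10_ref <- state$lattice$d10
  trace$stress <- force_to_stress(trace$force / state$geometry$n_thick, d10_ref)
  passive <- state$geometry$n_thick * titin_force(0, state$titin)
  structure(list(trace = trace, passive_force = passive, seed = seed,
                 final_state = out$state), class = "isometric_result")
}

#' Mean force borne per bound crossbridge over a plateau window
#'
#' Divides the mean net active force (M-line force minus the titin passive
#' preload) by the mean number of bound heads over the selected window of an
#' isometric run.
#'
#' @param result an `isometric_result`.
#' @param window time window `c(from, to)` in ms; default the second half of
#'   the trace.
#' @return force per crossbridge, pN.
#' @export
force_per_crossbridge <- function(result, window = NULL) {
  stopifnot(inherits(result, "isometric_result"))
  tr <- result$trace
  if (is.null(window)) window <- c(max(tr$time) / 2, max(tr$time))
  sel <- tr$time >= window[1L] & tr$time <= window[2L]
  mean(tr$force[sel] - result$passive_force) / mean(tr$n_bound[sel])
}

#' Rate functions over a grid of axial offsets
#'
#' Evaluates all six transition rates for a head whose binding site sits at
#' axial offset `dx` from the crown, at the given face spacing and without
#' thermal forcing (the binding rate uses the rest tip position). Reproduces
#' the familiar rate-vs-offset curves of spatially explicit crossbridge
#' models.
#'
#' @param dx axial site-minus-crown offsets, nm (vectorized).
#' @param face_spacing radial face spacing, nm.
#' @param springs a [spring_params()].
#' @param rates a [rate_params()].
#' @return tibble with `dx` and the rates `r12`, `r21`, `r23`, `r32`, `r31`.
#' @export
rate_curves <- function(dx = seq(0, 25, by = 0.1), face_spacing = 15,
                        springs = spring_params(), rates = rate_params()) {
  tip0 <- rest_tip(springs)
  d <- sqrt((dx - tip0[1])^2 + (face_spacing - tip0[2])^2)
  r12 <- rate_r12(d, rates)
  bg <- bound_geometry(dx, face_spacing)
  U1 <- free_energy(bg$r, bg$theta, springs, 1L)
  U2 <- free_energy(bg$r, bg$theta, springs, 2L)
  r21 <- rate_r21(r12, 0, U1)
  r23 <- rate_r23(U1, U2, rates)
  tibble::tibble(dx = dx, r12 = r12, r21 = r21, r23 = r23,
                 r32 = rate_r32(r23, U1, U2), r31 = rate_r31(U2, rates))
}
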