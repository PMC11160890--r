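#' Parameter sweeps over work-loop conditions
#'
#' Each sweep runs one independent work-loop trial per condition (reseeded
#' deterministically from `seed`) and returns a tidy tibble, one row per
#' condition, with the per-cycle mean and standard deviation of net work.
#'
#' @param phis phases of activation to simulate.
#' @param protocol a [workloop_protocol()] template.
#' @param state a `half_sarcomere` template (rebuilt fresh per condition).
#' @param activation an [activation_params()].
#' @param scaling a [scaling_params()].
#' @param seed base integer seed; condition `i` uses `seed + i - 1`.
#' @return a tibble with one row per condition.
#' @name sweeps
NULL

sweep_one <- function(state, protocol, activation, scaling, seed) {
  res <- run_workloop(state, protocol, activation, scaling, seed = seed)
  tibble::tibble(work_mean = res$work_mean, work_sd = res$work_sd,
                 work_se = res$work_sd / sqrt(length(res$per_cycle_work)),
                 n_cycles = length(res$per_cycle_work))
}

#' @rdname sweeps
#' @export
phase_sweep <- function(phis, protocol = workloop_protocol(),
                        state = build_half_sarcomere(),
                        activation = activation_params(),
                        scaling = scaling_params(), seed = 1L) {
  purrr::map2_dfr(phis, seq_along(phis), function(phi, i) {
    pr <- protocol
    pr$phi <- phi
    dplyr::bind_cols(tibble::tibble(phi = phi),
                     sweep_one(state, pr, activation, scaling, seed + i - 1L))
  })
}

#' @rdname sweeps
#' @param spacings base face spacings to simulate, nm.
#' @export
lattice_sweep <- function(spacings, protocol = workloop_protocol(),
                          state = build_half_sarcomere(),
                          activation = activation_params(),
                          scaling = scaling_params(), seed = 1L) {
  purrr::map2_dfr(spacings, seq_along(spacings), function(ls, i) {
    pr <- protocol
    pr$base_face_spacing <- ls
    st <- set_lattice_spacing(state, ls)
    dplyr::bind_cols(tibble::tibble(face_spacing = ls),
                     sweep_one(st, pr, activation, scaling, seed + i - 1L))
  })
}

#' @rdname sweeps
#' @param factors multipliers applied to each myosin spring stiffness
#'   (e.g. `c(0.5, 1.5)` for -50% and +50%).
#' @param spacings base face spacings for the grid, nm.
#' @details `stiffness_sweep` simulates the (phi, face spacing) grid at the
#'   default stiffness and with the linear (`k_r`) and torsional (`k_theta`)
#'   spring stiffness scaled by each factor separately; `dwork` expresses
#'   each modified cell relative to the default-stiffness cell.
#' @export
stiffness_sweep <- function(protocol = workloop_protocol(),
                            factors = c(0.5, 1.5),
                            phis = c(0, 0.5),
                            spacings = c(14, 15, 16),
                            state = build_half_sarcomere(),
                            activation = activation_params(),
                            scaling = scaling_params(), seed = 1L) {
  conds <- tidyr::expand_grid(
    component = c("none", "k_r", "k_theta"),
    factor = factors, phi = phis, face_spacing = spacings)
  conds <- dplyr::distinct(
    dplyr::mutate(conds, factor = ifelse(component == "none", 1, factor)))
  out <- purrr::pmap_dfr(
    c(conds, list(i = seq_len(nrow(conds)))),
    function(component, factor, phi, face_spacing, i) {
      sp <- state$springs
      if (component == "k_r") sp$k_r <- sp$k_r * factor
      if (component == "k_theta") sp$k_theta <- sp$k_theta * factor
      st <- build_half_sarcomere(state$geometry, state$filaments,
                                 lattice_state(face_spacing,
                                               state$lattice$lattice_class,
                                               state$lattice$r_sum),
                                 springs = sp, rates = state$rates,
                                 titin = state$titin, solver = state$solver)
      pr <- protocol
      pr$phi <- phi
      pr$base_face_spacing <- face_spacing
      dplyr::bind_cols(
        tibble::tibble(component = component, factor = factor, phi = phi,
                       face_spacing = face_spacing),
        sweep_one(st, pr, activation, scaling, seed + i - 1L))
    })
  ref <- dplyr::select(dplyr::filter(out, component == "none"),
                       phi, face_spacing, ref_work = work_mean)
  dplyr::mutate(dplyr::left_join(out, ref, by = c("phi", "face_spacing")),
                dwork = work_mean - ref_work)
}

#' @rdname sweeps
#' @param b_values titin exponential stiffnesses to simulate, 1/um.
#' @export
titin_sweep <- function(b_values = 4:10, protocol = workloop_protocol(),
                        phis = c(0, 0.5),
                        state = build_half_sarcomere(),
                        activation = activation_params(),
                        scaling = scaling_params(), seed = 1L) {
  conds <- tidyr::expand_grid(b = b_values, phi = phis)
  purrr::pmap_dfr(c(conds, list(i = seq_len(nrow(conds)))),
    function(b, phi, i) {
      st <- build_half_sarcomere(state$geometry, state$filaments,
                                 state$lattice, springs = state$springs,
                                 rates = state$rates,
                                 titin = titin_params(state$titin$a, b),
                                 solver = state$solver)
      pr <- protocol
      pr$phi <- phi
      dplyr::bind_cols(tibble::tibble(b = b, phi = phi),
                       sweep_one(st, pr, activation, scaling, seed + i - 1L))
    })
}
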