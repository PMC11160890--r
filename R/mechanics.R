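# Axial derivative of the bound-head elastic energy with respect to the
# site-minus-crown axial offset dx, at prescribed radial spacing ls.
# E(dx) = 1/2 k_r (rho - r_eq)^2 + 1/2 k_theta (phi - th_eq)^2 with
# rho = sqrt(dx^2 + ls^2), phi = atan2(ls, dx). Vectorized.
xb_dEdx <- function(dx, ls, springs, post) {
  r_eq <- ifelse(post, springs$r_r_post, springs$r_r_pre)
  th_eq <- ifelse(post, springs$theta_post, springs$theta_pre)
  rho <- sqrt(dx^2 + ls^2)
  phi <- atan2(ls, dx)
  springs$k_r * (rho - r_eq) * (dx / rho) +
    springs$k_theta * (phi - th_eq) * (-ls / rho^2)
}

# second derivative of the same energy (for the Newton solver)
xb_d2Edx2 <- function(dx, ls, springs, post) {
  r_eq <- ifelse(post, springs$r_r_post, springs$r_r_pre)
  th_eq <- ifelse(post, springs$theta_post, springs$theta_pre)
  rho <- sqrt(dx^2 + ls^2)
  phi <- atan2(ls, dx)
  springs$k_r * ((dx / rho)^2 + (rho - r_eq) * ls^2 / rho^3) +
    springs$k_theta * ((ls / rho^2)^2 + (phi - th_eq) * 2 * ls * dx / rho^4)
}

# radial derivative (reported by crossbridge_force; no radial DOF exists)
xb_dEdls <- function(dx, ls, springs, post) {
  r_eq <- ifelse(post, springs$r_r_post, springs$r_r_pre)
  th_eq <- ifelse(post, springs$theta_post, springs$theta_pre)
  rho <- sqrt(dx^2 + ls^2)
  phi <- atan2(ls, dx)
  springs$k_r * (rho - r_eq) * (ls / rho) +
    springs$k_theta * (phi - th_eq) * (dx / rho^2)
}

#' Axial and radial force of a bound crossbridge
#'
#' Restoring force of the two-spring head at its current configuration,
#' relative to the equilibria of its kinetic state (pre-stroke for weak,
#' post-stroke for strong). The axial component is the force exerted on the
#' binding site (negative = pulling the thin filament toward the M-line,
#' i.e. contractile). The radial component is computed but, because the
#' lattice spacing is prescribed, it is never fed back into the geometry.
#'
#' @param state a `half_sarcomere`.
#' @param head index of a bound head.
#' @return named numeric `c(axial = , radial = )`, pN.
#' @export
crossbridge_force <- function(state, head) {
  stopifnot(inherits(state, "half_sarcomere"))
  if (state$head_state[head] == 0L)
    rlang::abort("head is unbound; crossbridge force is undefined",
                 class = "myolattice_state_error")
  ls <- state$lattice$face_spacing
  dx <- state$x[state$site_node[state$head_site[head]]] -
    state$x[state$head_node[head]]
  post <- state$head_state[head] == 2L
  c(axial = -xb_dEdx(dx, ls, state$springs, post),
    radial = -xb_dEdls(dx, ls, state$springs, post))
}

#' Titin passive force
#'
#' `F = a * exp(b * delta_L)` with `delta_L` the change of half-sarcomere
#' length from rest, in micrometres. Applied axially from the Z-disk-side end
#' of each thick filament to the Z-disk; note the `a` preload at
#' `delta_L = 0`.
#'
#' @param delta_L length change, um.
#' @param params a [titin_params()].
#' @return force in pN (tension, pulling the thick filament toward the Z-disk).
#' @export
titin_force <- function(delta_L, params = titin_params()) {
  params$a * exp(params$b * delta_L)
}

# titin extension (um) seen by each thick filament tip at current state
titin_delta_L <- function(state) {
  nc <- state$geometry$crowns_per_thick
  tips <- state$x[state$idx_crown[, nc]]
  ((state$L - tips) - (state$L0 - state$x0[state$idx_crown[, nc]])) / 1000
}

#' Net axial force on every free node
#'
#' For each thick and thin filament node: the sum of the adjacent
#' filament-segment spring forces, the forces from crossbridges attached at
#' that node, and (at the Z-disk-side thick filament tips) the titin force.
#'
#' @param state a `half_sarcomere`.
#' @return numeric vector of per-node axial forces, pN, in the internal free
#'   node order (thick crowns filament-major, then thin sites ascending x).
#' @export
assemble_node_forces <- function(state) {
  stopifnot(inherits(state, "half_sarcomere"))
  g <- state$geometry
  f <- state$filaments
  x <- state$x
  forces <- numeric(state$n_free)

  for (ft in seq_len(g$n_thick)) {
    ids <- state$idx_crown[ft, ]
    xs <- c(0, x[ids]) # prepend pinned M-line node
    tension <- f$k_thick * (diff(xs) - g$crown_spacing) # per segment
    # node j feels +tension of segment above (toward Z) and -tension below
    tens_above <- c(tension[-1L], 0)
    forces[ids] <- tens_above - tension
  }
  # titin at thick tips
  forces[state$idx_crown[, g$crowns_per_thick]] <-
    forces[state$idx_crown[, g$crowns_per_thick]] +
    titin_force(titin_delta_L(state), state$titin)

  for (gt in seq_len(g$n_thin)) {
    ids <- state$idx_site[gt, ]
    xs <- c(x[ids], state$L) # append pinned Z-disk node (via tail spring)
    kseg <- c(rep(f$k_thin, state$m_sites - 1L), state$k_tail)
    rest <- c(rep(g$site_spacing, state$m_sites - 1L), state$tail_rest)
    tension <- kseg * (diff(xs) - rest)
    tens_below <- c(0, tension[-state$m_sites])
    forces[ids] <- tension - tens_below
  }

  bound <- which(state$head_state > 0L)
  if (length(bound)) {
    ls <- state$lattice$face_spacing
    cn <- state$head_node[bound]
    sn <- state$site_node[state$head_site[bound]]
    dEdx <- xb_dEdx(x[sn] - x[cn], ls, state$springs, state$head_state[bound] == 2L)
    # force on site = -dE/dx, equal and opposite on the crown
    forces[sn] <- forces[sn] - dEdx
    # crowns can carry several bound heads; accumulate
    agg <- rowsum(dEdx, cn)
    ids <- as.integer(rownames(agg))
    forces[ids] <- forces[ids] + agg[, 1L]
  }
  forces
}

#' Relax the lattice to mechanical equilibrium
#'
#' Iteratively adjusts every free node's axial position until the net force
#' on each node is below the solver tolerance, with the M-line and Z-disk
#' boundaries held fixed. Newton iterations on the full node system: the
#' constant filament-spring stiffness matrix is precomputed at build time and
#' the crossbridge and titin contributions are added each iteration.
#'
#' @param state a `half_sarcomere`.
#' @param solver optional [solver_config()] override.
#' @return the balanced state; `state$residual` holds the final max |force|.
#' @export
balance <- function(state, solver = NULL) {
  stopifnot(inherits(state, "half_sarcomere"))
  sv <- solver %||% state$solver
  nc <- state$geometry$crowns_per_thick
  tip_ids <- state$idx_crown[, nc]

  forces <- assemble_node_forces(state)
  res <- max(abs(forces))
  it <- 0L
  while (res > sv$tolerance) {
    if (it >= sv$max_iterations)
      rlang::abort(sprintf("force balance did not converge: residual %.3g pN after %d iterations",
                           res, it),
                   class = "myolattice_solver_error")
    J <- state$J0
    # titin stiffness at the thick tips
    dtit <- state$titin$a * state$titin$b * exp(state$titin$b * titin_delta_L(state)) / 1000
    J[cbind(tip_ids, tip_ids)] <- J[cbind(tip_ids, tip_ids)] - dtit
    bound <- which(state$head_state > 0L)
    if (length(bound)) {
      ls <- state$lattice$face_spacing
      cn <- state$head_node[bound]
      sn <- state$site_node[state$head_site[bound]]
      k2 <- xb_d2Edx2(state$x[sn] - state$x[cn], ls, state$springs,
                      state$head_state[bound] == 2L)
      for (b in seq_along(bound)) {
        i <- cn[b]; j <- sn[b]; k <- k2[b]
        J[i, i] <- J[i, i] - k
        J[j, j] <- J[j, j] - k
        J[i, j] <- J[i, j] + k
        J[j, i] <- J[j, i] + k
      }
    }
    step <- tryCatch(solve(J, -forces), error = function(e)
      rlang::abort("force balance failed: singular stiffness matrix",
                   class = "myolattice_solver_error"))
    # cap the step to keep the crossbridge linearization honest
    cap <- 5
    mx <- max(abs(step))
    if (mx > cap) step <- step * (cap / mx)
    state$x <- state$x + sv$relaxation * step
    forces <- assemble_node_forces(state)
    res <- max(abs(forces))
    it <- it + 1L
  }
  # refresh bound-head configurations for the moved nodes
  bound <- which(state$head_state > 0L)
  if (length(bound)) {
    dx <- state$x[state$site_node[state$head_site[bound]]] -
      state$x[state$head_node[bound]]
    bg <- bound_geometry(dx, state$lattice$face_spacing)
    state$head_r[bound] <- bg$r
    state$head_theta[bound] <- bg$theta
  }
  state$balanced <- TRUE
  state$residual <- res
  state
}

#' Net axial force at the M-line
#'
#' Sum over the thick filaments of the axial force transmitted at the node
#' nearest the M-line (the tension in the first thick filament segment).
#' Positive force pulls the M-line toward the Z-disk: contractile. The state
#' must be balanced.
#'
#' @param state a balanced `half_sarcomere`.
#' @return force in pN.
#' @export
net_axial_force <- function(state) {
  stopifnot(inherits(state, "half_sarcomere"))
  if (!isTRUE(state$balanced))
    rlang::abort("state is not balanced; call balance() first",
                 class = "myolattice_contract_error")
  sum(state$filaments$k_thick *
        (state$x[state$idx_crown[, 1L]] - state$geometry$crown_spacing))
}
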