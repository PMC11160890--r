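#' Elastic energy of the two-spring myosin head
#'
#' `E = 1/2 k_r (r - r_eq)^2 + 1/2 k_theta (theta - theta_eq)^2`, with the
#' equilibria chosen by the power-stroke state: the weakly bound state uses
#' the pre-stroke equilibria, the strongly bound state the post-stroke ones.
#'
#' @param r arm length(s), nm.
#' @param theta base angle(s), radians.
#' @param springs a [spring_params()].
#' @param stroke_state `"pre"` or `"post"`.
#' @return energy in pN nm (vectorized over `r`, `theta`).
#' @export
head_energy <- function(r, theta, springs = spring_params(),
                        stroke_state = c("pre", "post")) {
  stroke_state <- match.arg(stroke_state)
  if (stroke_state == "pre") {
    0.5 * springs$k_r * (r - springs$r_r_pre)^2 +
      0.5 * springs$k_theta * (theta - springs$theta_pre)^2
  } else {
    0.5 * springs$k_r * (r - springs$r_r_post)^2 +
      0.5 * springs$k_theta * (theta - springs$theta_post)^2
  }
}

#' Free energy of a myosin head in a given kinetic state
#'
#' State 0 (unbound) is the constant reference 0. State 1 (weakly bound) is
#' `alpha1 + E_pre/kT` and state 2 (strongly bound) `alpha2 + E_post/kT`,
#' where the elastic energies come from [head_energy()] at the head's current
#' configuration and the baselines `alpha1`, `alpha2` are the (calibration)
#' chemical free-energy drops of binding and of the power stroke.
#'
#' @inheritParams head_energy
#' @param state_index 0, 1 or 2.
#' @return free energy in kT units.
#' @export
free_energy <- function(r, theta, springs = spring_params(), state_index) {
  stopifnot(all(state_index %in% 0:2))
  if (length(state_index) == 1L) {
    switch(as.character(state_index),
      "0" = rep(0, length(r)),
      "1" = springs$alpha1 + head_energy(r, theta, springs, "pre") / springs$kT,
      "2" = springs$alpha2 + head_energy(r, theta, springs, "post") / springs$kT)
  } else {
    e1 <- springs$alpha1 + head_energy(r, theta, springs, "pre") / springs$kT
    e2 <- springs$alpha2 + head_energy(r, theta, springs, "post") / springs$kT
    ifelse(state_index == 0L, 0, ifelse(state_index == 1L, e1, e2))
  }
}

#' Thermal forcing of unbound heads
#'
#' Each spring of every unbound head draws a displacement from its Boltzmann
#' distribution: Gaussian about the pre-stroke rest value with variance
#' `kT / k` for that spring. Bound heads are untouched (their configuration
#' is fixed by the binding-site geometry).
#'
#' @param state a `half_sarcomere`.
#' @param kT optional override of the thermal energy, pN nm (0 collapses the
#'   heads onto their rest configuration).
#' @export
thermal_diffuse <- function(state, kT = NULL) {
  stopifnot(inherits(state, "half_sarcomere"))
  sp <- state$springs
  if (is.null(kT)) kT <- sp$kT
  idx <- which(state$head_state == 0L)
  n <- length(idx)
  if (n) {
    state$head_r[idx] <- sp$r_r_pre + sqrt(kT / sp$k_r) * stats::rnorm(n)
    state$head_theta[idx] <- sp$theta_pre + sqrt(kT / sp$k_theta) * stats::rnorm(n)
  }
  state
}

#' Crossbridge state-transition rate functions
#'
#' The three-state scheme (0 unbound, 1 weakly bound, 2 strongly bound) uses:
#' \itemize{
#'   \item `r12 = tau * exp(-(d/d_scale)^2) + baseline` with `d` the
#'     head-tip-to-site distance in nm. The small distance-independent
#'     `baseline` floor is what keeps the reverse rate `r21` finite and
#'     rapidly rising at extreme strains ("infinite well").
#'   \item `r21 = r12 * exp(U1 - U0)` (detailed balance against binding).
#'   \item `r23 = A * (1 + tanh(C + D*(U1 - U2)))` (power stroke).
#'   \item `r32 = r23 * exp(U2 - U1)` (reverse stroke, detailed balance).
#'   \item `r31 = max(0, G*U2 + H)`; `r13 = 0`.
#' }
#' Free energies `U` are in kT units. All rates are per millisecond and
#' vectorized.
#'
#' @param d head-to-site distance, nm.
#' @param params a [rate_params()].
#' @param r12,r23 forward rates used by the detailed-balance reverse rates.
#' @param U0,U1,U2 state free energies, kT units.
#' @name transition-rates
NULL

#' @rdname transition-rates
#' @export
rate_r12 <- function(d, params = rate_params()) {
  params$tau * exp(-(d / params$d_scale)^2) + params$baseline
}

#' @rdname transition-rates
#' @export
rate_r21 <- function(r12, U0, U1) r12 * exp(U1 - U0)

#' @rdname transition-rates
#' @export
rate_r23 <- function(U1, U2, params = rate_params()) {
  params$A * (1 + tanh(params$C + params$D * (U1 - U2)))
}

#' @rdname transition-rates
#' @export
rate_r32 <- function(r23, U1, U2) r23 * exp(U2 - U1)

#' @rdname transition-rates
#' @export
rate_r31 <- function(U2, params = rate_params()) {
  pmax(0, params$G * U2 + params$H)
}

#' Convert a rate to a per-step transition probability
#'
#' `p = 1 - exp(-rate * dt)`, in `[0, 1)`.
#'
#' @param rate transition rate, 1/ms (non-negative).
#' @param dt timestep, ms (positive).
#' @export
transition_probability <- function(rate, dt) {
  stopifnot(all(rate >= 0), dt > 0)
  1 - exp(-rate * dt)
}

# rest tip position (axial, radial) of the pre-stroke head
rest_tip <- function(springs) {
  c(springs$r_r_pre * cos(springs$theta_pre),
    springs$r_r_pre * sin(springs$theta_pre))
}

# bound-head configuration implied by the site geometry: arm from the crown
# node to the site at axial offset dx and radial offset = face spacing
bound_geometry <- function(dx, ls) {
  rho <- sqrt(dx^2 + ls^2)
  list(r = rho, theta = atan2(ls, dx))
}

# candidate binding sites for the given unbound heads: nearest site (by axial
# tip distance) on the faced thin filament, within the axial search window
# and currently unoccupied. Returns site index (NA if none) and the squared
# tip-to-site distance.
candidate_sites <- function(state, idx, tip_x, tip_y) {
  m <- state$m_sites
  ls <- state$lattice$face_spacing
  cand <- rep(NA_integer_, length(idx))
  d2 <- rep(NA_real_, length(idx))
  for (g in seq_len(state$geometry$n_thin)) {
    hg <- which(state$head_thin[idx] == g)
    if (!length(hg)) next
    srange <- (g - 1L) * m + seq_len(m)
    sx <- state$x[state$site_node[srange]]
    tx <- tip_x[hg]
    fi <- findInterval(tx, sx)
    lo <- pmax(fi, 1L)
    hi <- pmin(fi + 1L, m)
    pick <- ifelse(abs(sx[lo] - tx) <= abs(sx[hi] - tx), lo, hi)
    ax <- abs(sx[pick] - tx)
    ok <- ax <= state$binding_window & state$site_occ[srange[pick]] == 0L
    cand[hg[ok]] <- srange[pick[ok]]
    d2[hg[ok]] <- (sx[pick[ok]] - tx[ok])^2 + (ls - tip_y[hg[ok]])^2
  }
  list(site = cand, d2 = d2)
}

#' Advance the kinetic state of every myosin head by one timestep
#'
#' Computes, per head, the outgoing transition rates at the current spatial
#' configuration and performs at most one stochastic transition. Binding
#' (0 to 1) uses the thermally displaced tip-to-site distance and its
#' probability is multiplied by the actin permissiveness; competing outgoing
#' transitions from bound states share a single uniform draw, partitioned
#' proportionally to their rates so the total per-step probability is
#' `1 - exp(-sum(r) dt)`. One head per site: when several heads attempt the
#' same site in a step, a randomly ordered first-come rule applies and later
#' heads are refused.
#'
#' @param state a `half_sarcomere` (heads diffused via [thermal_diffuse()]).
#' @param permissiveness actin permissiveness in `[0, 1]`.
#' @param dt timestep, ms.
#' @export
step_states <- function(state, permissiveness, dt) {
  stopifnot(inherits(state, "half_sarcomere"),
            permissiveness >= 0, permissiveness <= 1, dt > 0)
  sp <- state$springs
  rp <- state$rates
  ls <- state$lattice$face_spacing
  tip0 <- rest_tip(sp)

  unbound <- which(state$head_state == 0L)
  weak <- which(state$head_state == 1L)
  strong <- which(state$head_state == 2L)

  # --- binding attempts -------------------------------------------------
  if (length(unbound) && permissiveness > 0) {
    tip_x <- state$x[state$head_node[unbound]] +
      state$head_r[unbound] * cos(state$head_theta[unbound])
    tip_y <- state$head_r[unbound] * sin(state$head_theta[unbound])
    cs <- candidate_sites(state, unbound, tip_x, tip_y)
    has <- which(!is.na(cs$site))
    if (length(has)) {
      r12 <- rp$tau * exp(-cs$d2[has] / rp$d_scale^2) + rp$baseline
      p <- permissiveness * (1 - exp(-r12 * dt))
      want <- has[stats::runif(length(has)) < p]
      if (length(want)) {
        ord <- sample.int(length(want)) # randomized first-come priority
        want <- want[ord]
        keep <- !duplicated(cs$site[want])
        winners <- want[keep]
        hid <- unbound[winners]
        sid <- cs$site[winners]
        state$head_state[hid] <- 1L
        state$head_site[hid] <- sid
        state$site_occ[sid] <- hid
        dx <- state$x[state$site_node[sid]] - state$x[state$head_node[hid]]
        bg <- bound_geometry(dx, ls)
        state$head_r[hid] <- bg$r
        state$head_theta[hid] <- bg$theta
      }
    }
  }

  # --- weakly bound: unbind or power stroke ----------------------------
  if (length(weak)) {
    dx <- state$x[state$site_node[state$head_site[weak]]] -
      state$x[state$head_node[weak]]
    bg <- bound_geometry(dx, ls)
    U1 <- sp$alpha1 + head_energy(bg$r, bg$theta, sp, "pre") / sp$kT
    U2 <- sp$alpha2 + head_energy(bg$r, bg$theta, sp, "post") / sp$kT
    d2rest <- (dx - tip0[1])^2 + (ls - tip0[2])^2
    r12b <- rp$tau * exp(-d2rest / rp$d_scale^2) + rp$baseline
    r21 <- r12b * exp(U1)            # U0 = 0 reference
    r23 <- rate_r23(U1, U2, rp)
    Rtot <- r21 + r23
    u <- stats::runif(length(weak))
    ptot <- 1 - exp(-Rtot * dt)
    go <- u < ptot
    to_unbind <- weak[go & u < ptot * r21 / Rtot]
    to_strong <- setdiff(weak[go], to_unbind)
    if (length(to_unbind)) {
      state$site_occ[state$head_site[to_unbind]] <- 0L
      state$head_site[to_unbind] <- NA_integer_
      state$head_state[to_unbind] <- 0L
    }
    if (length(to_strong)) state$head_state[to_strong] <- 2L
  }

  # --- strongly bound: reverse stroke or detach ------------------------
  if (length(strong)) {
    dx <- state$x[state$site_node[state$head_site[strong]]] -
      state$x[state$head_node[strong]]
    bg <- bound_geometry(dx, ls)
    U1 <- sp$alpha1 + head_energy(bg$r, bg$theta, sp, "pre") / sp$kT
    U2 <- sp$alpha2 + head_energy(bg$r, bg$theta, sp, "post") / sp$kT
    r23 <- rate_r23(U1, U2, rp)
    r32 <- rate_r32(r23, U1, U2)
    r31 <- rate_r31(U2, rp)
    Rtot <- r32 + r31
    u <- stats::runif(length(strong))
    ptot <- 1 - exp(-Rtot * dt)
    go <- u < ptot & Rtot > 0
    to_weak <- strong[go & u < ptot * r32 / Rtot]
    to_unbind <- setdiff(strong[go], to_weak)
    if (length(to_weak)) state$head_state[to_weak] <- 1L
    if (length(to_unbind)) {
      state$site_occ[state$head_site[to_unbind]] <- 0L
      state$head_site[to_unbind] <- NA_integer_
      state$head_state[to_unbind] <- 0L
    }
  }

  state$balanced <- FALSE
  state
}

#' Per-head binding probabilities at the current configuration
#'
#' Deterministic companion to [step_states()]: returns, for every head, the
#' probability that it would bind during one timestep at the given
#' permissiveness (0 for bound heads and heads without an eligible site).
#' Useful for testing and for rate diagnostics.
#'
#' @inheritParams step_states
#' @return numeric vector of length `n_heads`.
#' @export
binding_probabilities <- function(state, permissiveness, dt) {
  stopifnot(inherits(state, "half_sarcomere"))
  p <- numeric(state$n_heads)
  unbound <- which(state$head_state == 0L)
  if (!length(unbound)) return(p)
  rp <- state$rates
  tip_x <- state$x[state$head_node[unbound]] +
    state$head_r[unbound] * cos(state$head_theta[unbound])
  tip_y <- state$head_r[unbound] * sin(state$head_theta[unbound])
  cs <- candidate_sites(state, unbound, tip_x, tip_y)
  has <- !is.na(cs$site)
  r12 <- rp$tau * exp(-cs$d2[has] / rp$d_scale^2) + rp$baseline
  p[unbound[has]] <- permissiveness * (1 - exp(-r12 * dt))
  p
}
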