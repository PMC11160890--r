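# small, fast half-sarcomere fixtures used across the unit tests

small_geometry <- function(crowns = 6L, L0 = 420) {
  geometry_config(crowns_per_thick = crowns, rest_half_sarcomere_length = L0)
}

small_state <- function(crowns = 6L, L0 = 420, face_spacing = 15, ...) {
  build_half_sarcomere(config = small_geometry(crowns, L0),
                       lattice = lattice_state(face_spacing), ...)
}

quick_protocol <- function(n_cycles = 2L, warmup_cycles = 0L, ...) {
  workloop_protocol(n_cycles = n_cycles, warmup_cycles = warmup_cycles, ...)
}

# place a head onto a chosen site by force (bypassing kinetics), keeping the
# bookkeeping invariants intact
bind_head <- function(state, head, site, strong = FALSE) {
  stopifnot(state$site_thin[site] == state$head_thin[head],
            state$site_occ[site] == 0L)
  state$head_state[head] <- if (strong) 2L else 1L
  state$head_site[head] <- as.integer(site)
  state$site_occ[site] <- as.integer(head)
  dx <- state$x[state$site_node[site]] - state$x[state$head_node[head]]
  bg <- myolattice:::bound_geometry(dx, state$lattice$face_spacing)
  state$head_r[head] <- bg$r
  state$head_theta[head] <- bg$theta
  state$balanced <- FALSE
  state
}
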