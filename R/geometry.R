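#' Convert d10 lattice spacing to actin-myosin face spacing
#'
#' X-ray diffraction measures the d10 spacing of the hexagonal myofilament
#' crystal. The centre-to-centre actin-myosin distance is proportional to d10
#' with a geometry factor that depends on the filament packing: 2/3 for
#' vertebrate muscle and 1/sqrt(3) for invertebrate flight muscle. The
#' face-to-face (surface) spacing subtracts the combined filament radii.
#'
#' @param d10 d10 lattice plane spacing, nm.
#' @param lattice_class `"vertebrate"` or `"invertebrate_flight"`.
#' @param r_sum combined thick + thin filament radii, nm.
#' @return face spacing in nm.
#' @examples
#' d10_to_face_spacing(47.5, "invertebrate_flight") # ~15 nm
#' d10_to_face_spacing(38, "vertebrate")            # ~12.8 nm
#' @export
d10_to_face_spacing <- function(d10,
                                lattice_class = c("invertebrate_flight", "vertebrate"),
                                r_sum = 12.5) {
  lattice_class <- match.arg(lattice_class)
  if (any(d10 <= 0)) rlang::abort("`d10` must be positive", class = "myolattice_domain_error")
  fs <- lattice_geometry_factor(lattice_class) * d10 - r_sum
  if (any(fs <= 0))
    rlang::abort("resulting face spacing is non-positive", class = "myolattice_domain_error")
  fs
}

#' @rdname d10_to_face_spacing
#' @param face_spacing actin-myosin surface-to-surface spacing, nm.
#' @export
face_spacing_to_d10 <- function(face_spacing,
                                lattice_class = c("invertebrate_flight", "vertebrate"),
                                r_sum = 12.5) {
  lattice_class <- match.arg(lattice_class)
  if (any(face_spacing <= 0))
    rlang::abort("`face_spacing` must be positive", class = "myolattice_domain_error")
  (face_spacing + r_sum) / lattice_geometry_factor(lattice_class)
}

#' @rdname d10_to_face_spacing
#' @export
lattice_geometry_factor <- function(lattice_class = c("invertebrate_flight", "vertebrate")) {
  lattice_class <- match.arg(lattice_class)
  switch(lattice_class, vertebrate = 2 / 3, invertebrate_flight = 1 / sqrt(3))
}

#' Radial lattice state
#'
#' Bundles the prescribed actin-myosin face spacing with its equivalent d10
#' value for the given lattice class. The lattice spacing is prescribed: it is
#' an input to every head-to-site distance computation and has no radial
#' dynamics of its own.
#'
#' @inheritParams d10_to_face_spacing
#' @export
lattice_state <- function(face_spacing = 15,
                          lattice_class = c("invertebrate_flight", "vertebrate"),
                          r_sum = 12.5) {
  lattice_class <- match.arg(lattice_class)
  check_positive(face_spacing, "face_spacing")
  structure(list(
    face_spacing = face_spacing,
    d10 = face_spacing_to_d10(face_spacing, lattice_class, r_sum),
    geometry_factor = lattice_geometry_factor(lattice_class),
    lattice_class = lattice_class,
    r_sum = r_sum
  ), class = "lattice_state")
}

# Transverse (cross-sectional) arrangement: thick filaments on a triangular
# lattice, thin filaments at the two trigonal positions of each unit cell,
# periodic over a 2x2 supercell (4 thick / 8 thin). Returns the thick -> thin
# neighbor map: a matrix [n_thick x 6] where column k holds the thin filament
# faced by heads pointing along azimuth 30 + 60*(k-1) degrees.
build_neighbor_map <- function(n_thick = 4L, n_thin = 8L) {
  if (n_thick != 4L || n_thin != 8L)
    abort_config("n_thick", "only the 4 thick / 8 thin periodic unit is supported")
  a1 <- c(1, 0)
  a2 <- c(0.5, sqrt(3) / 2)
  cells <- expand.grid(i = 0:1, j = 0:1)
  thick <- t(apply(cells, 1, function(z) z[["i"]] * a1 + z[["j"]] * a2))
  thin <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    base <- thick[r, ]
    rbind(base + (a1 + a2) / 3, base + 2 * (a1 + a2) / 3)
  }))
  L1 <- 2 * a1
  L2 <- 2 * a2
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1))
  map <- matrix(NA_integer_, n_thick, 6L)
  for (f in seq_len(n_thick)) {
    for (g in seq_len(n_thin)) {
      img <- sweep(shifts %*% rbind(L1, L2), 2, thin[g, ] - thick[f, ], "+")
      d <- sqrt(rowSums(img^2))
      near <- which(d < 0.65) # trigonal neighbours sit at 1/sqrt(3) ~ 0.577
      for (w in near) {
        ang <- atan2(img[w, 2], img[w, 1]) * 180 / pi
        slot <- (round((ang - 30) / 60) %% 6) + 1L
        map[f, slot] <- g
      }
    }
  }
  stopifnot(!anyNA(map))
  map
}

#' Build the periodic half-sarcomere spring lattice
#'
#' Constructs the full spatial state: 4 thick filaments carrying crowns of 3
#' myosin heads (azimuthally 120 degrees apart, adjacent crowns rotated by 60
#' degrees), 8 thin filaments of binding sites, titin anchors from each thick
#' filament tip to the Z-disk, and the periodic transverse neighbour map under
#' which each thick filament interacts with 6 thin filaments. All heads start
#' unbound and all springs at rest.
#'
#' Axial convention: `x = 0` at the M-line, Z-disk at `x = L`; positive strain
#' lengthens. Thin filament nodes are placed at binding sites every
#' `site_spacing` nm over the span that can ever interact with the thick
#' filament; the remaining crossbridge-free run to the Z-disk is represented
#' by a single exactly equivalent series spring.
#'
#' @param config a [geometry_config()].
#' @param filaments a [filament_params()].
#' @param lattice a [lattice_state()].
#' @param springs a [spring_params()].
#' @param rates a [rate_params()].
#' @param titin a [titin_params()].
#' @param solver a [solver_config()].
#' @param binding_window axial search window for candidate binding sites, nm.
#' @return an object of class `half_sarcomere`.
#' @export
build_half_sarcomere <- function(config = geometry_config(),
                                 filaments = filament_params(),
                                 lattice = lattice_state(),
                                 springs = spring_params(),
                                 rates = rate_params(),
                                 titin = titin_params(),
                                 solver = solver_config(),
                                 binding_window = 16) {
  stopifnot(inherits(config, "geometry_config"), inherits(filaments, "filament_params"),
            inherits(lattice, "lattice_state"))
  nf <- config$n_thick
  ng <- config$n_thin
  nc <- config$crowns_per_thick
  L0 <- config$rest_half_sarcomere_length
  span <- nc * config$crown_spacing

  nbr <- build_neighbor_map(nf, ng)

  # thin filament discretization: total sites sized so the pointed end stays
  # on the M-line side of x = 0 at 10% shortening; explicit sites are those
  # that can ever come within reach of the thick filament (8% strain margin).
  n_total <- max(1L, floor(L0 * 0.95 / config$site_spacing))
  reach <- span + binding_window + 2 * config$site_spacing
  j_min <- max(1L, ceiling((L0 * 0.92 - reach) / config$site_spacing))
  m <- n_total - j_min + 1L # explicit sites per thin filament
  tail_segments <- j_min    # Z-disk anchor to deepest explicit site
  k_tail <- filaments$k_thin / tail_segments

  n_free <- nf * nc + ng * m

  # global free-node indexing: thick crowns first, then thin sites (ascending x)
  idx_crown <- matrix(seq_len(nf * nc), nrow = nf, byrow = TRUE)
  idx_site <- matrix(nf * nc + seq_len(ng * m), nrow = ng, byrow = TRUE)

  x0 <- numeric(n_free)
  for (f in seq_len(nf)) x0[idx_crown[f, ]] <- seq_len(nc) * config$crown_spacing
  # site s = 1..m ordered by ascending x; site s has Z-offset (n_total - s + 1)*ss
  site_offsets <- (n_total - seq_len(m) + 1L) * config$site_spacing
  for (g in seq_len(ng)) x0[idx_site[g, ]] <- L0 - site_offsets

  # heads: one row per head, filament-major then crown then triplet position
  head_thick <- rep(seq_len(nf), each = nc * 3L)
  head_crown <- rep(rep(seq_len(nc), each = 3L), times = nf)
  head_pos <- rep(0:2, times = nf * nc)
  head_slot <- (2L * head_pos + (head_crown - 1L)) %% 6L + 1L
  head_thin <- nbr[cbind(head_thick, head_slot)]
  head_node <- idx_crown[cbind(head_thick, head_crown)]
  n_heads <- length(head_thick)

  site_thin <- rep(seq_len(ng), each = m)
  site_node <- as.integer(t(idx_site))

  # constant part of the force Jacobian: filament segment springs (incl.
  # springs to the pinned M-line and Z-disk boundary nodes)
  J0 <- matrix(0, n_free, n_free)
  add_spring <- function(i, j, k) {
    # i, j global free-node indices; NA means a pinned boundary node
    if (!is.na(i)) J0[i, i] <<- J0[i, i] - k
    if (!is.na(j)) J0[j, j] <<- J0[j, j] - k
    if (!is.na(i) && !is.na(j)) {
      J0[i, j] <<- J0[i, j] + k
      J0[j, i] <<- J0[j, i] + k
    }
  }
  for (f in seq_len(nf)) {
    add_spring(NA, idx_crown[f, 1L], filaments$k_thick) # M-line pin to crown 1
    if (nc > 1L)
      for (j in seq_len(nc - 1L))
        add_spring(idx_crown[f, j], idx_crown[f, j + 1L], filaments$k_thick)
  }
  for (g in seq_len(ng)) {
    if (m > 1L)
      for (s in seq_len(m - 1L))
        add_spring(idx_site[g, s], idx_site[g, s + 1L], filaments$k_thin)
    add_spring(idx_site[g, m], NA, k_tail) # deepest explicit site to Z-disk
  }

  state <- structure(list(
    geometry = config, filaments = filaments, lattice = lattice,
    springs = springs, rates = rates, titin = titin, solver = solver,
    binding_window = binding_window,
    n_free = n_free, n_heads = n_heads, m_sites = m, n_total_sites = n_total,
    tail_segments = tail_segments, k_tail = k_tail,
    tail_rest = tail_segments * config$site_spacing,
    idx_crown = idx_crown, idx_site = idx_site,
    neighbor_map = nbr,
    head_thick = head_thick, head_crown = head_crown, head_pos = head_pos,
    head_thin = head_thin, head_node = head_node,
    site_thin = site_thin, site_node = site_node,
    site_offsets = site_offsets,
    x0 = x0, x = x0, J0 = J0,
    L0 = L0, L = L0, time = 0,
    head_state = integer(n_heads),
    head_r = rep(springs$r_r_pre, n_heads),
    head_theta = rep(springs$theta_pre, n_heads),
    head_site = rep(NA_integer_, n_heads),
    site_occ = integer(ng * m),
    balanced = TRUE, residual = 0
  ), class = "half_sarcomere")
  state
}

#' @export
print.half_sarcomere <- function(x, ...) {
  cat(sprintf(
    "<half_sarcomere> %d thick / %d thin filaments, %d heads (%d crowns/filament)\n",
    x$geometry$n_thick, x$geometry$n_thin, x$n_heads, x$geometry$crowns_per_thick))
  cat(sprintf("  L = %.1f nm (rest %.1f), face spacing %.2f nm (d10 %.2f, %s)\n",
              x$L, x$L0, x$lattice$face_spacing, x$lattice$d10,
              x$lattice$lattice_class))
  cat(sprintf("  bound heads: %d weak, %d strong; t = %.1f ms\n",
              sum(x$head_state == 1L), sum(x$head_state == 2L), x$time))
  invisible(x)
}

#' Impose an axial strain on the half sarcomere
#'
#' Moves the Z-disk boundary to `L0 * (1 + strain)`. The setter is absolute
#' (not cumulative); internal nodes are unchanged until [balance()] is called.
#'
#' @param state a `half_sarcomere`.
#' @param strain dimensionless strain, `|strain| < 0.5`.
#' @export
apply_axial_strain <- function(state, strain) {
  stopifnot(inherits(state, "half_sarcomere"))
  if (abs(strain) >= 0.5)
    rlang::abort("`strain` must satisfy |strain| < 0.5", class = "myolattice_domain_error")
  newL <- state$L0 * (1 + strain)
  if (newL != state$L) {
    state$L <- newL
    state$balanced <- FALSE
  }
  state
}

#' Prescribe the radial lattice spacing
#'
#' Sets the actin-myosin face spacing used by every head-to-site distance and
#' bound-head energy computation. There are no radial degrees of freedom: the
#' spacing is an input, never an output, of the model.
#'
#' @param state a `half_sarcomere`.
#' @param face_spacing face spacing in nm, positive.
#' @export
set_lattice_spacing <- function(state, face_spacing) {
  stopifnot(inherits(state, "half_sarcomere"))
  if (!is.numeric(face_spacing) || length(face_spacing) != 1L || !is.finite(face_spacing) ||
      face_spacing <= 0)
    rlang::abort("`face_spacing` must be a single positive number",
                 class = "myolattice_domain_error")
  if (face_spacing != state$lattice$face_spacing) {
    state$lattice$face_spacing <- face_spacing
    state$lattice$d10 <- face_spacing_to_d10(face_spacing, state$lattice$lattice_class,
                                             state$lattice$r_sum)
    state$balanced <- FALSE
  }
  state
}

#' Axial-plus-radial distance from a myosin head to a binding site
#'
#' Combines the axial offset between the head tip and the site with the
#' prescribed radial face spacing; the site must lie on the thin filament the
#' head faces. This is the backbone-to-backbone geometric distance (always at
#' least the face spacing); the stochastic binding step uses the thermally
#' displaced tip position instead (see [step_states()]).
#'
#' @param state a `half_sarcomere`.
#' @param head head index (1..n_heads).
#' @param site site index (1..n_sites, global across thin filaments).
#' @export
head_to_site_distance <- function(state, head, site) {
  stopifnot(inherits(state, "half_sarcomere"))
  if (head < 1L || head > state$n_heads) rlang::abort("invalid head index")
  if (site < 1L || site > length(state$site_node)) rlang::abort("invalid site index")
  if (state$site_thin[site] != state$head_thin[head])
    rlang::abort("site is not on the thin filament faced by this head",
                 class = "myolattice_lookup_error")
  tip_x <- state$x[state$head_node[head]] +
    state$head_r[head] * cos(state$head_theta[head])
  sqrt((state$x[state$site_node[site]] - tip_x)^2 + state$lattice$face_spacing^2)
}
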