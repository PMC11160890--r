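test_that("titin force is the exponential of length change with its preload", {
  tp <- titin_params()
  expect_equal(titin_force(0, tp), 260)
  expect_equal(titin_force(0.1, tp), 260 * exp(0.4))
  dl <- seq(-0.2, 0.3, by = 0.05)
  expect_true(all(diff(titin_force(dl, tp)) > 0))
})

test_that("crossbridge force vanishes at rest, matches the analytic gradient, and is continuous", {
  hs <- small_state()
  sp <- hs$springs
  g <- hs$head_thin[1L]
  s <- which(hs$site_thin == g)[2L]
  hs <- bind_head(hs, 1L, s)
  expect_error(crossbridge_force(hs, 2L), class = "myolattice_state_error")
  # place the site exactly at the pre-stroke rest tip: zero force
  tip0 <- myolattice:::rest_tip(sp)
  hs15 <- set_lattice_spacing(hs, tip0[2])
  hs15$x[hs15$site_node[s]] <- hs15$x[hs15$head_node[1L]] + tip0[1]
  expect_equal(unname(crossbridge_force(hs15, 1L)), c(0, 0), tolerance = 1e-12)
  # finite-difference check of the axial force at an arbitrary configuration
  ls <- hs$lattice$face_spacing
  dx <- hs$x[hs$site_node[s]] - hs$x[hs$head_node[1L]]
  h <- 1e-6
  E <- function(z) {
    bg <- myolattice:::bound_geometry(z, ls)
    head_energy(bg$r, bg$theta, sp, "pre")
  }
  fd <- -(E(dx + h) - E(dx - h)) / (2 * h)
  expect_equal(unname(crossbridge_force(hs, 1L)["axial"]), fd, tolerance = 1e-6)
  # continuity in the offset
  f1 <- myolattice:::xb_dEdx(seq(-5, 20, by = 0.01), ls, sp, FALSE)
  expect_lt(max(abs(diff(f1))), 1.5) # no jumps at 0.01 nm resolution
})

test_that("node force assembly obeys Newton's third law and conservation", {
  hs <- small_state()
  f0 <- assemble_node_forces(hs)
  nc <- hs$geometry$crowns_per_thick
  tips <- hs$idx_crown[, nc]
  interior <- setdiff(seq_len(hs$n_free), tips)
  # all springs at rest: only the titin preload at the thick tips
  expect_equal(f0[interior], numeric(length(interior)))
  expect_equal(f0[tips], rep(260, 4))
  # stretch one thick segment by 1 nm: +/- k_thick on its two nodes
  hs2 <- hs
  j <- hs$idx_crown[1L, 2L]
  hs2$x[j] <- hs2$x[j] + 1
  f2 <- assemble_node_forces(hs2) - f0
  expect_equal(f2[hs$idx_crown[1L, 1L]], 2020)
  expect_equal(f2[j], -2 * 2020)       # stretched below, compressed above
  expect_equal(f2[hs$idx_crown[1L, 3L]], 2020)
  expect_equal(sum(f2), 0)             # internal forces cancel in the sum
})

test_that("the balance solver reaches tolerance and solves series springs exactly", {
  # two equal springs in series: displaced end puts the middle node at delta/2
  cfg <- geometry_config(crowns_per_thick = 2L, rest_half_sarcomere_length = 400)
  hs <- build_half_sarcomere(config = cfg)
  hs$titin$a <- 1e-12 # switch the titin preload off for the closed forms
  # perturb an interior node: equal springs in series put it back midway
  # between its (resting) neighbours after balance
  j <- hs$idx_crown[1L, 1L]
  hs$x[j] <- hs$x0[j] + 3
  hs$balanced <- FALSE
  hs <- balance(hs)
  expect_equal(hs$x[j], hs$x0[j], tolerance = 1e-6) # midpoint of 0 and crown 2
  expect_equal(hs$x, hs$x0, tolerance = 1e-6)
  expect_lte(max(abs(assemble_node_forces(hs))), hs$solver$tolerance)
  # an already-balanced state is returned unchanged
  hs2 <- balance(hs)
  expect_equal(hs2$x, hs$x)
  # thin filament under Z displacement: uniform translation (free tip)
  hs3 <- balance(apply_axial_strain(hs, 0.05))
  shift <- hs3$x[hs3$site_node] - hs$x[hs$site_node]
  expect_equal(shift, rep(0.05 * hs$L0, length(shift)), tolerance = 1e-6)
})

test_that("rigid-limit force equals the brute-force crossbridge + titin sum", {
  hs <- small_state(filaments = filament_params(k_thick = 1e6, k_thin = 1e6))
  set.seed(8)
  # bind a handful of heads at their nearest sites
  bound <- 0L
  for (h in seq_len(hs$n_heads)) {
    if (bound >= 6L) break
    g <- hs$head_thin[h]
    sites <- which(hs$site_thin == g & hs$site_occ == 0L)
    dx <- hs$x[hs$site_node[sites]] - hs$x[hs$head_node[h]]
    s <- sites[which.min(abs(dx - 13.5))]
    if (abs(hs$x[hs$site_node[s]] - hs$x[hs$head_node[h]] - 13.5) > 12) next
    hs <- bind_head(hs, h, s, strong = (bound %% 2L == 0L))
    bound <- bound + 1L
  }
  expect_gt(bound, 3L)
  hs <- balance(hs)
  # brute force: on rigid filaments each bound head transmits its axial force
  # to the M-line, plus each filament's titin tension
  ls <- hs$lattice$face_spacing
  heads <- which(hs$head_state > 0L)
  dx <- hs$x[hs$site_node[hs$head_site[heads]]] - hs$x[hs$head_node[heads]]
  fxb <- -myolattice:::xb_dEdx(dx, ls, hs$springs, hs$head_state[heads] == 2L)
  # force on the site is -dE/dx; the reaction on the thick filament is +dE/dx,
  # transmitted to the M-line with opposite sign of the site force
  expected <- -sum(fxb) + sum(titin_force(myolattice:::titin_delta_L(hs), hs$titin))
  expect_equal(net_axial_force(hs), expected, tolerance = 1e-4)
})

test_that("net axial force demands a balanced state and reduces to titin when passive", {
  hs <- small_state()
  hs <- apply_axial_strain(hs, 0.02)
  expect_error(net_axial_force(hs), class = "myolattice_contract_error")
  hs <- balance(hs)
  # fully passive: net force equals the summed titin tension only
  expect_equal(net_axial_force(hs),
               sum(titin_force(myolattice:::titin_delta_L(hs), hs$titin)),
               tolerance = 1e-6)
})

test_that("a passive closed strain cycle does no net work", {
  hs <- small_state()
  pr <- quick_protocol(n_cycles = 2L)
  res <- run_workloop(hs, pr, seed = 1,
                      activation = activation_params(peak_level = 1e-9))
  expect_true(all(res$trace$n_bound == 0L))
  expect_lt(max(abs(res$per_cycle_work)), 1e-3) # elastic network: ~0 J/kg
})
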