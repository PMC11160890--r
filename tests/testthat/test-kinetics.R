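sp <- spring_params()
rp <- rate_params()

test_that("head elastic energy is zero at rest and quadratic in each spring", {
  expect_equal(head_energy(sp$r_r_pre, sp$theta_pre, sp, "pre"), 0)
  expect_equal(head_energy(sp$r_r_post, sp$theta_post, sp, "post"), 0)
  # 1 nm arm displacement: E = 1/2 * 16 * 1^2 = 8 pN nm
  expect_equal(head_energy(sp$r_r_pre + 1, sp$theta_pre, sp, "pre"), 8)
  # 0.1 rad torsional displacement: E = 1/2 * 4000 * 0.01 = 20 pN nm
  expect_equal(head_energy(sp$r_r_pre, sp$theta_pre + 0.1, sp, "pre"), 20)
})

test_that("free energies use state baselines plus spring energy in kT", {
  expect_equal(free_energy(sp$r_r_pre, sp$theta_pre, sp, 0L), 0)
  expect_equal(free_energy(sp$r_r_pre, sp$theta_pre, sp, 1L), sp$alpha1)
  # a 4.11 pN nm spring energy contributes exactly 1 kT
  r_off <- sp$r_r_pre + sqrt(2 * 4.11 / sp$k_r)
  expect_equal(free_energy(r_off, sp$theta_pre, sp, 1L), sp$alpha1 + 1)
  # monotone in |r - r_eq| at fixed theta
  rr <- sp$r_r_pre + seq(0, 3, by = 0.25)
  expect_true(all(diff(free_energy(rr, rep(sp$theta_pre, length(rr)), sp, 1L)) > 0))
})

test_that("rate function examples evaluate analytically", {
  expect_equal(rate_r12(0, rp), 72.005)
  expect_equal(rate_r12(1, rp), 72 * exp(-1) + 0.005)
  expect_equal(rate_r12(50, rp), 0.005) # distant floor
  expect_equal(rate_r21(26.49, 0, 0), 26.49) # equal free energies
  expect_equal(rate_r21(26.49, 0, -2), 26.49 * exp(-2))
  # the binding floor makes the reverse rate rise without bound with strain
  expect_equal(rate_r21(0.005, 0, 10), 0.005 * exp(10))
  expect_gt(rate_r21(0.005, 0, 10), 110)
  expect_equal(rate_r23(-30 + 0, 0, rp), rp$A) # tanh argument zero
  expect_equal(rate_r23(1e4, 0, rp), 2 * rp$A)
  expect_equal(rate_r23(-1e4, 0, rp), 0)
  expect_equal(rate_r32(0.8, 0, -3), 0.8 * exp(-3))
  expect_equal(rate_r31(0, rp), rp$H)
  expect_equal(rate_r31(1, rp), 0.62)
  expect_equal(rate_r31(-100, rp), 0) # clipped at zero
  expect_true(all(diff(rate_r31(seq(0, 10, 0.5), rp)) > 0))
})

test_that("detailed balance holds to machine precision at random configurations", {
  set.seed(5)
  for (i in 1:50) {
    U0 <- 0
    U1 <- runif(1, -5, 40)
    U2 <- runif(1, -5, 40)
    r12 <- rate_r12(runif(1, 0, 4), rp)
    r21 <- rate_r21(r12, U0, U1)
    expect_equal(r21 / r12, exp(U1 - U0))
    r23 <- rate_r23(U1, U2, rp)
    r32 <- rate_r32(r23, U1, U2)
    if (r23 > 0) expect_equal(r32 / r23, exp(U2 - U1))
  }
})

test_that("transition probability maps rates into [0, 1) monotonically", {
  expect_equal(transition_probability(0, 1), 0)
  expect_equal(transition_probability(1, 1), 1 - exp(-1))
  p <- transition_probability(seq(0, 8, by = 0.25), 1)
  expect_true(all(diff(p) > 0) && all(p >= 0 & p < 1))
  expect_true(transition_probability(2, 2) > transition_probability(2, 1))
})

test_that("thermal forcing samples each spring's Boltzmann distribution", {
  hs <- small_state()
  set.seed(99)
  n <- 1e5
  draws_r <- numeric(0)
  draws_th <- numeric(0)
  while (length(draws_r) < n) {
    hs2 <- thermal_diffuse(hs)
    draws_r <- c(draws_r, hs2$head_r)
    draws_th <- c(draws_th, hs2$head_theta)
  }
  draws_r <- draws_r[seq_len(n)]
  draws_th <- draws_th[seq_len(n)]
  v_target <- sp$kT / sp$k_r # 4.11/16 = 0.257 nm^2
  se_var <- v_target * sqrt(2 / (n - 1))
  expect_lt(abs(var(draws_r) - v_target), 3 * se_var)
  expect_lt(abs(mean(draws_r) - sp$r_r_pre), 3 * sqrt(v_target / n))
  vth <- sp$kT / sp$k_theta
  expect_lt(abs(var(draws_th) - vth), 3 * vth * sqrt(2 / (n - 1)))
  # Kolmogorov-Smirnov against the analytic Gaussian
  ks <- suppressWarnings(
    ks.test(draws_r, "pnorm", mean = sp$r_r_pre, sd = sqrt(v_target)))
  expect_gt(ks$p.value, 0.01)
  # zero-temperature limit collapses onto the rest configuration
  hs0 <- thermal_diffuse(hs, kT = 0)
  expect_equal(hs0$head_r, rep(sp$r_r_pre, hs$n_heads))
  expect_equal(hs0$head_theta, rep(sp$theta_pre, hs$n_heads))
})

test_that("permissiveness scales binding probability exactly and gates binding", {
  hs <- small_state()
  set.seed(3)
  hs <- thermal_diffuse(hs)
  p1 <- binding_probabilities(hs, 1, 1)
  p05 <- binding_probabilities(hs, 0.5, 1)
  expect_true(any(p1 > 0))
  expect_equal(p05, 0.5 * p1) # each binding event 50% less likely
  expect_equal(binding_probabilities(hs, 0, 1), numeric(hs$n_heads))
  # permissiveness 0: no head ever leaves the unbound state
  set.seed(4)
  for (i in 1:20) {
    hs <- thermal_diffuse(hs)
    hs <- step_states(hs, 0, 1)
  }
  expect_true(all(hs$head_state == 0L))
})

test_that("stochastic stepping respects site exclusivity and at most one transition", {
  hs <- small_state()
  set.seed(11)
  ever_bound <- 0L
  for (i in 1:40) {
    before <- hs$head_state
    hs <- thermal_diffuse(hs)
    hs <- step_states(hs, 1, 1)
    ever_bound <- ever_bound + sum(hs$head_state > 0L)
    # no head jumps two states in one step (0<->1<->2 only)
    expect_true(all(abs(hs$head_state - before) <= 1L))
    bound <- which(hs$head_state > 0L)
    # every bound head's site is occupied by exactly that head
    expect_true(all(hs$site_occ[hs$head_site[bound]] == bound))
    expect_equal(sum(hs$site_occ > 0L), length(bound))
    hs <- balance(hs)
  }
  expect_gt(ever_bound, 0L) # binding does occur at full activation
})

test_that("rate curves expose the infinite-well reverse rate across offsets", {
  rc <- rate_curves(dx = seq(4, 24, by = 0.5), face_spacing = 15)
  expect_true(all(rc$r12 >= 0.005))
  # r21 rises steeply away from the binding locus in both directions
  locus <- rc$dx[which.min(rc$r21)]
  expect_gt(rc$r21[rc$dx == 4] / min(rc$r21), 1e6)
  expect_gt(rc$r21[rc$dx == 24] / min(rc$r21), 1e6)
  expect_true(locus > 11 && locus < 16)
})
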