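test_that("the strain waveform starts at maximum length and averages zero", {
  pr <- workloop_protocol()
  expect_equal(strain_waveform(0, pr), 0.05)
  expect_equal(strain_waveform(20, pr), -0.05) # T/2 at 25 Hz
  tt <- seq(0, 40 - 0.01, by = 0.01)
  expect_equal(mean(strain_waveform(tt, pr)), 0, tolerance = 1e-12)
})

test_that("lattice trajectories follow the Poisson-ratio law exactly", {
  lat <- lattice_state(15)
  iso <- workloop_protocol(lattice_mode = "isolattice")
  expect_equal(lattice_trajectory(c(0, 7, 23), c(0.05, 0, -0.03), iso, lat),
               rep(15, 3))
  # nu = 0 keeps the lattice constant even in poisson mode
  p0 <- workloop_protocol(lattice_mode = "poisson", nu = 0)
  expect_equal(lattice_trajectory(0, 0.05, p0, lat), 15)
  # nu = 0.5 at +5% strain: delta-d10 = d10 (1 - 1.05^-0.5) ~ 1.145 nm down
  p5 <- workloop_protocol(lattice_mode = "poisson", nu = 0.5,
                          base_face_spacing = d10_to_face_spacing(47.5))
  ls <- lattice_trajectory(0, 0.05, p5, lat)
  d10 <- face_spacing_to_d10(ls)
  expect_equal(47.5 - d10, 47.5 * (1 - 1.05^-0.5), tolerance = 1e-9)
  # isovolume invariant: d10^2 * L constant over the whole cycle
  eps <- strain_waveform(seq(0, 40, 0.5), p5)
  d10_t <- face_spacing_to_d10(lattice_trajectory(seq(0, 40, 0.5), eps, p5, lat))
  vol <- d10_t^2 * (1 + eps)
  expect_equal(vol, rep(vol[1], length(vol)), tolerance = 1e-12)
})

test_that("the synthetic in vivo trace is periodic, scaled and phase-advanced", {
  tr <- make_invivo_trace(amplitude_factor = 0.75, phase_lead = 0.1)
  expect_equal(nrow(tr), 200)
  expect_lt(max(abs(tr$delta_d10)), 2) # nanometre-scale excursions
  # amplitude 0 collapses onto the isolattice (flat) trajectory
  tr0 <- make_invivo_trace(amplitude_factor = 0)
  expect_equal(tr0$delta_d10, numeric(200))
  # zero lead at unit amplitude matches the isovolumetric fundamental
  tr1 <- make_invivo_trace(amplitude_factor = 1, phase_lead = 0)
  lat <- lattice_state(15)
  w <- 2 * pi * tr1$time / 40
  d10_0 <- face_spacing_to_d10(15)
  iso <- d10_0 * ((1 + 0.05 * cos(w))^(-0.5) - 1)
  c1 <- 2 * mean(iso * cos(w)); s1 <- 2 * mean(iso * sin(w))
  expect_equal(tr1$delta_d10, c1 * cos(w) + s1 * sin(w), tolerance = 1e-9)
  # the phase-advanced peak comes earlier in the cycle
  expect_lt(tr$time[which.max(tr$delta_d10)], tr1$time[which.max(tr1$delta_d10)])
  # prescribed mode demands a trace
  expect_error(workloop_protocol(lattice_mode = "prescribed"),
               class = "myolattice_config_error")
})

test_that("net work of analytic loops: rectangle value, zero for constant stress, orientation", {
  n <- 101
  eps <- c(seq(0.05, -0.05, length.out = 51), seq(-0.05, 0.05, length.out = 51)[-1])
  # rectangle: 10 mN/mm^2 higher during shortening, 0.1 strain width
  sigma <- c(rep(10, 51), rep(0, 50))
  expect_equal(net_work_per_cycle(sigma, eps, 1060), 10 * 1e3 * 0.1 / 1060,
               tolerance = 0.02) # trapezoid smears the two stress jumps

  expect_equal(net_work_per_cycle(rep(7, n), eps, 1060), 0)
  expect_equal(net_work_per_cycle(rev(sigma), rev(eps), 1060),
               -net_work_per_cycle(sigma, eps, 1060))
  expect_error(net_work_per_cycle(sigma, eps + seq(0, 1, length.out = n)),
               class = "myolattice_contract_error")
})

test_that("work loop runs are reproducible, shaped as promised, and balanced throughout", {
  hs <- small_state()
  pr <- workloop_protocol(n_cycles = 3L, warmup_cycles = 1L)
  r1 <- run_workloop(hs, pr, seed = 5)
  r2 <- run_workloop(hs, pr, seed = 5)
  expect_identical(r1$trace, r2$trace) # same seed, identical trajectories
  expect_identical(r1$per_cycle_work, r2$per_cycle_work)
  r3 <- run_workloop(hs, pr, seed = 6)
  expect_false(identical(r1$trace$force, r3$trace$force))
  expect_length(r1$per_cycle_work, 3L) # n_cycles recorded after warmup
  expect_equal(nrow(r1$trace), (3 + 1) * 40 + 1)
  expect_equal(r1$work_mean, mean(r1$per_cycle_work))
  expect_equal(r1$work_sd, sd(r1$per_cycle_work))
  expect_named(r1$trace, c("time", "strain", "force", "permissiveness",
                           "face_spacing", "n_bound", "n_strong", "stress"))
})

test_that("sweeps return one tidy row per condition and honour their templates", {
  hs <- small_state(crowns = 4L)
  pr <- quick_protocol()
  ps <- phase_sweep(c(0, 0.5), pr, state = hs, seed = 3)
  expect_equal(ps$phi, c(0, 0.5))
  expect_true(all(c("work_mean", "work_sd", "work_se", "n_cycles") %in% names(ps)))
  ls <- lattice_sweep(14.5, pr, state = hs, seed = 3)
  expect_equal(nrow(ls), 1L)
  # a single-spacing sweep equals a plain work-loop run at that spacing
  pr1 <- pr; pr1$base_face_spacing <- 14.5
  direct <- run_workloop(set_lattice_spacing(hs, 14.5), pr1, seed = 3)
  expect_equal(ls$work_mean, direct$work_mean)
  ts <- titin_sweep(c(4, 10), pr, phis = 0, state = hs, seed = 3)
  expect_equal(nrow(ts), 2L)
  # b = 4 is the default condition
  expect_equal(ts$work_mean[ts$b == 4],
               run_workloop(hs, pr, seed = 3)$work_mean)
  # passive force at maximum stretch strictly increases with b
  f_at <- function(b) {
    st <- small_state(crowns = 4L, titin = titin_params(b = b))
    net_axial_force(balance(apply_axial_strain(st, 0.05)))
  }
  expect_true(f_at(10) > f_at(7) && f_at(7) > f_at(4))
})

test_that("stiffness sweep reports changes relative to the default grid", {
  hs <- small_state(crowns = 4L)
  ss <- stiffness_sweep(quick_protocol(), factors = 1.5, phis = 0,
                        spacings = 15, state = hs, seed = 9)
  expect_setequal(ss$component, c("none", "k_r", "k_theta"))
  expect_equal(ss$dwork[ss$component == "none"], 0)
  expect_equal(nrow(ss), 3L)
})

test_that("isometric runs expose per-crossbridge force over the plateau", {
  hs <- small_state()
  res <- run_isometric(hs, function(t) 1, duration = 60, seed = 12)
  expect_equal(res$passive_force, 4 * 260)
  fpx <- force_per_crossbridge(res, window = c(30, 60))
  expect_true(is.finite(fpx))
  sel <- res$trace$time >= 30
  expect_equal(fpx, mean(res$trace$force[sel] - 4 * 260) /
                 mean(res$trace$n_bound[sel]))
})
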