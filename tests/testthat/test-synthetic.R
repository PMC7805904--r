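test_that("marker synthesis is exact, seeded and statistically calibrated", {
  m <- planar_model()
  mset <- default_marker_set(m)
  q <- standing_pose(m)
  # zero noise: markers sit exactly on the virtual markers
  md0 <- synthesize_markers(m, 0, rbind(q), mset)
  cache <- gaitbench:::fk_cache(m, q)
  k <- 5
  at <- m$seg_attach[[mset$segment[k]]]
  p <- gaitbench:::x_point_inv(at$X, as.numeric(mset[k, c("x", "y", "z")]))
  expect_equal(as.numeric(md0$markers[1, k, ]),
               gaitbench:::body_point_world(cache, m$seg_body[[mset$segment[k]]], p),
               tolerance = 1e-12)
  # identical seeds give bitwise-identical noise, and the global RNG state
  # is untouched
  set.seed(1234); before <- .Random.seed
  md1 <- synthesize_markers(m, 0, rbind(q), mset, noise_sigma = 0.005,
                            seed = 7)
  expect_identical(.Random.seed, before)
  md2 <- synthesize_markers(m, 0, rbind(q), mset, noise_sigma = 0.005,
                            seed = 7)
  expect_identical(md1$markers, md2$markers)
  # empirical noise SD within 10% of sigma
  times <- seq(0, 1, length.out = 50)
  Q <- matrix(rep(q, 50), 50, byrow = TRUE)
  mdn <- synthesize_markers(m, times, Q, mset, noise_sigma = 0.005,
                            seed = 11)
  noise <- mdn$markers - rep(md0$markers[1, , ], each = 50)
  expect_lt(abs(sd(noise) - 0.005) / 0.005, 0.1)
})

test_that("zero-torque flight follows a ballistic COM parabola", {
  m <- planar_model()
  q0 <- standing_pose(m); q0[2] <- q0[2] + 0.4
  v0 <- c(0.6, 0.8, numeric(m$n_dof - 2)); v0[5] <- 1.0
  tr <- integrate_phase(m, c(q0, v0), function(t) numeric(m$n_act),
                        contact_set(m, character(0)), 0, 0.3, h = 0.005)
  c0 <- com_state(m, q0, v0)
  for (i in c(21, 61)) {
    t <- tr$times[i]
    ci <- com_state(m, tr$q[i, ], tr$v[i, ])
    expect_equal(ci$r_com[1], c0$r_com[1] + c0$rdot_com[1] * t,
                 tolerance = 1e-8)
    expect_equal(ci$r_com[3],
                 c0$r_com[3] + c0$rdot_com[3] * t - 9.81 / 2 * t^2,
                 tolerance = 1e-8)
  }
})

test_that("double-support equilibrium torques hold the walker stationary", {
  m <- planar_model()
  q <- standing_pose(m)
  cs <- contact_set(m, m$contacts$id, q)
  id <- gaitbench:::inverse_dynamics_contact(m, q, numeric(m$n_dof),
                                             numeric(m$n_dof), cs)
  tr <- integrate_phase(m, c(q, numeric(m$n_dof)),
                        function(t) id$tau, cs, 0, 0.4, h = 0.01)
  nt <- length(tr$times)
  expect_lt(max(abs(tr$q[nt, ] - q)), 1e-8)
  expect_lt(max(abs(tr$v[nt, ])), 1e-7)
})

test_that("the stride fixture satisfies the hybrid dynamics it declares", {
  fx <- stride_fixture()
  expect_false(fx$sim$fallen)
  expect_equal(nrow(fx$schedule), 8)
  # re-integrating phase 1 from its start with the recorded controls
  # reproduces the stored ground truth
  sched <- fx$schedule
  cs <- contact_set(fx$model, attr(sched, "contacts")[[1]], fx$sim$q[1, ])
  uf <- gaitbench:::pwl_control(fx$controls[[1]]$times,
                                fx$controls[[1]]$values)
  tr <- integrate_phase(fx$model, c(fx$sim$q[1, ], fx$sim$v[1, ]),
                        function(t) uf(t), cs, sched$t_start[1],
                        sched$t_end[1], h = 0.005, project = FALSE)
  idx <- which(fx$sim$phase == 1)
  expect_lt(max(abs(tr$q - fx$sim$q[idx, ])), 1e-9)
  # total vertical load stays compressive at all interior samples (the
  # instant before a touch-down can transiently dip as the rollout meets
  # the incoming impact)
  tot <- rowSums(fx$sim$forces)
  boundary <- fx$sim$times %in% fx$sim$times[duplicated(fx$sim$times)]
  expect_gt(min(tot[!boundary]), 0)
  expect_gt(mean(tot), 0.8 * fx$model$total_mass * 9.81)
})

test_that("detected events on the fixture match the schedule", {
  fx <- stride_fixture()
  # the generator's contact forces are identically zero off-contact, so a
  # small threshold recovers the scheduled activations exactly
  ev <- detect_gait_events(list(times = fx$sim$times,
                                forces = abs(fx$sim$forces)),
                           body_weight = fx$model$total_mass * 9.81,
                           force_frac = 1e-9)
  # threshold semantics also report the contact present at the very first
  # sample as a rising edge (and contact at the last sample as a falling
  # edge), so match each true event to the nearest detection
  h <- 0.011
  near <- function(det, truth) min(abs(det - truth))
  expect_lt(near(ev$left$heel_strike, fx$events$left$heel_strike), h)
  expect_lt(near(ev$left$toe_strike, fx$events$left$toe_strike), h)
  expect_lt(near(ev$right$heel_strike, fx$events$right$heel_strike), h)
  expect_lt(near(ev$right$toe_off, fx$events$right$toe_off), h)
  # the stride grammar of the detected events rebuilds the schedule
  sched <- build_phase_schedule(fx$events)
  expect_equal(nrow(sched), 8)
})

test_that("markers from the fixture round-trip through IK", {
  fx <- stride_fixture()
  ref <- stride_reference()
  uid <- !duplicated(fx$sim$times)
  expect_lt(max(abs(ref$q - fx$sim$q[uid, ])), 1e-6)
  expect_lt(ref$stats[["mean"]], 1e-9)
})

test_that("touch-down events can be located by integration", {
  # drop the planar rod and find the tip touch-down by bisection
  m <- rod_model()
  q0 <- c(0, 1.4, 0.2); v0 <- c(0, 0, 0)
  tip_height <- function(t, q, v) {
    cache <- gaitbench:::fk_cache(m, q)
    gaitbench:::body_point_world(cache, m$seg_body[["rod"]],
                                 c(0, 0, -1.2))[3]
  }
  out <- integrate_until_event(m, c(q0, v0), function(t) numeric(0),
                               contact_set(m, character(0)), tip_height,
                               0, 1.0, h = 0.01)
  expect_false(is.na(out$event_time))
  # oracle: free fall of the COM by the initial tip clearance
  h0 <- tip_height(0, q0, v0)
  expect_equal(out$event_time, sqrt(2 * h0 / 9.81), tolerance = 1e-5)
})
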