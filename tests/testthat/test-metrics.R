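test_that("angular eigenfrequency follows the pendulum formula", {
  expect_equal(angular_eigenfrequency(9.81), 1.0)
  expect_equal(angular_eigenfrequency(0.792), sqrt(9.81 / 0.792),
               tolerance = 1e-12)
  l <- 0.85
  expect_equal(angular_eigenfrequency(l / 4), 2 * angular_eigenfrequency(l),
               tolerance = 1e-12)
  expect_error(angular_eigenfrequency(0), "positive")
  expect_error(angular_eigenfrequency(-1), "positive")
})

test_that("instantaneous capture point offsets by velocity over omega0", {
  expect_equal(instantaneous_capture_point(c(0.3, -0.1), c(0, 0), 3.5),
               c(0.3, -0.1))
  expect_equal(instantaneous_capture_point(c(0, 0), c(1.2, 0), 3.5),
               c(1.2 / 3.5, 0), tolerance = 1e-12)
  expect_error(instantaneous_capture_point(c(0, 0), c(1, 0), 0))
})

test_that("normalized orbital energy evaluates its defining expression", {
  # at rest over the CoP
  expect_equal(normalized_orbital_energy(c(0.2, 0), c(0.2, 0), c(0, 0), 3.5),
               0)
  # CoP at the COM-based ICaP cancels exactly
  v <- c(0.4, -0.15); w0 <- 3.3
  expect_equal(normalized_orbital_energy(c(0.1, 0.2), c(0.1, 0.2) + v / w0,
                                         v, w0), 0, tolerance = 1e-12)
  # direct evaluation
  expect_equal(normalized_orbital_energy(c(0.1, 0), c(0, 0), c(0.4, 0), 3.5),
               0.5 * 0.4^2 - 0.5 * 0.1^2 * 3.5^2, tolerance = 1e-12)
  expect_equal(0.5 * 0.4^2 - 0.5 * 0.1^2 * 3.5^2, 0.01875)
})

test_that("normalization order does not matter", {
  set.seed(31)
  l <- 0.792
  r_com <- runif(2); r_cop <- runif(2); v <- runif(2); w0 <- 3.4
  e_pre <- normalized_orbital_energy(r_com / l, r_cop / l, v / l, w0)
  e_post <- normalized_orbital_energy(r_com, r_cop, v, w0) / l^2
  expect_equal(e_pre, e_post, tolerance = 1e-12)
})

test_that("stride averaging reproduces the published per-subject values", {
  # left/right heel-strike values of the three reported subjects
  expect_equal(round(stride_average(0.0664, 0.0660), 4), 0.0662)
  expect_equal(round(stride_average(0.0783, 0.0435), 4), 0.0609)
  expect_equal(round(stride_average(0.0723, 0.0649), 4), 0.0686)
})

test_that("residual orbital energy handles events robustly", {
  g <- simulate_lipm_gait(lipm_gait_spec(n_steps = 4))
  ev <- g$events
  # an event outside the trajectory span is skipped with a warning
  ev$left$heel_strike <- c(ev$left$heel_strike, 99)
  expect_warning(res <- residual_orbital_energy(g$traj, ev),
                 "outside")
  expect_equal(nrow(res), length(g$events$left$heel_strike) +
                 length(g$events$right$heel_strike))
  # both omega modes agree for a constant-height trajectory with l = z0
  r1 <- residual_orbital_energy(g$traj, g$events,
                                omega_mode = "instantaneous")
  r2 <- residual_orbital_energy(g$traj, g$events, omega_mode = "leg_length")
  expect_equal(r1$E_res, r2$E_res, tolerance = 1e-12)
})

test_that("angular momentum decomposition is additive and vanishes at rest", {
  m <- reduced_model()
  set.seed(32)
  q1 <- standing_pose(m) + rnorm(m$n_dof, 0, 0.15)
  q2 <- standing_pose(m) + rnorm(m$n_dof, 0, 0.15)
  v1 <- rnorm(m$n_dof, 0, 0.5); v2 <- rnorm(m$n_dof, 0, 0.5)
  dec <- decompose_angular_momentum(m, c(0, 0.1), rbind(q1, q2),
                                    rbind(v1, v2))
  full <- dec$L[, , "upper"] + dec$L[, , "lower"]
  expect_equal(full, dec$L[, , "full"], tolerance = 1e-12)
  expect_gt(max(abs(dec$L)), 0)
  # static pose: identically zero
  dec0 <- decompose_angular_momentum(m, 0, rbind(q1),
                                     rbind(numeric(m$n_dof)))
  expect_equal(max(abs(dec0$L)), 0)
  # a split that is not a partition is rejected
  expect_error(decompose_angular_momentum(m, 0, rbind(q1), rbind(v1),
                                          split = list(upper = "head",
                                                       lower = "pelvis")),
               "partition")
})

test_that("mirrored states carry mirrored angular momenta", {
  # left-right mirror of the reduced model: negate lateral translation,
  # yaw and roll, swap sides, flip ab/adduction and axial rotation
  m <- reduced_model()
  mirror_state <- function(x) {
    out <- x
    nm <- m$qnames
    for (j in seq_along(nm)) {
      n2 <- nm[j]
      if (grepl("_l_", n2)) n2 <- sub("_l_", "_r_", n2)
      else if (grepl("_r_", n2)) n2 <- sub("_r_", "_l_", n2)
      jj <- match(n2, nm)
      sgn <- if (grepl("_Rx$|_Rz$|_Py$", nm[j])) -1 else 1
      out[jj] <- sgn * x[j]
    }
    out
  }
  set.seed(33)
  q <- standing_pose(m) + rnorm(m$n_dof, 0, 0.1)
  v <- rnorm(m$n_dof, 0, 0.4)
  qm <- mirror_state(q); vm <- mirror_state(v)
  L <- angular_momentum(m, q, v)
  Lm <- angular_momentum(m, qm, vm)
  # frontal (x) and horizontal (z) components flip, sagittal (y) persists
  expect_equal(Lm[1], -L[1], tolerance = 1e-9)
  expect_equal(Lm[2], L[2], tolerance = 1e-9)
  expect_equal(Lm[3], -L[3], tolerance = 1e-9)
})

test_that("gait event detection follows threshold semantics", {
  # monotone force ramp crossing the threshold once -> exactly one event
  tt <- seq(0, 1, by = 0.01)
  F <- matrix(0, length(tt), 6,
              dimnames = list(NULL, c("left_heel", "left_hallux",
                                      "left_meta5", "right_heel",
                                      "right_hallux", "right_meta5")))
  F[, "left_heel"] <- 800 * tt
  ev <- detect_gait_events(list(times = tt, forces = F), body_weight = 700)
  expect_length(ev$left$heel_strike, 1)
  expect_length(ev$right$heel_strike, 0)
  # constant flight -> empty events with a warning
  expect_warning(ev0 <- detect_gait_events(list(times = tt, forces = F * 0),
                                           body_weight = 700), "no contact")
  expect_length(ev0$left$heel_strike, 0)
})

test_that("foot placement offsets are measured in the landing foot frame", {
  # trivial case: ICaP exactly at the landing heel
  times <- c(0, 1, 2)
  traj <- ground_ref_traj(times,
                          r_com = cbind(c(0, 0.5, 1), 0, 0.9),
                          rdot_com = cbind(rep(0.7, 3), 0, 0),
                          r_cop = cbind(c(0, 0.5, 1), 0),
                          leg_length = 0.9)
  w0 <- angular_eigenfrequency(0.9)
  icap_at_1 <- c(0.5 + 0.7 / w0, 0)
  events <- gait_events(left = list(heel_strike = 1, toe_strike = numeric(0),
                                    toe_off = numeric(0)),
                        right = list(heel_strike = numeric(0),
                                     toe_strike = numeric(0),
                                     toe_off = numeric(0)), validate = FALSE)
  fp <- list(list(side = "left", time = 1, heel = icap_at_1,
                  hallux = icap_at_1 + c(0.25, -0.02),
                  meta5 = icap_at_1 + c(0.19, 0.04)))
  out <- foot_placement_summary(traj, events, fp)
  expect_equal(out$anterior, 0, tolerance = 1e-9)
  expect_equal(out$medial, 0, tolerance = 1e-9)
  # missing footprint: step skipped with a warning
  expect_warning(out2 <- foot_placement_summary(traj, events, list()),
                 "no footprint")
  expect_equal(nrow(out2), 0)
})

test_that("LIPM stepping onto the ICaP lands the foot on it", {
  g <- simulate_lipm_gait(lipm_gait_spec(foot_placement_mode = "on_icap",
                                         n_steps = 3))
  out <- foot_placement_summary(g$traj, g$events, g$footprints)
  cap <- out[nrow(out), ]      # the capturing step
  expect_lt(abs(cap$anterior), 1e-6)
  expect_lt(abs(cap$lateral), 1e-6)
})

test_that("periodic gait has mirror-symmetric lateral ICaP offsets", {
  g <- simulate_lipm_gait(lipm_gait_spec())
  out <- foot_placement_summary(g$traj, g$events, g$footprints)
  lat_l <- out$lateral[out$side == "left"]
  lat_r <- out$lateral[out$side == "right"]
  np <- min(length(lat_l), length(lat_r))
  expect_lt(max(abs(lat_l[seq_len(np)] + lat_r[seq_len(np)])), 1e-9)
  med <- out$medial
  expect_lt(max(abs(med - med[1])), 1e-9)
  ant <- out$anterior
  expect_lt(max(abs(ant - ant[1])), 1e-9)
})
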