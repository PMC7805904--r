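test_that("orbital energy is conserved along every fixed-CoP phase", {
  g <- simulate_lipm_gait(lipm_gait_spec())
  tr <- g$traj
  l <- g$spec$leg_length
  E <- normalized_orbital_energy(tr$r_com[, 1:2] / l, tr$r_cop / l,
                                 tr$rdot_com[, 1:2] / l,
                                 angular_eigenfrequency(tr$com_height))
  brk <- c(0, which(diff(tr$times) == 0), length(tr$times))
  for (i in seq_len(length(brk) - 1)) {
    e <- E[(brk[i] + 1):brk[i + 1]]
    expect_lt(max(abs(e - e[1])) / max(abs(e[1]), 1e-12), 1e-9)
  }
})

test_that("stepping onto the ICaP captures the pendulum", {
  g <- simulate_lipm_gait(lipm_gait_spec(foot_placement_mode = "on_icap",
                                         n_steps = 3))
  n <- length(g$traj$times)
  # COM comes to rest
  expect_lt(sqrt(sum(g$traj$rdot_com[n, ]^2)), 1e-8)
  # orbital energy with the CoP on the COM-based ICaP is zero
  l <- g$spec$leg_length
  i <- which(diff(g$traj$times) == 0)[1] + 1  # first post-capture sample
  Ecap <- normalized_orbital_energy(g$traj$r_com[i, 1:2] / l,
                                    g$traj$r_cop[i, ] / l,
                                    g$traj$rdot_com[i, 1:2] / l, g$omega0)
  expect_lt(abs(Ecap), 1e-9)
})

test_that("periodic symmetric gait has side-symmetric positive E_res", {
  g <- simulate_lipm_gait(lipm_gait_spec())
  res <- residual_orbital_energy(g$traj, g$events)
  s <- attr(res, "summary")
  expect_lt(abs(s[["left"]] - s[["right"]]), 1e-9)
  expect_true(all(res$E_res > 0))
  # closed-form oracle for the periodic solution: with step length S, width
  # W, step time T, E'_res = (w0^2 / 2 l^2) (S^2/4 sinh^-2 - W^2/4 cosh^-2)
  sp <- g$spec
  w0 <- sqrt(9.81 / sp$com_height)
  x <- w0 * sp$step_time / 2
  E_exp <- (w0^2 / (2 * sp$leg_length^2)) *
    ((sp$step_length / 2)^2 / sinh(x)^2 - (sp$step_width / 2)^2 / cosh(x)^2)
  expect_equal(unname(s[["average"]]), E_exp, tolerance = 1e-9)
})

test_that("LIPM generator validates parameters and is deterministic", {
  expect_error(lipm_gait_spec(step_length = 3, com_height = 0.9),
               "too long")
  expect_error(lipm_gait_spec(n_steps = 1))
  g1 <- simulate_lipm_gait(lipm_gait_spec())
  g2 <- simulate_lipm_gait(lipm_gait_spec())
  expect_identical(g1$traj$r_com, g2$traj$r_com)
  expect_identical(g1$events, g2$events)
})
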