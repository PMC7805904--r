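# Unit tests of the reconstruction machinery on a small standing-balance
# problem: the planar walker in double support, disturbed by a smooth hip
# torque wiggle. (The full walking recovery is exercised by the acceptance
# suite.)

toy_problem <- function() {
  cached("toy_problem", function() {
    m <- planar_model()
    # crouched stance: straight knees are a kinematic singularity of the
    # closed double-support chain (rank-deficient contact Jacobian)
    q0 <- standing_pose(m)
    q0[c(4, 7)] <- -0.3   # hips
    q0[c(5, 8)] <- 0.6    # knees
    q0[c(6, 9)] <- -0.3   # ankles
    q0[2] <- q0[2] - 0.06
    ids <- m$contacts$id
    cs <- contact_set(m, ids, q0)
    id0 <- gaitbench:::inverse_dynamics_contact(m, q0, numeric(m$n_dof),
                                                numeric(m$n_dof), cs)
    # a generic wiggle (a symmetric hip-only pattern would fall into the
    # double-support actuation null space and move nothing)
    tau_fun <- function(t)
      id0$tau + c(6 * sin(2 * pi * t), -4 * sin(2 * pi * t),
                  1.5 * cos(2 * pi * t), 3 * cos(2 * pi * t),
                  -5 * sin(2 * pi * t), 1 * sin(2 * pi * t))
    # near-continuum reference so that grid-refinement comparisons probe
    # the solver discretization, not the reference generation
    tr <- integrate_phase(m, c(q0, numeric(m$n_dof)), tau_fun, cs, 0, 0.3,
                          h = 0.0025, project = FALSE)
    sched <- data.frame(phase = 1:2, t_start = c(0, 0.15),
                        t_end = c(0.15, 0.3),
                        label = c("double support", "double support"))
    attr(sched, "contacts") <- list(ids, ids)
    attr(sched, "transitions") <-
      data.frame(time = numeric(0), event = character(0),
                 before_phase = integer(0), after_phase = integer(0))
    class(sched) <- c("phase_schedule", "data.frame")
    list(model = m, schedule = sched,
         reference = list(times = tr$times, q = tr$q),
         truth = tr, tau_fun = tau_fun)
  })
}

toy_solve <- function(gamma_u, node_spacing = 0.03) {
  tp <- toy_problem()
  reconstruct_gait(tp$model, tp$reference, tp$schedule,
                   ocp_config(gamma_u = gamma_u,
                              node_spacing = node_spacing,
                              max_iter = 15L))
}

test_that("exact-fit limit: gamma_u = 0 drives the objective to zero", {
  rec <- cached("toy_rec0", function() toy_solve(0))
  expect_lt(rec$objective[["tracking"]], 1e-6)
  expect_lt(rec$constraint_norm, 1e-6)
})

test_that("regularization path: stronger gamma_u shrinks the control norm", {
  tp <- toy_problem()
  rec1 <- cached("toy_rec_g1", function() toy_solve(1e-3))
  rec2 <- cached("toy_rec_g2", function() toy_solve(2e-3))
  wnorm <- function(rec) {
    W <- 1 / rec$config$u_scale
    mean(rowSums((rec$u * W)^2))
  }
  expect_lte(wnorm(rec2), wnorm(rec1) * (1 + 1e-6))
  # and the tracking term pays for it
  expect_gte(rec2$objective[["tracking"]],
             rec1$objective[["tracking"]] * (1 - 1e-6))
})

test_that("the reconstructed motion is stable under grid refinement", {
  # discretization convergence: halving the integration step changes the
  # exact-fit solution trajectory only through the integrator's truncation
  # error, far below the motion amplitude
  tp <- toy_problem()
  rec_c <- cached("toy_rec0", function() toy_solve(0))
  rec_f <- cached("toy_rec_href", function()
    reconstruct_gait(tp$model, tp$reference, tp$schedule,
                     ocp_config(gamma_u = 0, node_spacing = 0.03,
                                h = 0.005, max_iter = 15L)))
  qc <- predict(rec_c, tp$reference$times)$q
  qf <- predict(rec_f, tp$reference$times)$q
  amp <- rms(sweep(tp$reference$q, 2, tp$reference$q[1, ]))
  expect_lt(rms(qf - qc) / amp, 0.01)
})

test_that("check_solution verifies a converged result and flags corruption", {
  rec <- cached("toy_rec0", function() toy_solve(0))
  chk <- check_solution(rec)
  expect_true(chk$ok)
  expect_lt(chk$max_defect, 1e-3)
  expect_true(is.finite(chk$min_vertical_force))
  # corrupting the torques produces a visible re-integration defect
  bad <- rec
  bad$U[[1]][, 1] <- bad$U[[1]][, 1] + 30
  chk2 <- check_solution(bad)
  expect_gt(chk2$max_defect, 1e-2)
})

test_that("reconstruction methods expose the fit", {
  rec <- cached("toy_rec0", function() toy_solve(0))
  tp <- toy_problem()
  expect_output(print(rec), "Gait reconstruction")
  s <- summary(rec)
  expect_s3_class(s, "summary.gait_recon")
  expect_lt(max(s$rms_tracking_per_dof), 1e-3)
  cf <- coef(rec)
  expect_true(all(c("phase", "time", "hip_l_Ry") %in% names(cf)))
  res <- residuals(rec)
  expect_equal(dim(res), dim(tp$reference$q))
  expect_lt(max(abs(res)), 1e-2)
  pr <- predict(rec, c(0.05, 0.2))
  expect_equal(dim(pr$q), c(2, tp$model$n_dof))
  # torque recovery up to the double-support actuation redundancy: in
  # two-footed multi-point contact, torque combinations with
  # B tau in range(G^T) move nothing and are not identifiable
  u_true <- t(vapply(rec$times, tp$tau_fun, numeric(tp$model$n_act)))
  m <- tp$model
  cs <- contact_set(m, m$contacts$id, rec$x0[[1]][1:m$n_dof])
  ck <- gaitbench:::contact_kinematics(m, rec$x0[[1]][1:m$n_dof], NULL, cs)
  keep <- gaitbench:::reduce_contact_rows(ck$G, cs, ck$dims)
  G <- ck$G[keep, , drop = FALSE]
  B <- matrix(0, m$n_dof, m$n_act)
  B[cbind(m$actuated, seq_len(m$n_act))] <- 1
  M <- cbind(B, t(G))
  sv <- svd(M, nv = ncol(M))
  dd <- c(sv$d, rep(0, ncol(M) - length(sv$d)))
  Ntau <- sv$v[seq_len(m$n_act), dd < 1e-8 * max(dd), drop = FALSE]
  qn <- qr(Ntau)
  P <- diag(m$n_act)
  if (qn$rank > 0) {
    Qb <- qr.Q(qn)[, seq_len(qn$rank), drop = FALSE]
    P <- P - Qb %*% t(Qb)
  }
  du <- (rec$u - u_true) %*% P
  up <- u_true %*% P
  expect_lt(rms(du) / rms(up), 0.05)
})
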