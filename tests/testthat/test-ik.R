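test_that("IK recovers an exactly consistent pose", {
  m <- planar_model()
  mset <- default_marker_set(m)
  set.seed(41)
  q_star <- standing_pose(m) + rnorm(m$n_dof, 0, 0.15)
  md <- synthesize_markers(m, 0, rbind(q_star), mset)
  mk <- matrix(md$markers[1, , ], ncol = 3,
               dimnames = list(dimnames(md$markers)[[2]], NULL))
  fit <- fit_frame(m, mset, mk, q_star + rnorm(m$n_dof, 0, 0.05))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$q - q_star)), 1e-8)
  expect_lt(fit$residual, 1e-8)
})

test_that("IK residual matches the least-squares noise expectation", {
  m <- planar_model()
  mset <- default_marker_set(m)
  sigma <- 0.005
  n_markers <- nrow(mset)
  set.seed(42)
  q_star <- standing_pose(m) + rnorm(m$n_dof, 0, 0.1)
  msq <- numeric(100)
  for (rep in 1:100) {
    md <- synthesize_markers(m, 0, rbind(q_star), mset,
                             noise_sigma = sigma, seed = rep)
    mk <- matrix(md$markers[1, , ], ncol = 3,
                 dimnames = list(dimnames(md$markers)[[2]], NULL))
    msq[rep] <- fit_frame(m, mset, mk, q_star)$residual^2
  }
  # E[sum of squared residuals] = sigma^2 (3 m - n_dof); per-marker mean
  expected <- sigma^2 * (3 * n_markers - m$n_dof) / n_markers
  expect_lt(abs(mean(msq) - expected) / expected, 0.1)
})

test_that("trajectory fitting warm-starts and validates ordering", {
  m <- planar_model()
  mset <- default_marker_set(m)
  q_star <- standing_pose(m)
  md <- synthesize_markers(m, c(0, 0.01, 0.02),
                           rbind(q_star, q_star, q_star), mset)
  ref <- fit_trajectory(m, mset, md, q_init = q_star + 0.02)
  expect_equal(nrow(ref$q), 3)
  expect_lt(max(abs(ref$q - rep(q_star, each = 3))), 1e-7)
  md_rev <- md; md_rev$times <- rev(md$times)
  expect_error(fit_trajectory(m, mset, md_rev), "ordered")
})

test_that("rigid marker transforms move only the base coordinates", {
  m <- planar_model()
  mset <- default_marker_set(m)
  set.seed(43)
  q_star <- standing_pose(m) + rnorm(m$n_dof, 0, 0.1)
  md <- synthesize_markers(m, 0, rbind(q_star), mset)
  mk <- matrix(md$markers[1, , ], ncol = 3,
               dimnames = list(dimnames(md$markers)[[2]], NULL))
  fit0 <- fit_frame(m, mset, mk, q_star)
  # rigidly translate and pitch all markers (planar transform)
  dtheta <- 0.07; dxz <- c(0.11, 0, -0.04)
  R <- gaitbench:::roty(-dtheta)   # active rotation of the scene
  mk2 <- t(apply(mk, 1, function(p) as.numeric(R %*% p) + dxz))
  rownames(mk2) <- rownames(mk)
  fit2 <- fit_frame(m, mset, mk2, fit0$q + c(0.1, -0.05, 0.05,
                                             numeric(m$n_dof - 3)))
  expect_lt(fit2$residual, 1e-8)
  # internal joint angles unchanged
  expect_lt(max(abs(fit2$q[4:9] - fit0$q[4:9])), 1e-8)
  expect_equal(fit2$q[3], fit0$q[3] + dtheta, tolerance = 1e-8)
})

test_that("frames with too few markers are skipped with a warning", {
  m <- planar_model()
  mset <- default_marker_set(m)
  q_star <- standing_pose(m)
  md <- synthesize_markers(m, 0, rbind(q_star), mset)
  mk <- matrix(md$markers[1, , ], ncol = 3,
               dimnames = list(dimnames(md$markers)[[2]], NULL))
  mk[3:nrow(mk), ] <- NA
  expect_warning(fit <- fit_frame(m, mset, mk, q_star), "fewer than 3")
  expect_true(is.na(fit$residual))
  # a residual-free fit stays residual-free when a consistent marker with
  # matching virtual position is added back
  mk_all <- matrix(md$markers[1, , ], ncol = 3,
                   dimnames = list(dimnames(md$markers)[[2]], NULL))
  sub <- mset[1:6, ]
  class(sub) <- class(mset)
  f_sub <- fit_frame(m, sub, mk_all, q_star)
  f_all <- fit_frame(m, mset, mk_all, q_star)
  expect_lte(f_all$residual, f_sub$residual + 1e-10)
})
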