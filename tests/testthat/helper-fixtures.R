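# Shared lazily-built fixtures: the heavier objects (models, the synthetic
# stride, its IK) are constructed once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

subject_a <- function() subject_anthropometry("female", 54.1, 1.68, 0.792)
subject_b <- function() subject_anthropometry("male", 89.0, 1.88, 0.862)

segments_a <- function() cached("segments_a", function()
  de_leva_parameters(subject_a()))

reduced_model <- function() cached("reduced_model", function()
  build_reduced_model(segments_a()))

full_model <- function() cached("full_model", function()
  build_full_model(segments_a()))

planar_model <- function() cached("planar_model", function()
  build_planar_walker(de_leva_parameters(
    subject_anthropometry("male", 72, 1.75))))

stride_fixture <- function() cached("stride_fixture", function()
  planar_stride_fixture())

stride_reference <- function() cached("stride_reference", function() {
  fx <- stride_fixture()
  fit_trajectory(fx$model, fx$mset, fx$markers, q_init = fx$sim$q[1, ])
})

# a planar rigid rod on a floating planar base: the analytic test body for
# impact and angular-momentum closed forms
rod_model <- function() cached("rod_model", function() {
  m <- 3; L <- 1.2
  Ic <- m * L^2 / 12
  segs <- list(rod = list(name = "rod", type = "rod", side = NA,
                          mass = m, com_offset = c(0, 0, -L / 2),
                          inertia = diag(c(Ic, Ic, 1e-4)), length = L))
  class(segs) <- "segment_params"
  attr(segs, "anthro") <- subject_anthropometry("male", m, L + 0.3)
  bp <- list(base = list(segment = "rod", dof = c("Px", "Pz", "Ry")),
             joints = list(),
             fused = list(),
             contacts = data.frame(segment = "rod", side = "left",
                                   point = "tip", x = 0, y = 0, z = -L,
                                   id = "left_tip"),
             planar = TRUE)
  compile_model(bp, segs, type = "custom")
})

rms <- function(x) sqrt(mean(x^2))

# torque-recovery comparison on the identifiable projection, weighted by
# phase duration: in phases with redundant multi-point contact, torque
# components in the null space of [B G^T] produce no motion and are gauge,
# not signal; the duration weights make the comparison the RMS difference
# of the torque trajectories rather than of the (unevenly spaced) node
# values
projected_torque_error <- function(rec, fx) {
  model <- fx$model
  err <- c(); refv <- c(); wts <- c()
  for (i in seq_len(nrow(fx$schedule))) {
    dur <- fx$schedule$t_end[i] - fx$schedule$t_start[i]
    cs <- contact_set(model, attr(fx$schedule, "contacts")[[i]],
                      rec$x0[[i]][1:model$n_dof])
    for (m in seq_along(rec$nodes[[i]])) {
      tn <- rec$nodes[[i]][m]
      k <- gaitbench:::.post_index(rec$times, tn)
      ck <- gaitbench:::contact_kinematics(model, rec$q[k, ], NULL, cs)
      keep <- gaitbench:::reduce_contact_rows(ck$G, cs, ck$dims)
      G <- ck$G[keep, , drop = FALSE]
      B <- matrix(0, model$n_dof, model$n_act)
      B[cbind(model$actuated, seq_len(model$n_act))] <- 1
      M <- cbind(B, t(G))
      sv <- svd(M, nv = ncol(M))
      dd <- c(sv$d, rep(0, ncol(M) - length(sv$d)))
      ns <- sv$v[, dd < 1e-8 * max(dd), drop = FALSE]
      du <- rec$U[[i]][m, ] - fx$controls[[i]]$values[m, ]
      ut <- fx$controls[[i]]$values[m, ]
      if (ncol(ns) > 0) {
        Ntau <- ns[seq_len(model$n_act), , drop = FALSE]
        qn <- qr(Ntau)
        if (qn$rank > 0) {
          Qb <- qr.Q(qn)[, seq_len(qn$rank), drop = FALSE]
          du <- du - Qb %*% (t(Qb) %*% du)
          ut <- ut - Qb %*% (t(Qb) %*% ut)
        }
      }
      w <- dur / length(rec$nodes[[i]])
      err <- c(err, du); refv <- c(refv, ut)
      wts <- c(wts, rep(w, length(du)))
    }
  }
  sqrt(sum(wts * err^2) / sum(wts)) / sqrt(sum(wts * refv^2) / sum(wts))
}

flagship_reconstruction <- function() {
  cached("flagship_rec", function() {
    fx <- stride_fixture()
    ref <- stride_reference()
    # thin the reference to 10 ms frames inside the two long single-support
    # phases (the 5 ms frames there double the tracking rows without adding
    # information); short phases keep every frame
    keep <- rep(TRUE, length(ref$times))
    long1 <- ref$times > 0.004 & ref$times < 0.394
    long2 <- ref$times > 0.534 & ref$times < 0.894
    odd <- seq_along(ref$times) %% 2 == 0
    keep[(long1 | long2) & odd] <- FALSE
    cfg <- ocp_config(gamma_u = 0, h = 0.005, segment_length = 0.04,
                      max_iter = 22L, track_times = ref$times[keep])
    reconstruct_gait(fx$model, ref, fx$schedule, cfg)
  })
}
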