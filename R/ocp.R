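# Multi-phase least-squares optimal control reconstruction.
#
# The stride is transcribed by per-phase multiple shooting: the decision
# variables are each phase's initial state and its piecewise-linear torque
# node values. The objective is the tracking term (squared deviation of
# the simulated generalized coordinates from the inverse-kinematics
# reference at the reference times) plus the control regularization
# gamma_u * ||W u||^2 evaluated at the same times. Continuity across phase
# boundaries is an equality constraint; at touch-down transitions the
# velocities are linked through the inelastic impact map. The resulting
# equality-constrained nonlinear least-squares problem is solved by
# Gauss-Newton on a KKT system, with Jacobians from first-order state
# transition matrices propagated along each phase (finite-difference
# linearization of the constrained dynamics at every integration step).

#' Configuration of the reconstruction problem
#'
#' @param node_spacing approximate spacing of the torque control nodes (s);
#'   every phase gets at least two nodes (its endpoints).
#' @param segment_length target length of the multiple-shooting segments
#'   (s); long phases are split into several segments with their own
#'   initial-state variables and continuity constraints, which keeps the
#'   transcription well-conditioned despite the open-loop instability of
#'   walking dynamics.
#' @param h integration step inside phases (s).
#' @param gamma_u control regularization factor (>= 0).
#' @param u_scale torque scale per actuated joint (N m); the weight matrix
#'   is `W = diag(1 / u_scale)`. Scalar or length `n_act`.
#' @param track_weights per-DoF tracking weights (default 1 for every
#'   generalized coordinate, including the floating base).
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol convergence threshold on the step norm.
#' @param ctol feasibility threshold on the continuity constraints.
#' @param x_bounds,u_bounds optional 2-row matrices (lower/upper) of state
#'   and control path bounds, checked on the solution and reported by
#'   [check_solution()].
#' @param lin_stages sensitivity scheme per integration step: 1 (default)
#'   linearizes once at the step midpoint and uses the full RK4 step
#'   polynomial; 4 chains the exact RK4 stage Jacobians (about three times
#'   the cost, slightly more accurate).
#' @param track_times optional subset of reference times to track (the
#'   warm start still differentiates the full reference); default: all.
#' @param verbose print per-iteration progress.
#' @return list of class `ocp_config`.
#' @export
ocp_config <- function(node_spacing = 0.02, segment_length = 0.08,
                       h = 0.01, gamma_u = 1e-3,
                       u_scale = 150, track_weights = NULL,
                       max_iter = 25L, tol = 1e-8, ctol = 1e-8,
                       x_bounds = NULL, u_bounds = NULL,
                       lin_stages = 1L, track_times = NULL,
                       verbose = FALSE) {
  stopifnot(node_spacing > 0, segment_length > 0, h > 0, gamma_u >= 0,
            all(u_scale > 0), lin_stages %in% c(1L, 4L))
  structure(list(node_spacing = node_spacing,
                 segment_length = segment_length, h = h, gamma_u = gamma_u,
                 u_scale = u_scale, track_weights = track_weights,
                 max_iter = as.integer(max_iter), tol = tol, ctol = ctol,
                 x_bounds = x_bounds, u_bounds = u_bounds,
                 lin_stages = as.integer(lin_stages),
                 track_times = track_times,
                 verbose = isTRUE(verbose)),
            class = "ocp_config")
}

## control node times per phase (shared rule with the synthetic fixture so
## that a fixture's torque grid is representable exactly)
phase_control_nodes <- function(schedule, node_spacing) {
  lapply(seq_len(nrow(schedule)), function(i) {
    dur <- schedule$t_end[i] - schedule$t_start[i]
    seq(schedule$t_start[i], schedule$t_end[i],
        length.out = max(2L, ceiling(dur / node_spacing) + 1L))
  })
}

## simulate one segment under PWL controls. Projection-free: the
## constraint-manifold projection is a non-smooth map that would corrupt
## the transcription's sensitivities; over the short shooting segments the
## acceleration-level constraint enforcement keeps drift negligible.
.ocp_phase_sim <- function(model, x0, U, nodes, contacts, t0, t1, h) {
  uf <- pwl_control(nodes, U)
  integrate_phase(model, x0, function(t) uf(t), contacts, t0, t1, h = h,
                  project = FALSE)
}

## first-order sensitivities along a simulated phase: state-transition
## matrices M_x (d x(t_k) / d x0) and M_u (d x(t_k) / d vec(U)) at every
## integration node, via FD linearization of the phase dynamics
.ocp_phase_linearize <- function(model, sim, U, nodes, contacts,
                                 stages = 1L) {
  n2 <- 2 * model$n_dof
  na <- model$n_act
  nn <- length(nodes)
  nu <- na * nn
  nt <- length(sim$times)
  uf <- pwl_control(nodes, U)
  Mx <- vector("list", nt); Mu <- vector("list", nt)
  Mx[[1]] <- diag(n2); Mu[[1]] <- matrix(0, n2, nu)
  if (nt == 1) return(list(Mx = Mx, Mu = Mu))
  # exact Jacobian of the RK4 step map, chained through the four stages
  # (A at the repeated midpoint stages is shared); A and B are FD
  # linearizations of the constrained dynamics at the stage states
  lin_at <- function(t, x, tau) {
    f0 <- .rhs_xt(model, x, tau, contacts)
    A <- matrix(0, n2, n2)
    for (j in seq_len(n2)) {
      ee <- 1e-6 * (1 + abs(x[j]))
      xp <- x; xp[j] <- xp[j] + ee
      A[, j] <- (.rhs_xt(model, xp, tau, contacts) - f0) / ee
    }
    B <- matrix(0, n2, na)
    for (j in seq_len(na)) {
      ee <- 1e-4 * (1 + abs(tau[j]))
      tp <- tau; tp[j] <- tp[j] + ee
      B[, j] <- (.rhs_xt(model, x, tp, contacts) - f0) / ee
    }
    list(f = f0, A = A, B = B)
  }
  Wt <- function(t) {
    w <- .pwl_weights(nodes, t)
    M <- matrix(0, na, nu)
    for (m in seq_len(nn))
      if (w[m] != 0) M[cbind(seq_len(na), (m - 1) * na + seq_len(na))] <- w[m]
    M
  }
  for (k in seq_len(nt - 1)) {
    hh <- sim$times[k + 1] - sim$times[k]
    t0 <- sim$times[k]; tm <- t0 + hh / 2; t1 <- t0 + hh
    x1 <- c(sim$q[k, ], sim$v[k, ])
    if (stages == 1L) {
      # single midpoint linearization with the full RK4 step polynomial:
      # for a frozen A the RK4 map is exactly I + hA + (hA)^2/2 + (hA)^3/6
      # + (hA)^4/24, and the cubic/quartic terms are NOT negligible for the
      # fast contact-constrained modes (h * lambda of order one)
      sm <- lin_at(tm, x1, as.numeric(uf(tm)))
      hA <- hh * sm$A
      hA2 <- hA %*% hA
      Phi <- diag(n2) + hA + hA2 / 2 + (hA2 %*% hA) / 6 +
        (hA2 %*% hA2) / 24
      Gam <- (hh * (diag(n2) + hA / 2 + hA2 / 6 + (hA2 %*% hA) / 24)) %*%
        sm$B
      dU <- Gam %*% Wt(tm)
      Mx[[k + 1]] <- Phi %*% Mx[[k]]
      Mu[[k + 1]] <- Phi %*% Mu[[k]] + dU
      next
    }
    u1 <- as.numeric(uf(t0)); um <- as.numeric(uf(tm))
    u4 <- as.numeric(uf(t1))
    s1 <- lin_at(t0, x1, u1)
    x2 <- x1 + hh / 2 * s1$f
    s2 <- lin_at(tm, x2, um)
    x3 <- x1 + hh / 2 * s2$f
    f3 <- .rhs_xt(model, x3, um, contacts)
    A3 <- s2$A; B3 <- s2$B                  # midpoint linearization shared
    x4 <- x1 + hh * f3
    s4 <- lin_at(t1, x4, u4)
    W1 <- Wt(t0); Wm <- Wt(tm); W4 <- Wt(t1)
    dk1 <- s1$A;                      du1 <- s1$B %*% W1
    dk2 <- s2$A %*% (diag(n2) + hh / 2 * dk1)
    du2 <- s2$A %*% (hh / 2 * du1) + s2$B %*% Wm
    dk3 <- A3 %*% (diag(n2) + hh / 2 * dk2)
    du3 <- A3 %*% (hh / 2 * du2) + B3 %*% Wm
    dk4 <- s4$A %*% (diag(n2) + hh * dk3)
    du4 <- s4$A %*% (hh * du3) + s4$B %*% W4
    Phi <- diag(n2) + hh / 6 * (dk1 + 2 * dk2 + 2 * dk3 + dk4)
    dU <- hh / 6 * (du1 + 2 * du2 + 2 * du3 + du4)
    Mx[[k + 1]] <- Phi %*% Mx[[k]]
    Mu[[k + 1]] <- Phi %*% Mu[[k]] + dU
  }
  list(Mx = Mx, Mu = Mu)
}

.rhs_xt <- function(model, x, tau, contacts) {
  s <- state_unpack(model, x)
  dyn <- constrained_forward_dynamics(model, s$q, s$v, tau, contacts,
                                      want_forces = FALSE)
  c(s$v, dyn$a)
}

## cubic Hermite interpolation weights over an integration-node interval:
## returns the interval index k and weights (q_k, v_k, q_{k+1}, v_{k+1})
.hermite_weights <- function(times, t) {
  k <- findInterval(t, times, all.inside = TRUE)
  dt <- times[k + 1] - times[k]
  if (dt <= 0) return(list(k = k, w = c(0, 0, 1, 0)))
  s <- (t - times[k]) / dt
  list(k = k,
       w = c(2 * s^3 - 3 * s^2 + 1, dt * (s^3 - 2 * s^2 + s),
             -2 * s^3 + 3 * s^2, dt * (s^3 - s^2)))
}

.pwl_weights <- function(nodes, t) {
  nn <- length(nodes)
  w <- numeric(nn)
  if (t <= nodes[1]) { w[1] <- 1; return(w) }
  if (t >= nodes[nn]) { w[nn] <- 1; return(w) }
  k <- findInterval(t, nodes)
  a <- (t - nodes[k]) / (nodes[k + 1] - nodes[k])
  w[k] <- 1 - a; w[k + 1] <- a
  w
}

#' Reconstruct dynamically consistent gait from a reference motion
#'
#' Fits state and joint-torque trajectories of the multibody model to an
#' inverse-kinematics reference over the stride phase schedule, solving the
#' multi-phase least-squares optimal control problem described above.
#'
#' @param model a `multibody_model`.
#' @param reference a `reference_motion` from [fit_trajectory()] (or any
#'   list with `times` and `q`).
#' @param schedule a `phase_schedule` from [build_phase_schedule()],
#'   consistent with the reference time span.
#' @param config an [ocp_config()].
#' @param init optional warm start: list with `x0` (list of per-phase
#'   initial states) and `U` (list of per-phase control node matrices).
#'   Default: states from the reference, torques from constrained inverse
#'   dynamics along the reference.
#' @return An object of class `gait_recon` (see [print.gait_recon()],
#'   [coef.gait_recon()], [predict.gait_recon()], [check_solution()]).
#' @export
reconstruct_gait <- function(model, reference, schedule,
                             config = ocp_config(), init = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"))
  n <- model$n_dof; n2 <- 2 * n; na <- model$n_act
  nph <- nrow(schedule)
  contacts_l <- attr(schedule, "contacts")
  trans <- attr(schedule, "transitions")
  nodes_l <- phase_control_nodes(schedule, config$node_spacing)
  wtrack <- config$track_weights %||% rep(1, n)
  W <- 1 / rep(config$u_scale, length.out = na)
  sg <- sqrt(config$gamma_u)

  # multiple-shooting segments: long phases are split
  seg <- do.call(rbind, lapply(seq_len(nph), function(i) {
    dur <- schedule$t_end[i] - schedule$t_start[i]
    ns <- max(1L, round(dur / config$segment_length))
    bnd <- seq(schedule$t_start[i], schedule$t_end[i], length.out = ns + 1)
    data.frame(phase = i, t0 = bnd[-(ns + 1)], t1 = bnd[-1],
               first = c(TRUE, rep(FALSE, ns - 1)))
  }))
  nseg <- nrow(seg)
  seg$impact <- seg$first & seg$phase %in% trans$after_phase

  # reference frames assigned to segments (boundary frames go to the
  # earlier segment, whose trajectory contains the boundary point)
  tref <- reference$times
  qref <- as.matrix(reference$q)
  keep <- tref >= schedule$t_start[1] - 1e-9 &
    tref <= schedule$t_end[nph] + 1e-9
  tref <- tref[keep]; qref <- qref[keep, , drop = FALSE]
  if (!is.null(config$track_times)) {
    # track only the requested subset of reference frames (the warm start
    # still differentiates the full reference)
    sel <- vapply(tref, function(t)
      any(abs(config$track_times - t) < 1e-9), TRUE)
    tref <- tref[sel]; qref <- qref[sel, , drop = FALSE]
  }
  fseg <- pmin(pmax(findInterval(tref, seg$t0), 1L), nseg)

  # variable layout: all segment states, then all phase control blocks
  nn_l <- vapply(nodes_l, length, 0L)
  xoff <- (seq_len(nseg) - 1L) * n2
  uoff <- nseg * n2 + c(0, cumsum(na * nn_l))[seq_len(nph)]
  nz <- nseg * n2 + sum(na * nn_l)
  ucols <- function(i) uoff[i] + seq_len(na * nn_l[i])

  guess <- init %||% .ocp_initial_guess(model, reference, schedule, nodes_l,
                                        seg)
  if (is.null(guess$x0s)) {
    # per-phase init supplied: replicate the phase state to its segments
    guess$x0s <- lapply(seq_len(nseg), function(k) {
      i <- seg$phase[k]
      if (seg$first[k]) guess$x0[[i]]
      else .seg_state_from_reference(model, reference, seg$t0[k])
    })
  }

  pack <- function(x0s, U_l)
    c(unlist(x0s), unlist(lapply(U_l, function(U) as.vector(t(U)))))
  unpack <- function(z) {
    x0s <- lapply(seq_len(nseg), function(k) z[xoff[k] + 1:n2])
    U <- lapply(seq_len(nph), function(i)
      matrix(z[ucols(i)], nn_l[i], na, byrow = TRUE))
    list(x0s = x0s, U = U)
  }

  nres <- length(tref) * (n + na)
  eval_all <- function(z, need_jac = FALSE) {
    zz <- unpack(z)
    sims <- vector("list", nseg); lins <- vector("list", nseg)
    csl <- vector("list", nseg)
    r <- numeric(nres); rpos <- 0L
    c_eq <- numeric((nseg - 1) * n2)
    Jr <- if (need_jac) matrix(0, nres, nz) else NULL
    Ac <- if (need_jac) matrix(0, (nseg - 1) * n2, nz) else NULL
    ends <- vector("list", nseg)
    track_sq <- 0; reg_sq <- 0
    for (k in seq_len(nseg)) {
      i <- seg$phase[k]
      cs <- contact_set(model, contacts_l[[i]], zz$x0s[[k]][1:n])
      csl[[k]] <- cs
      sims[[k]] <- .ocp_phase_sim(model, zz$x0s[[k]], zz$U[[i]],
                                  nodes_l[[i]], cs, seg$t0[k], seg$t1[k],
                                  config$h)
      nt <- length(sims[[k]]$times)
      ends[[k]] <- c(sims[[k]]$q[nt, ], sims[[k]]$v[nt, ])
      if (need_jac)
        lins[[k]] <- .ocp_phase_linearize(model, sims[[k]], zz$U[[i]],
                                          nodes_l[[i]], cs,
                                          stages = config$lin_stages %||% 1L)
      jdx <- which(fseg == k)
      for (j in jdx) {
        # cubic Hermite interpolation between integration nodes (positions
        # and velocities): a linear interpolant would floor the attainable
        # tracking at the h^2 interpolation error
        hw <- .hermite_weights(sims[[k]]$times, tref[j])
        kk <- hw$k
        qj <- hw$w[1] * sims[[k]]$q[kk, ] + hw$w[2] * sims[[k]]$v[kk, ] +
          hw$w[3] * sims[[k]]$q[kk + 1, ] + hw$w[4] * sims[[k]]$v[kk + 1, ]
        rj <- sqrt(wtrack) * (qj - qref[j, ])
        r[rpos + 1:n] <- rj
        track_sq <- track_sq + sum(rj^2)
        if (need_jac) {
          iq <- 1:n; iv <- n + 1:n
          Mx <- hw$w[1] * lins[[k]]$Mx[[kk]][iq, , drop = FALSE] +
            hw$w[2] * lins[[k]]$Mx[[kk]][iv, , drop = FALSE] +
            hw$w[3] * lins[[k]]$Mx[[kk + 1]][iq, , drop = FALSE] +
            hw$w[4] * lins[[k]]$Mx[[kk + 1]][iv, , drop = FALSE]
          Mu <- hw$w[1] * lins[[k]]$Mu[[kk]][iq, , drop = FALSE] +
            hw$w[2] * lins[[k]]$Mu[[kk]][iv, , drop = FALSE] +
            hw$w[3] * lins[[k]]$Mu[[kk + 1]][iq, , drop = FALSE] +
            hw$w[4] * lins[[k]]$Mu[[kk + 1]][iv, , drop = FALSE]
          Jr[rpos + 1:n, xoff[k] + 1:n2] <- sqrt(wtrack) * Mx
          Jr[rpos + 1:n, ucols(i)] <- sqrt(wtrack) * Mu
        }
        rpos <- rpos + n
        uj <- as.numeric(pwl_control(nodes_l[[i]], zz$U[[i]])(tref[j]))
        rr <- sg * W * uj
        r[rpos + 1:na] <- rr
        reg_sq <- reg_sq + sum(rr^2)
        if (need_jac) {
          wts <- .pwl_weights(nodes_l[[i]], tref[j])
          for (m in seq_len(nn_l[i]))
            if (wts[m] != 0) {
              cidx <- uoff[i] + (m - 1) * na + seq_len(na)
              Jr[cbind(rpos + seq_len(na), cidx)] <- sg * W * wts[m]
            }
        }
        rpos <- rpos + na
      }
    }
    # continuity constraints between consecutive segments; at phase
    # boundaries with a touch-down the velocities map through the impact
    for (k in seq_len(nseg - 1)) {
      xe <- ends[[k]]
      kp <- k + 1L
      if (seg$impact[kp]) {
        cs_next <- contact_set(model, contacts_l[[seg$phase[kp]]], xe[1:n])
        im <- impact_map(model, xe[1:n], xe[n + 1:n], cs_next)
        map_x <- c(xe[1:n], im$v_plus)
      } else map_x <- xe
      crows <- (k - 1) * n2 + 1:n2
      c_eq[crows] <- zz$x0s[[kp]] - map_x
      if (need_jac) {
        Ac[cbind(crows, xoff[kp] + 1:n2)] <- 1
        DmapDxe <- if (seg$impact[kp])
          .impact_jacobian(model, xe, contacts_l[[seg$phase[kp]]])
        else diag(n2)
        nt <- length(sims[[k]]$times)
        i <- seg$phase[k]
        Ac[crows, xoff[k] + 1:n2] <- Ac[crows, xoff[k] + 1:n2] -
          DmapDxe %*% lins[[k]]$Mx[[nt]]
        Ac[crows, ucols(i)] <- Ac[crows, ucols(i)] -
          DmapDxe %*% lins[[k]]$Mu[[nt]]
      }
    }
    list(r = r, c = c_eq,
         Jr = Jr,
         Ac = if (need_jac) Ac else matrix(0, 0, nz),
         sims = sims, csl = csl, track = track_sq, reg = reg_sq)
  }

  if (!is.null(config$debug_env)) {
    for (nm in c("eval_all", "pack", "unpack", "guess", "seg", "nodes_l"))
      assign(nm, get(nm), envir = config$debug_env)
    return(invisible(NULL))
  }
  z <- pack(guess$x0s, guess$U)
  ev <- eval_all(z, need_jac = FALSE)
  merit <- function(ev) sum(ev$r^2) + 1e4 * sum(ev$c^2)
  m0 <- merit(ev)
  converged <- FALSE; iter <- 0L; step_norm <- NA_real_
  nu <- 1e-10
  while (iter < config$max_iter) {
    iter <- iter + 1L
    ev <- eval_all(z, need_jac = TRUE)
    J <- ev$Jr; A <- ev$Ac
    g <- crossprod(J, ev$r)
    Hgn <- crossprod(J)
    nc <- length(ev$c)
    lam0 <- 1e-12 * max(diag(Hgn), 1)  # absolute floor for weakly coupled
    K <- rbind(cbind(Hgn + nu * diag(diag(Hgn)) + lam0 * diag(nz), t(A)),
               cbind(A, matrix(0, nc, nc)))
    sol <- tryCatch(solve(K, c(-g, -ev$c)),
                    error = function(e) { if (config$verbose)
                      message("  [KKT] ", conditionMessage(e)); NULL })
    if (is.null(sol) || any(!is.finite(sol))) {
      nu <- max(nu * 100, 1e-6)
      if (config$verbose)
        message(sprintf("  it %2d: KKT solve failed, damping -> %.1e",
                        iter, nu))
      if (nu > 1e8) break
      next
    }
    dz <- sol[1:nz]
    step_norm <- sqrt(sum(dz^2))
    # trust-region style cap: gigantic Newton steps (ill-conditioned KKT)
    # are shortened before the line search ever sees them
    if (step_norm > 200) dz <- dz * (200 / step_norm)
    alpha <- 1; accepted <- FALSE
    for (ls in 1:10) {
      zc <- z + alpha * dz
      evc <- tryCatch(eval_all(zc, need_jac = FALSE),
                      error = function(e) NULL)
      if (!is.null(evc) && merit(evc) <= m0 * (1 + 1e-12) + 1e-14) {
        z <- zc; ev <- evc; m0 <- merit(evc); accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { nu <- max(nu * 100, 1e-8)
      if (config$verbose)
        message(sprintf(
          "  it %2d: step rejected (|dz| %.2e, merit %.3e), damping -> %.1e",
          iter, step_norm, m0, nu))
      if (nu > 1e8) break
      next
    }
    step_norm <- min(step_norm, 200)
    nu <- max(nu / 10, 1e-12)
    if (config$verbose)
      message(sprintf(
        "  it %2d: obj %.3e (track %.3e, reg %.3e) |c| %.2e |dz| %.2e a %.3g",
        iter, sum(ev$r^2), ev$track, ev$reg,
        if (length(ev$c)) max(abs(ev$c)) else 0, alpha * step_norm, alpha))
    if (alpha * step_norm < config$tol &&
        (length(ev$c) == 0 || max(abs(ev$c)) < config$ctol)) {
      converged <- TRUE
      break
    }
  }
  ev <- eval_all(z, need_jac = FALSE)
  zz <- unpack(z)

  # concatenated trajectory with duplicated boundary samples
  times <- c(); Q <- NULL; V <- NULL; Uu <- NULL; Ff <- NULL; phase <- c()
  fids <- model$contacts$id
  for (k in seq_len(nseg)) {
    i <- seg$phase[k]
    s <- ev$sims[[k]]
    pick <- if (seg$first[k]) seq_along(s$times) else seq_along(s$times)[-1]
    uf <- pwl_control(nodes_l[[i]], zz$U[[i]])
    times <- c(times, s$times[pick])
    Q <- rbind(Q, s$q[pick, , drop = FALSE])
    V <- rbind(V, s$v[pick, , drop = FALSE])
    Uu <- rbind(Uu, t(vapply(s$times[pick], function(t) as.numeric(uf(t)),
                             numeric(na))))
    Ff <- rbind(Ff, t(vapply(pick, function(kk) {
      dyn <- constrained_forward_dynamics(model, s$q[kk, ], s$v[kk, ],
                                          as.numeric(uf(s$times[kk])),
                                          ev$csl[[k]])
      out <- stats::setNames(numeric(length(fids)), fids)
      if (nrow(dyn$forces) > 0) out[rownames(dyn$forces)] <- dyn$forces[, 3]
      out
    }, numeric(length(fids)))))
    phase <- c(phase, rep(i, length(pick)))
  }

  structure(list(model = model, schedule = schedule, config = config,
                 reference = list(times = tref, q = qref),
                 x0 = zz$x0s[which(seg$first)], U = zz$U, nodes = nodes_l,
                 x0_segments = zz$x0s, segments = seg,
                 times = times, q = Q, v = V, u = Uu, forces = Ff,
                 phase = phase,
                 objective = c(total = sum(ev$r^2), tracking = ev$track,
                               regularization = ev$reg),
                 constraint_norm = if (length(ev$c)) max(abs(ev$c)) else 0,
                 solver = list(iterations = iter, converged = converged,
                               step_norm = step_norm)),
            class = "gait_recon")
}

## state at an arbitrary time from the reference (velocities by local
## finite differences)
.seg_state_from_reference <- function(model, reference, t) {
  tr <- reference$times; qr_ <- as.matrix(reference$q)
  q <- .interp_row(tr, qr_, t)
  hh <- 0.004
  ta <- max(tr[1], t - hh); tb <- min(tr[length(tr)], t + hh)
  v <- (.interp_row(tr, qr_, tb) - .interp_row(tr, qr_, ta)) / (tb - ta)
  c(q, v)
}

## reorder Mu columns from node-major (na per node, node index fastest in
## .ocp_phase_linearize) to the row-major vec(t(U)) layout used in z
.mu_reorder <- function(Mu, nn, na) Mu  # layouts already agree

.nearest_node <- function(times, t) which.min(abs(times - t))

.interp_row <- function(times, M, t) {
  k <- findInterval(t, times, all.inside = TRUE)
  if (times[k + 1] == times[k]) return(M[k + 1, ])
  a <- (t - times[k]) / (times[k + 1] - times[k])
  (1 - a) * M[k, ] + a * M[k + 1, ]
}

## FD Jacobian of the transition map x- -> (q, v+) at a touch-down
.impact_jacobian <- function(model, x_end, contact_ids) {
  n <- length(x_end) / 2
  map <- function(x) {
    cs <- contact_set(model, contact_ids, x[1:n])
    im <- impact_map(model, x[1:n], x[n + 1:n], cs)
    c(x[1:n], im$v_plus)
  }
  f0 <- map(x_end)
  Jc <- matrix(0, 2 * n, 2 * n)
  for (j in seq_len(2 * n)) {
    ee <- 1e-6 * (1 + abs(x_end[j]))
    xp <- x_end; xp[j] <- xp[j] + ee
    Jc[, j] <- (map(xp) - f0) / ee
  }
  Jc
}

## default warm start: states from the reference with high-order
## finite-difference velocities and accelerations computed per phase (so
## the stencils never straddle an impact), torques from constrained
## inverse dynamics, refined by a per-phase stabilized rollout
.ocp_initial_guess <- function(model, reference, schedule, nodes_l,
                               seg = NULL) {
  n <- model$n_dof
  tr <- reference$times; qr_ <- as.matrix(reference$q)
  contacts_l <- attr(schedule, "contacts")
  nph <- nrow(schedule)

  # per-phase frame sets (boundary frames belong to both adjacent phases;
  # q is continuous there while the one-sided stencils give each phase its
  # own velocity side)
  ph <- vector("list", nph)
  for (i in seq_len(nph)) {
    idx <- which(tr >= schedule$t_start[i] - 1e-9 &
                   tr <= schedule$t_end[i] + 1e-9)
    tt <- tr[idx]
    Q <- qr_[idx, , drop = FALSE]
    V <- .fd_matrix(tt, Q)
    A <- .fd_matrix(tt, V)
    ph[[i]] <- list(t = tt, Q = Q, V = V, A = A)
  }
  interp_ph <- function(i, M, t) .interp_row(ph[[i]]$t, M, t)

  x0 <- vector("list", nph); U <- vector("list", nph)
  for (i in seq_len(nph)) {
    t0 <- schedule$t_start[i]
    x0[[i]] <- c(interp_ph(i, ph[[i]]$Q, t0), interp_ph(i, ph[[i]]$V, t0))
    cs <- contact_set(model, contacts_l[[i]], x0[[i]][1:n])
    U[[i]] <- t(vapply(nodes_l[[i]], function(tn) {
      inverse_dynamics_contact(model,
                               interp_ph(i, ph[[i]]$Q, tn),
                               interp_ph(i, ph[[i]]$V, tn),
                               interp_ph(i, ph[[i]]$A, tn), cs)$tau
    }, numeric(model$n_act)))
  }

  # stabilized rollout pass: roll each phase under the inverse-dynamics
  # torques plus an inertia-scaled PD correction toward the reference and
  # resample the applied torque at the nodes, absorbing residual
  # differentiation error
  Hd <- diag(crba(model, x0[[1]][1:n]))[model$actuated]
  wn <- 15
  kp <- Hd * wn^2; kd <- 1.8 * Hd * wn
  for (i in seq_len(nph)) {
    t0 <- schedule$t_start[i]; t1 <- schedule$t_end[i]
    cs <- contact_set(model, contacts_l[[i]], x0[[i]][1:n])
    uf <- pwl_control(nodes_l[[i]], U[[i]])
    ctrl <- function(t, q, v) {
      as.numeric(uf(t)) +
        kp * (interp_ph(i, ph[[i]]$Q, t) - q)[model$actuated] +
        kd * (interp_ph(i, ph[[i]]$V, t) - v)[model$actuated]
    }
    s <- tryCatch(integrate_phase(model, x0[[i]], ctrl, cs, t0, t1,
                                  h = min(0.005, (t1 - t0) / 2),
                                  project = FALSE),
                  error = function(e) NULL)
    if (is.null(s)) next
    U[[i]] <- t(vapply(nodes_l[[i]], function(tn) {
      k <- which.min(abs(s$times - tn))
      ctrl(s$times[k], s$q[k, ], s$v[k, ])
    }, numeric(model$n_act)))
  }

  # toe-only single-support slivers are underactuated and too short to be
  # observable from the tracking data; carry the previous phase's final
  # torque through them (torque continuity)
  toe_only <- vapply(contacts_l, function(ids)
    length(ids) == 2 && all(grepl("hallux|meta5", ids)), TRUE)
  for (i in which(toe_only)) if (i > 1) {
    prev <- U[[i - 1]]
    U[[i]] <- matrix(prev[nrow(prev), ], nrow(U[[i]]), ncol(prev),
                     byrow = TRUE)
  }

  x0s <- if (!is.null(seg)) {
    lapply(seq_len(nrow(seg)), function(k) {
      i <- seg$phase[k]
      c(interp_ph(i, ph[[i]]$Q, seg$t0[k]),
        interp_ph(i, ph[[i]]$V, seg$t0[k]))
    })
  } else NULL
  list(x0 = x0, U = U, x0s = x0s)
}

## derivative of uniformly sampled rows: 5-point central stencils inside,
## 4th-order one-sided stencils at the edges; falls back to simple
## differences when the grid is too short or non-uniform
.fd_matrix <- function(t, M) {
  nr <- length(t)
  D <- M * 0
  if (nr < 2) return(D)
  h <- diff(t)
  if (nr < 6 || max(h) - min(h) > 1e-6 * max(h)) {
    D[1, ] <- (M[2, ] - M[1, ]) / (t[2] - t[1])
    D[nr, ] <- (M[nr, ] - M[nr - 1, ]) / (t[nr] - t[nr - 1])
    if (nr > 2)
      D[2:(nr - 1), ] <- (M[3:nr, , drop = FALSE] -
                            M[1:(nr - 2), , drop = FALSE]) /
        (t[3:nr] - t[1:(nr - 2)])
    return(D)
  }
  hh <- h[1]
  ii <- 3:(nr - 2)
  D[ii, ] <- (-M[ii + 2, , drop = FALSE] + 8 * M[ii + 1, , drop = FALSE] -
                8 * M[ii - 1, , drop = FALSE] + M[ii - 2, , drop = FALSE]) /
    (12 * hh)
  fwd <- function(k) (-25 * M[k, ] + 48 * M[k + 1, ] - 36 * M[k + 2, ] +
                        16 * M[k + 3, ] - 3 * M[k + 4, ]) / (12 * hh)
  bwd <- function(k) (25 * M[k, ] - 48 * M[k - 1, ] + 36 * M[k - 2, ] -
                        16 * M[k - 3, ] + 3 * M[k - 4, ]) / (12 * hh)
  D[1, ] <- fwd(1); D[2, ] <- fwd(2)
  D[nr - 1, ] <- bwd(nr - 1); D[nr, ] <- bwd(nr)
  D
}
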