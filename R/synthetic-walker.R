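# Synthetic multibody walking fixtures.
#
# A full planar stride with the canonical 8-phase contact schedule is
# generated in three stages:
#   1. a contact-consistent kinematic gait pattern (analytic leg IK over
#      crafted ankle/foot-pitch trajectories; stance feet pinned exactly);
#   2. constrained inverse dynamics of that pattern along the scheduled
#      contact sets, sampled as piecewise-linear torque profiles;
#   3. an open-loop hybrid re-simulation (scheduled contact changes with
#      inelastic impact maps at touch-downs) driven by those torques.
# The re-simulated trajectory, not the kinematic pattern, is the ground
# truth of the fixture: by construction it satisfies the package dynamics
# to integrator tolerance, and its torques are exactly piecewise linear.

## quintic smoothstep and its slope (zero rate at both ends)
.s5 <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3

## planar rotation of (x, z) about +y by phi (toes-down positive)
.rot2 <- function(phi, p) c(cos(phi) * p[1] + sin(phi) * p[2],
                            -sin(phi) * p[1] + cos(phi) * p[2])

## sagittal two-link leg IK: hip and ankle in the x-z plane -> from-down
## link angles (positive forward), human knee (knee in front of the
## hip-ankle chord)
.leg_ik <- function(hip, ankle, Lt, Ls) {
  d2 <- sum((ankle - hip)^2); d <- sqrt(d2)
  dmax <- (Lt + Ls) * (1 - 1e-9)
  if (d > dmax)
    stop("leg target unreachable (d = ", round(d, 3), " m > ",
         round(Lt + Ls, 3), " m): step too long for the leg")
  alpha <- atan2(ankle[1] - hip[1], hip[2] - ankle[2])
  bh <- acos(pmin(1, pmax(-1, (Lt^2 + d2 - Ls^2) / (2 * Lt * d))))
  bk <- acos(pmin(1, pmax(-1, (Lt^2 + Ls^2 - d2) / (2 * Lt * Ls))))
  theta_t <- unname(alpha + bh)
  theta_s <- theta_t - (pi - bk)
  c(theta_t = theta_t, theta_s = theta_s)
}

#' Parameters of the synthetic planar stride
#'
#' Event fractions follow the canonical stride grammar (stride from left
#' toe off; single support about 60\% per foot, short toe-only and
#' heel-rollover slivers around the touch-downs).
#'
#' @param step_length distance between successive (opposite-foot)
#'   placements (m).
#' @param stride_time stride duration (s).
#' @param clearance swing foot clearance (m).
#' @param phi_max heel-rise (toe pivot) foot pitch (rad).
#' @param phi_land heel-strike foot pitch (rad, negative = toes up).
#' @param hip_drop hip height as a fraction of full leg extension.
#' @return list of pattern parameters.
#' @export
stride_pattern <- function(step_length = 0.42, stride_time = 1.0,
                           clearance = 0.05, phi_max = 0.40,
                           phi_land = -0.20, hip_drop = 0.945,
                           pelvis_lead = 0.20) {
  list(step_length = step_length, stride_time = stride_time,
       clearance = clearance, phi_max = phi_max, phi_land = phi_land,
       hip_drop = hip_drop, pelvis_lead = pelvis_lead,
       frac = c(rho = 0.398, lhs = 0.40, lts = 0.47, rto = 0.53,
                lho = 0.898, rhs = 0.90, rts = 0.97))
}

## kinematic reference of the planar stride: q(t) on a dense grid, exactly
## satisfying the scheduled contacts
planar_stride_reference <- function(model, pattern = stride_pattern(),
                                    dt = 0.002) {
  stopifnot(model$type == "planar")
  Lt <- model$segments$thigh_l$length
  Ls <- model$segments$shank_l$length
  Lf <- model$segments$foot_l$length
  h <- -model$contacts$z[1]                      # ankle height
  heel_l <- c(-0.25 * Lf, -h)                    # sagittal local offsets
  toe_l <- c(0.75 * Lf, -h)
  S <- pattern$step_length
  T <- pattern$stride_time
  fr <- pattern$frac * T
  vbar <- 2 * S / T
  z_hip <- pattern$hip_drop * (Lt + Ls) + h

  # flat ankle x positions: right support at 0, left lands at +S, right
  # relands at +2S; the left foot lifted from -S before the stride started
  ankle_flat <- c(R0 = 0, L1 = S, R1 = 2 * S, Lprev = -S)

  # per-foot ankle pose (x, z, phi) as a function of time
  foot_pose <- function(t, side) {
    pivot_about <- function(pv, off, phi) c(pv - .rot2(phi, off), phi)
    flat <- function(xa) c(xa, h, 0)
    ramp <- function(t0, t1, a, b) a + (.s5((t - t0) / (t1 - t0))) * (b - a)
    if (side == "right") {
      toe_pv <- c(ankle_flat["R0"] + toe_l[1], 0)
      if (t <= fr["rho"]) return(flat(ankle_flat["R0"]))
      if (t <= fr["rto"]) {                      # heel rise, pivot on toe
        phi <- ramp(fr["rho"], fr["rto"], 0, pattern$phi_max)
        return(pivot_about(toe_pv, toe_l, phi))
      }
      if (t <= fr["rhs"]) {                      # swing
        p0 <- pivot_about(toe_pv, toe_l, pattern$phi_max)
        heel_pv <- c(ankle_flat["R1"] + heel_l[1], 0)
        p1 <- pivot_about(heel_pv, heel_l, pattern$phi_land)
        u <- .s5((t - fr["rto"]) / (fr["rhs"] - fr["rto"]))
        uz <- (t - fr["rto"]) / (fr["rhs"] - fr["rto"])
        p <- p0 + u * (p1 - p0)
        p[2] <- p[2] + pattern$clearance * sin(pi * uz)^2
        return(p)
      }
      if (t <= fr["rts"]) {                      # heel rollover to flat
        heel_pv <- c(ankle_flat["R1"] + heel_l[1], 0)
        phi <- ramp(fr["rhs"], fr["rts"], pattern$phi_land, 0)
        return(pivot_about(heel_pv, heel_l, phi))
      }
      return(flat(ankle_flat["R1"]))
    } else {
      toe_pv <- c(ankle_flat["Lprev"] + toe_l[1], 0)
      if (t <= fr["lhs"]) {                      # swing from lift-off pose
        p0 <- pivot_about(toe_pv, toe_l, pattern$phi_max)
        heel_pv <- c(ankle_flat["L1"] + heel_l[1], 0)
        p1 <- pivot_about(heel_pv, heel_l, pattern$phi_land)
        u <- .s5(t / fr["lhs"])
        uz <- t / fr["lhs"]
        p <- p0 + u * (p1 - p0)
        p[2] <- p[2] + pattern$clearance * sin(pi * uz)^2
        return(p)
      }
      if (t <= fr["lts"]) {                      # heel rollover
        heel_pv <- c(ankle_flat["L1"] + heel_l[1], 0)
        phi <- ramp(fr["lhs"], fr["lts"], pattern$phi_land, 0)
        return(pivot_about(heel_pv, heel_l, phi))
      }
      if (t <= fr["lho"]) return(flat(ankle_flat["L1"]))
      # heel rise until the stride ends at left toe off
      toe_pv2 <- c(ankle_flat["L1"] + toe_l[1], 0)
      phi <- ramp(fr["lho"], T, 0, pattern$phi_max)
      return(pivot_about(toe_pv2, toe_l, phi))
    }
  }

  # pelvis lead: the COM passes the support ankle early in single support,
  # keeping the CoP demanded by the pattern inside the support polygon for
  # most of the stride
  x_pelvis <- function(t) vbar * (t - pattern$pelvis_lead * T)

  times <- seq(0, T, by = dt)
  if (times[length(times)] < T - 1e-12) times <- c(times, T)
  Q <- matrix(0, length(times), model$n_dof)
  for (i in seq_along(times)) {
    t <- times[i]
    hip <- c(unname(x_pelvis(t)), z_hip)
    q <- numeric(model$n_dof)
    q[1] <- hip[1]; q[2] <- hip[2]; q[3] <- 0
    for (side in c("left", "right")) {
      fp <- foot_pose(t, side)
      th <- .leg_ik(hip, fp[1:2], Lt, Ls)
      qh <- -th["theta_t"]
      qk <- th["theta_t"] - th["theta_s"]
      qa <- fp[3] + th["theta_s"]
      if (side == "left") q[4:6] <- c(qh, qk, qa) else q[7:9] <- c(qh, qk, qa)
    }
    Q[i, ] <- q
  }
  V <- .fd_rows(Q, times)
  A <- .fd_rows(V, times)
  list(times = times, q = Q, v = V, a = A, event_times = fr, T = T,
       pattern = pattern)
}

## central finite differences along rows (one-sided at the ends)
.fd_rows <- function(M, t) {
  n <- nrow(M); D <- M
  D[1, ] <- (M[2, ] - M[1, ]) / (t[2] - t[1])
  D[n, ] <- (M[n, ] - M[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2)
    D[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) /
      (t[3:n] - t[1:(n - 2)])
  D
}

## constrained inverse dynamics at one sample: least-squares actuated
## torques (+ contact forces) reproducing the acceleration under the
## active contacts; exact when the phase is (over)actuated
inverse_dynamics_contact <- function(model, q, v, a, contacts,
                                     method = c("min_norm", "basic")) {
  method <- match.arg(method)
  cache <- fk_cache(model, q, v)
  H <- crba(model, q, cache)
  C <- nonlinear_effects(model, q, v, cache)
  rhs <- as.numeric(H %*% a) + C
  B <- matrix(0, model$n_dof, model$n_act)
  B[cbind(model$actuated, seq_len(model$n_act))] <- 1
  if (!is.null(contacts) && nrow(contacts) > 0) {
    ck <- contact_kinematics(model, q, v = NULL, contacts, cache = cache)
    keep <- reduce_contact_rows(ck$G, contacts, ck$dims)
    M <- cbind(B, t(ck$G[keep, , drop = FALSE]))
  } else M <- B
  if (method == "min_norm") {
    # minimum-norm least-squares solution (SVD pseudo-inverse): bounded and
    # symmetric also when the phase is statically indeterminate
    sv <- svd(M)
    kp <- sv$d > 1e-10 * sv$d[1]
    sol <- as.numeric(sv$v[, kp, drop = FALSE] %*%
                        ((t(sv$u[, kp, drop = FALSE]) %*% rhs) / sv$d[kp]))
  } else {
    # deterministic basic solution of the (possibly redundant) system
    sol <- qr.coef(qr(M), rhs)
    sol[is.na(sol)] <- 0
  }
  list(tau = sol[seq_len(model$n_act)],
       lambda = sol[-seq_len(model$n_act)],
       residual = max(abs(M %*% sol - rhs)))
}

## piecewise-linear control interpolator over node times
pwl_control <- function(node_times, node_values) {
  force(node_times); force(node_values)
  function(t) {
    apply(node_values, 2, function(col)
      stats::approx(node_times, col, xout = t, rule = 2)$y)
  }
}

#' Hybrid scheduled simulation of a multibody walker
#'
#' Integrates the constrained dynamics phase by phase along a
#' [build_phase_schedule()]: within each phase the scheduled contact set is
#' enforced (anchored where the points are when the phase starts), and at
#' touch-down transitions the inelastic [impact_map()] resets the
#' velocities. Controls are per-phase piecewise-linear torque profiles or
#' an arbitrary `function(t, q, v)`.
#'
#' @param model a `multibody_model`.
#' @param controls either a list with one element per phase, each
#'   `list(times =, values =)` (node times and an `n_nodes x n_act` value
#'   matrix), or a single `function(t, q, v) -> tau`.
#' @param x0 initial state `c(q, v)` at the schedule start.
#' @param schedule a `phase_schedule`.
#' @param h integrator step (s).
#' @param fall_z if the pelvis height drops below this, the simulation
#'   stops early and the fixture is flagged (`fallen = TRUE`).
#' @return An object of class `walker_sim`: list with `times`, `q`, `v`,
#'   `u` (applied torques per sample), `forces` (per-point vertical force
#'   matrix), `phase` (phase index per sample), `impacts` (per transition:
#'   time, energy loss), `fallen`.
#' @export
simulate_walker <- function(model, controls, x0, schedule, h = 0.005,
                            fall_z = 0.3, project = TRUE) {
  contacts_l <- attr(schedule, "contacts")
  trans <- attr(schedule, "transitions")
  n <- model$n_dof
  x <- x0
  out_t <- c(); out_q <- NULL; out_v <- NULL; out_u <- NULL
  out_f <- NULL; out_ph <- c()
  impacts <- data.frame(time = numeric(0), energy_loss = numeric(0))
  fallen <- FALSE
  fids <- model$contacts$id
  for (i in seq_len(nrow(schedule))) {
    s <- state_unpack(model, x)
    cs <- contact_set(model, contacts_l[[i]], s$q)
    # touch-down into this phase: apply the impact map with the new set
    ti <- which(trans$after_phase == i)
    if (length(ti) == 1) {
      im <- impact_map(model, s$q, s$v, cs)
      x <- state_pack(s$q, im$v_plus)
      impacts <- rbind(impacts, data.frame(time = schedule$t_start[i],
                                           energy_loss = im$energy_loss))
    }
    tau_fun <- if (is.function(controls)) controls else {
      ui <- controls[[i]]
      uf <- pwl_control(ui$times, ui$values)
      function(t) uf(t)
    }
    ph <- integrate_phase(model, x, tau_fun, cs, schedule$t_start[i],
                          schedule$t_end[i], h = h, record_forces = TRUE,
                          project = project)
    fmat <- t(vapply(ph$forces, function(f) {
      out <- stats::setNames(numeric(length(fids)), fids)
      if (nrow(f) > 0) out[rownames(f)] <- f[, 3]
      out
    }, numeric(length(fids))))
    out_t <- c(out_t, ph$times)
    out_q <- rbind(out_q, ph$q)
    out_v <- rbind(out_v, ph$v)
    out_u <- rbind(out_u, t(vapply(seq_along(ph$times), function(k)
      as.numeric(eval_tau(tau_fun, ph$times[k], ph$q[k, ],
                          ph$v[k, ]))[seq_len(model$n_act)],
      numeric(model$n_act))))
    out_f <- rbind(out_f, fmat)
    out_ph <- c(out_ph, rep(i, length(ph$times)))
    x <- state_pack(ph$q[nrow(ph$q), ], ph$v[nrow(ph$v), ])
    if (state_unpack(model, x)$q[2] < fall_z) { fallen <- TRUE; break }
  }
  structure(list(times = out_t, q = out_q, v = out_v, u = out_u,
                 forces = out_f, phase = out_ph, impacts = impacts,
                 fallen = fallen, schedule = schedule),
            class = "walker_sim")
}

#' Synthesize marker trajectories from a joint trajectory
#'
#' Forward-kinematics positions of the marker set's virtual markers plus
#' optional seeded isotropic Gaussian noise. Deterministic for a fixed
#' seed; the global RNG state is left untouched.
#'
#' @param model a `multibody_model`.
#' @param times sample times.
#' @param q matrix of configurations (rows = samples).
#' @param mset a [marker_set()].
#' @param noise_sigma marker noise SD (m) per axis.
#' @param seed integer seed for the noise.
#' @return marker data list (`times`, `markers` array, `valid`) as consumed
#'   by [fit_trajectory()].
#' @export
synthesize_markers <- function(model, times, q, mset, noise_sigma = 0,
                               seed = 1L) {
  q <- as.matrix(q)
  n <- length(times); m <- nrow(mset)
  bodies <- model$seg_body[mset$segment]
  offs <- as.matrix(mset[, c("x", "y", "z")])
  for (k in seq_len(m)) {
    at <- model$seg_attach[[mset$segment[k]]]
    offs[k, ] <- x_point_inv(at$X, offs[k, ])
  }
  arr <- array(NA_real_, c(n, m, 3),
               dimnames = list(NULL, mset$name, c("x", "y", "z")))
  for (i in seq_len(n)) {
    cache <- fk_cache(model, q[i, ])
    for (k in seq_len(m))
      arr[i, k, ] <- body_point_world(cache, bodies[k], offs[k, ])
  }
  if (noise_sigma > 0) {
    arr <- arr + .with_seed(seed, array(stats::rnorm(n * m * 3, 0,
                                                     noise_sigma),
                                        c(n, m, 3)))
  }
  list(times = times, markers = arr,
       valid = matrix(TRUE, n, m, dimnames = list(NULL, mset$name)))
}

## evaluate an expression under a temporary RNG seed, restoring the global
## RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate the planar one-stride walking fixture
#'
#' Runs the three-stage pipeline described above on the planar 7-segment
#' walker and packages ground truth plus synthesized markers. The torques
#' driving the ground-truth simulation are exactly piecewise linear on the
#' per-phase node grid.
#'
#' @param anthro subject (default: a 1.75 m / 72 kg male).
#' @param pattern a [stride_pattern()].
#' @param node_spacing approximate spacing of the control nodes (s); each
#'   phase gets at least two nodes.
#' @param h integrator step (s), shared by the fixture and downstream
#'   reconstruction tests.
#' @param noise_sigma marker noise SD (m).
#' @param seed noise seed.
#' @return An object of class `walker_fixture`: list with `model`, `sim`
#'   (the ground-truth `walker_sim`), `controls` (per-phase PWL torques),
#'   `schedule`, `events`, `markers`, `mset`, `reference_kinematics`.
#' @export
planar_stride_fixture <- function(anthro = NULL, pattern = stride_pattern(),
                                  node_spacing = 0.02, h = 0.005,
                                  noise_sigma = 0, seed = 1L,
                                  id_method = NULL) {
  if (is.null(anthro)) anthro <- subject_anthropometry("male", 72, 1.75)
  segs <- de_leva_parameters(anthro)
  model <- build_planar_walker(segs)
  ref <- planar_stride_reference(model, pattern)
  fr <- ref$event_times; T <- ref$T
  events <- gait_events(
    left = list(heel_strike = fr[["lhs"]], toe_strike = fr[["lts"]],
                toe_off = c(0, T), heel_off = fr[["lho"]]),
    right = list(heel_strike = fr[["rhs"]], toe_strike = fr[["rts"]],
                 toe_off = fr[["rto"]], heel_off = fr[["rho"]]),
    validate = FALSE)
  schedule <- build_phase_schedule(events)

  # stage 2: scheduled inverse dynamics sampled on the control node grid
  contacts_l <- attr(schedule, "contacts")
  # toe-only single-support slivers are underactuated: no torque profile
  # reproduces the pattern there, so the previous torque is held constant
  toe_only <- vapply(contacts_l, function(ids)
    length(ids) == 2 && all(grepl("hallux|meta5", ids)), TRUE)
  # actuation-redundancy resolution per phase: minimum-norm torques where
  # the rollout tolerates them, the deterministic basic solution in the
  # flat+toe double-support phases whose internal loading stabilizes the
  # open-loop stride
  if (is.null(id_method)) {
    id_method <- rep("min_norm", nrow(schedule))
    flat_toe <- vapply(contacts_l, function(ids) length(ids) == 5, TRUE)
    id_method[flat_toe] <- "basic"
  }
  if (length(id_method) == 1) id_method <- rep(id_method, nrow(schedule))
  controls <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    dur <- schedule$t_end[i] - schedule$t_start[i]
    nt <- seq(schedule$t_start[i], schedule$t_end[i],
              length.out = max(2L, ceiling(dur / node_spacing) + 1L))
    cs <- contact_set(model, contacts_l[[i]],
                      ref$q[which.min(abs(ref$times - nt[1])), ])
    vals <- t(vapply(nt, function(t) {
      j <- which.min(abs(ref$times - t))
      inverse_dynamics_contact(model, ref$q[j, ], ref$v[j, ], ref$a[j, ],
                               cs, method = if (length(id_method) > 1)
                                 id_method[i] else id_method)$tau
    }, numeric(model$n_act)))
    if (toe_only[i] && i > 1) {
      prev <- controls[[i - 1]]$values
      vals <- matrix(prev[nrow(prev), ], nrow(vals), ncol(vals),
                     byrow = TRUE)
    }
    controls[[i]] <- list(times = nt, values = vals)
  }

  # stage 3: open-loop hybrid re-simulation = ground truth. The rollout
  # drifts from the kinematic pattern over the stride (the open-loop
  # walking dynamics are unstable and the toe-pivot slivers are
  # underactuated), but it is exactly consistent with the piecewise-linear
  # torques, which is what downstream reconstruction tests require.
  # projection-free, like the downstream reconstruction transcription: the
  # scheduled phases are short enough that acceleration-level constraint
  # enforcement keeps the contact drift far below the 1e-6 consistency
  # tolerance, and the fixture stays exactly representable by the
  # multiple-shooting reconstruction
  x0 <- state_pack(ref$q[1, ], ref$v[1, ])
  sim <- simulate_walker(model, controls, x0, schedule, h = h,
                         project = FALSE)
  if (sim$fallen)
    warning("synthetic walker fell during re-simulation; fixture truncated")

  mset <- default_marker_set(model)
  # drop duplicated phase-boundary samples (q is continuous across them)
  uid <- !duplicated(sim$times)
  markers <- synthesize_markers(model, sim$times[uid],
                                sim$q[uid, , drop = FALSE], mset,
                                noise_sigma = noise_sigma, seed = seed)
  structure(list(model = model, sim = sim, controls = controls,
                 schedule = schedule, events = events, markers = markers,
                 mset = mset, reference_kinematics = ref,
                 anthro = anthro, noise_sigma = noise_sigma, seed = seed),
            class = "walker_fixture")
}

## assemble per-phase PWL controls into one function of time (the later
## phase wins at shared boundaries)
.global_pwl <- function(controls, schedule) {
  funs <- lapply(controls, function(ci) pwl_control(ci$times, ci$values))
  starts <- schedule$t_start
  function(t) {
    i <- max(1L, findInterval(t + 1e-12, starts))
    funs[[min(i, length(funs))]](t)
  }
}

#' @export
print.walker_fixture <- function(x, ...) {
  cat(sprintf(paste0("Planar stride fixture: %d samples over %.2f s, ",
                     "%d-DoF walker, %d phases\n"),
              length(x$sim$times), diff(range(x$sim$times)),
              x$model$n_dof, nrow(x$schedule)))
  cat(sprintf("  marker noise sigma: %g m (seed %d); fallen: %s\n",
              x$noise_sigma, x$seed, x$sim$fallen))
  invisible(x)
}
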