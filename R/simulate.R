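# Forward integration of the constrained dynamics: fixed-step RK4 with
# post-step projection onto the contact constraint manifold (drift control),
# and bisection-based event location for hybrid simulation.

state_pack <- function(q, v) c(q, v)
state_unpack <- function(model, x) {
  n <- model$n_dof
  list(q = x[1:n], v = x[n + 1:n])
}

## evaluate a control law: plain torque profiles take (t), feedback
## controllers take (t, q, v)
eval_tau <- function(tau_fun, t, q, v) {
  if (length(formals(tau_fun)) >= 3) tau_fun(t, q, v) else tau_fun(t)
}

## right-hand side of the phase ODE xdot = f(t, x) under a fixed contact set
phase_rhs <- function(model, t, x, tau_fun, contacts) {
  s <- state_unpack(model, x)
  dyn <- constrained_forward_dynamics(model, s$q, s$v,
                                      eval_tau(tau_fun, t, s$q, s$v),
                                      contacts, want_forces = FALSE)
  c(s$v, dyn$a)
}

rk4_step <- function(model, t, x, h, tau_fun, contacts) {
  k1 <- phase_rhs(model, t, x, tau_fun, contacts)
  k2 <- phase_rhs(model, t + h / 2, x + h / 2 * k1, tau_fun, contacts)
  k3 <- phase_rhs(model, t + h / 2, x + h / 2 * k2, tau_fun, contacts)
  k4 <- phase_rhs(model, t + h, x + h * k3, tau_fun, contacts)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Integrate one contact phase
#'
#' Fixed-step RK4 integration of the constrained dynamics under a constant
#' contact set, with least-norm projection of (q, v) back onto the contact
#' constraint manifold after every step.
#'
#' @param model a `multibody_model`.
#' @param x0 initial state `c(q, v)`.
#' @param tau_fun function of time returning actuated torques (length
#'   `n_act`) or generalized forces (length `n_dof`).
#' @param contacts a [contact_set()] (may be empty).
#' @param t0,t1 phase start and end times (s).
#' @param h nominal step size (s); the actual step divides `t1 - t0` evenly.
#' @param record_forces if `TRUE`, contact forces are evaluated and stored at
#'   every node.
#' @param project logical; apply constraint projection after each step.
#' @return list with `times`, matrices `q`, `v` (rows = nodes) and, when
#'   requested, `forces` (list of per-point force matrices per node).
#' @export
integrate_phase <- function(model, x0, tau_fun, contacts, t0, t1, h = 0.005,
                            record_forces = FALSE, project = TRUE) {
  nsteps <- max(1L, ceiling((t1 - t0) / h - 1e-12))
  hh <- (t1 - t0) / nsteps
  n <- model$n_dof
  times <- t0 + hh * (0:nsteps)
  Q <- matrix(0, nsteps + 1, n); V <- matrix(0, nsteps + 1, n)
  forces <- if (record_forces) vector("list", nsteps + 1) else NULL
  x <- x0
  s <- state_unpack(model, x)
  Q[1, ] <- s$q; V[1, ] <- s$v
  if (record_forces)
    forces[[1]] <- .phase_forces(model, s$q, s$v,
                                 eval_tau(tau_fun, t0, s$q, s$v), contacts)
  for (k in seq_len(nsteps)) {
    x <- rk4_step(model, times[k], x, hh, tau_fun, contacts)
    if (project && !is.null(contacts) && nrow(contacts) > 0) {
      s <- state_unpack(model, x)
      pr <- project_state(model, s$q, s$v, contacts)
      x <- state_pack(pr$q, pr$v)
    }
    s <- state_unpack(model, x)
    Q[k + 1, ] <- s$q; V[k + 1, ] <- s$v
    if (record_forces)
      forces[[k + 1]] <- .phase_forces(model, s$q, s$v,
                                       eval_tau(tau_fun, times[k + 1], s$q,
                                                s$v), contacts)
  }
  list(times = times, q = Q, v = V, forces = forces)
}

.phase_forces <- function(model, q, v, tau, contacts) {
  if (is.null(contacts) || nrow(contacts) == 0)
    return(matrix(0, 0, 3))
  dyn <- constrained_forward_dynamics(model, q, v, tau, contacts)
  ck <- contact_kinematics(model, q, v = NULL, contacts)
  structure(dyn$forces, points = ck$pos)
}

#' Integrate until a scalar event function crosses zero
#'
#' Steps the phase dynamics until `event_fun(t, q, v)` changes sign from
#' positive to non-positive, then locates the crossing by bisection on the
#' step. Used to detect touch-down events (event = height of an approaching
#' contact point).
#'
#' @inheritParams integrate_phase
#' @param event_fun function `(t, q, v) -> numeric`; the event fires at the
#'   first downward zero crossing.
#' @param t_max give up after this time.
#' @param tol time tolerance of the bisection (s).
#' @return list as [integrate_phase()] plus `event_time` (or `NA` if the
#'   event did not fire) and final `x`.
#' @export
integrate_until_event <- function(model, x0, tau_fun, contacts, event_fun,
                                  t0, t_max, h = 0.005, tol = 1e-10) {
  x <- x0; t <- t0
  s <- state_unpack(model, x)
  times <- t; Q <- matrix(s$q, 1); V <- matrix(s$v, 1)
  g_prev <- event_fun(t, s$q, s$v)
  event_time <- NA_real_
  while (t < t_max - 1e-12) {
    hh <- min(h, t_max - t)
    x_new <- rk4_step(model, t, x, hh, tau_fun, contacts)
    if (!is.null(contacts) && nrow(contacts) > 0) {
      sn <- state_unpack(model, x_new)
      pr <- project_state(model, sn$q, sn$v, contacts)
      x_new <- state_pack(pr$q, pr$v)
    }
    sn <- state_unpack(model, x_new)
    g_new <- event_fun(t + hh, sn$q, sn$v)
    if (g_prev > 0 && g_new <= 0) {
      lo <- 0; hi <- hh; x_lo <- x
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        x_mid <- rk4_step(model, t, x, mid, tau_fun, contacts)
        sm <- state_unpack(model, x_mid)
        if (event_fun(t + mid, sm$q, sm$v) > 0) lo <- mid else hi <- mid
      }
      x <- rk4_step(model, t, x, hi, tau_fun, contacts)
      t <- t + hi
      s <- state_unpack(model, x)
      times <- c(times, t); Q <- rbind(Q, s$q); V <- rbind(V, s$v)
      event_time <- t
      break
    }
    x <- x_new; t <- t + hh; g_prev <- g_new
    times <- c(times, t); Q <- rbind(Q, sn$q); V <- rbind(V, sn$v)
  }
  list(times = times, q = Q, v = V, event_time = event_time, x = x)
}
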