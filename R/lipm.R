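# Closed-form linear-inverted-pendulum (LIPM) walking.
#
# Within a support phase with the CoP fixed at c, each horizontal COM
# coordinate follows
#   r(t) = c + (r0 - c) cosh(w0 t) + (v0 / w0) sinh(w0 t),
# with eigenfrequency w0 = sqrt(g / z0). The orbital energy
#   E = v^2 / 2 - w0^2 (r - c)^2 / 2
# is conserved along each phase. Steps are instantaneous support exchanges
# (optionally a finite double-support CoP transfer), so the COM velocity is
# continuous across steps and only the CoP jumps.

#' Specification of a synthetic LIPM gait
#'
#' @param com_height constant pendulum height z0 (m).
#' @param step_length forward distance between successive foot placements (m).
#' @param step_width lateral distance between left and right foot lines (m).
#' @param step_time single-support duration per step (s).
#' @param n_steps number of steps (>= 2).
#' @param foot_placement_mode `"fixed_offsets"` (periodic steady-state gait;
#'   each foot lands at a fixed offset from the Instantaneous Capture Point,
#'   the offset implied by the periodic solution) or `"on_icap"` (after one
#'   periodic step the next foot is placed exactly on the COM-based ICaP and
#'   held, so the pendulum is captured and comes to rest).
#' @param leg_length pendulum/normalization length (m); default `com_height`.
#' @param foot_length footprint length used for synthetic footprints (m).
#' @param double_support optional finite double-support duration (s) during
#'   which the CoP transfers linearly to the new foot; default 0
#'   (instantaneous exchange).
#' @param dt sample spacing of the returned trajectory (s).
#' @param capture_hold duration the capturing support is held in
#'   `"on_icap"` mode (s).
#' @param seed integer seed (reserved for optional noise; the nominal
#'   trajectories are deterministic).
#' @return A `lipm_gait_spec` list.
#' @export
lipm_gait_spec <- function(com_height = 0.9, step_length = 0.6,
                           step_width = 0.2, step_time = 0.55, n_steps = 10,
                           foot_placement_mode = c("fixed_offsets", "on_icap"),
                           leg_length = com_height, foot_length = 0.25,
                           double_support = 0, dt = 0.005,
                           capture_hold = 8, seed = 1L) {
  foot_placement_mode <- match.arg(foot_placement_mode)
  stopifnot(com_height > 0, step_length > 0, step_width > 0, step_time > 0,
            n_steps >= 2, leg_length > 0, dt > 0, double_support >= 0)
  if (sqrt((step_length / 2)^2 + com_height^2) > 1.15 * leg_length)
    stop("no periodic solution: step_length too long for the given ",
         "com_height/leg_length (required leg extension exceeds the leg)")
  structure(list(com_height = com_height, step_length = step_length,
                 step_width = step_width, step_time = step_time,
                 n_steps = as.integer(n_steps),
                 foot_placement_mode = foot_placement_mode,
                 leg_length = leg_length, foot_length = foot_length,
                 double_support = double_support, dt = dt,
                 capture_hold = capture_hold, seed = as.integer(seed)),
            class = "lipm_gait_spec")
}

## periodic single-support initial conditions for (S, W, T, w0): state at a
## support exchange, relative to the new support foot
.lipm_periodic_ic <- function(S, W, T, w0) {
  list(xi0 = -S / 2,
       xid0 = (S / 2) * w0 / tanh(w0 * T / 2),
       eta0 = W / 2,                       # distance to the support foot line
       etad0 = -(W / 2) * w0 * tanh(w0 * T / 2))
}

#' Simulate a closed-form LIPM gait
#'
#' Generates the piecewise-analytic COM trajectory, CoP sequence, gait
#' events and synthetic footprints of a periodic LIPM walk (see
#' [lipm_gait_spec()]). The first support foot is the right one, so the
#' walk emulates a stride that begins with a left-foot swing. Support
#' exchanges emit a heel-strike event for the landing side and a toe-off
#' event for the lifting side; trajectory samples are duplicated at the
#' exchange instants so both the pre- and post-exchange CoP are represented.
#'
#' @param spec a [lipm_gait_spec()].
#' @return An object of class `lipm_gait`: list with `traj` (a
#'   `ground_ref_traj`), `events` (a `gait_events`), `footprints` (per
#'   heel strike), `cop_sequence` and `spec`.
#' @export
simulate_lipm_gait <- function(spec) {
  stopifnot(inherits(spec, "lipm_gait_spec"))
  w0 <- sqrt(9.81 / spec$com_height)
  S <- spec$step_length; W <- spec$step_width; T <- spec$step_time
  ic <- .lipm_periodic_ic(S, W, T, w0)

  side <- "right"                       # first support
  foot <- c(0, -W / 2)                  # CoP of first support (heel point)
  r <- foot + c(ic$xi0, ic$eta0)
  v <- c(ic$xid0, ic$etad0)

  times <- c(); R <- NULL; V <- NULL; COP <- NULL
  hs_t <- list(left = numeric(0), right = numeric(0))
  to_t <- list(left = numeric(0), right = numeric(0))
  footprints <- list()
  cop_seq <- data.frame(side = character(0), t = numeric(0),
                        x = numeric(0), y = numeric(0))
  t_now <- 0
  captured <- FALSE

  sample_phase <- function(r0, v0, c_, t0, dur) {
    tt <- seq(0, dur, by = spec$dt)
    if (tt[length(tt)] < dur - 1e-12) tt <- c(tt, dur)
    # exponential-mode form r = c + A e^{w0 t} + B e^{-w0 t}: free of the
    # cosh/sinh cancellation when the growing mode is (near) zero, as it is
    # exactly for a capturing step
    ep <- exp(w0 * tt); em <- exp(-w0 * tt)
    A <- ((r0 - c_) + v0 / w0) / 2
    B <- ((r0 - c_) - v0 / w0) / 2
    x <- c_[1] + A[1] * ep + B[1] * em
    y <- c_[2] + A[2] * ep + B[2] * em
    vx <- w0 * (A[1] * ep - B[1] * em)
    vy <- w0 * (A[2] * ep - B[2] * em)
    list(t = t0 + tt, r = cbind(x, y), v = cbind(vx, vy))
  }

  for (k in seq_len(spec$n_steps)) {
    dur <- if (captured) spec$capture_hold else T
    ph <- sample_phase(r, v, foot, t_now, dur)
    times <- c(times, ph$t)
    R <- rbind(R, ph$r); V <- rbind(V, ph$v)
    COP <- rbind(COP, matrix(foot, nrow(ph$r), 2, byrow = TRUE))
    cop_seq <- rbind(cop_seq, data.frame(side = side, t = t_now,
                                         x = foot[1], y = foot[2]))
    np <- nrow(ph$r)
    r <- ph$r[np, ]; v <- ph$v[np, ]
    t_now <- t_now + dur
    if (captured || k == spec$n_steps) break

    # support exchange: place the next foot
    new_side <- if (side == "left") "right" else "left"
    if (spec$foot_placement_mode == "on_icap" && k >= 1) {
      new_foot <- r + v / w0               # COM-based ICaP
      captured <- TRUE
    } else {
      # periodic placement: the landing foot restores the periodic IC
      # (eta0 is signed: + for a right support, - for a left support)
      new_foot <- c(r[1] - ic$xi0,
                    r[2] - ic$eta0 * (if (new_side == "right") 1 else -1))
    }
    hs_t[[new_side]] <- c(hs_t[[new_side]], t_now)
    to_t[[side]] <- c(to_t[[side]], t_now)
    footprints[[length(footprints) + 1]] <-
      .lipm_footprint(new_side, new_foot, t_now, spec$foot_length)
    side <- new_side; foot <- new_foot
  }

  events <- gait_events(
    left = list(heel_strike = hs_t$left, toe_strike = numeric(0),
                toe_off = to_t$left, heel_off = numeric(0)),
    right = list(heel_strike = hs_t$right, toe_strike = numeric(0),
                 toe_off = to_t$right, heel_off = numeric(0)),
    validate = FALSE)

  traj <- ground_ref_traj(times = times,
                          r_com = cbind(R, spec$com_height),
                          rdot_com = cbind(V, 0),
                          r_cop = COP,
                          com_height = rep(spec$com_height, length(times)),
                          leg_length = spec$leg_length)
  structure(list(traj = traj, events = events, footprints = footprints,
                 cop_sequence = cop_seq, omega0 = w0, spec = spec),
            class = "lipm_gait")
}

## synthetic footprint: the CoP of the LIPM support acts at the heel point;
## toes extend in the walking (+x) direction
.lipm_footprint <- function(side, heel_xy, t, foot_length) {
  s <- if (side == "left") 1 else -1
  list(side = side, time = t,
       heel = heel_xy,
       hallux = heel_xy + c(foot_length, -s * 0.10 * foot_length),
       meta5 = heel_xy + c(0.75 * foot_length, s * 0.18 * foot_length))
}

#' @export
print.lipm_gait <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(paste0("LIPM gait: %d steps, step %.2f m x %.2f m, %.2f s, ",
                     "z0 = %.2f m (mode: %s)\n"),
              sp$n_steps, sp$step_length, sp$step_width, sp$step_time,
              sp$com_height, sp$foot_placement_mode))
  cat(sprintf("  omega0 = %.4f 1/s, %d heel strikes\n", x$omega0,
              length(x$events$left$heel_strike) +
                length(x$events$right$heel_strike)))
  invisible(x)
}
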