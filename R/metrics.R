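# Stability benchmarks: Instantaneous Capture Point, normalized orbital
# energy, Residual Orbital Energy at heel strike, angular-momentum
# decomposition and foot-placement geometry.

#' Angular eigenfrequency of the linear inverted pendulum
#'
#' @param length pendulum length (m, > 0).
#' @param g gravitational acceleration (m/s^2).
#' @return omega0 = sqrt(g / length), in 1/s.
#' @export
angular_eigenfrequency <- function(length, g = 9.81) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop("pendulum length must be positive")
  sqrt(g / length)
}

#' Instantaneous Capture Point
#'
#' Ground point offset from a reference point by the horizontal COM
#' velocity divided by the pendulum eigenfrequency:
#' `r_icap = r_ref + rdot_com / omega0`. The reference point is either the
#' CoP (as-printed form) or the ground projection of the COM (the form used
#' by the capture-point literature; package default elsewhere).
#'
#' @param reference_point 2-vector (or n x 2 matrix) in the ground plane (m).
#' @param rdot_com 2-vector (or n x 2 matrix) of horizontal COM velocity
#'   (m/s).
#' @param omega0 eigenfrequency (1/s, > 0), scalar or length-n.
#' @return 2-vector or n x 2 matrix of ICaP positions (m).
#' @export
instantaneous_capture_point <- function(reference_point, rdot_com, omega0) {
  if (any(omega0 <= 0)) stop("omega0 must be positive")
  reference_point + rdot_com / omega0
}

#' Normalized orbital energy of the LIPM
#'
#' `E'_lip = |rdot'_com|^2 / 2 - |r'_com - r'_cop|^2 omega0^2 / 2`, using
#' the horizontal components of pre-normalized inputs (positions divided by
#' the normalization length, so velocities are in 1/s and the result in
#' 1/s^2). The COM velocity is assumed horizontal.
#'
#' @param r_com_n,r_cop_n normalized horizontal positions: 2-vectors or
#'   n x 2 matrices (dimensionless).
#' @param rdot_com_n normalized horizontal COM velocity (1/s).
#' @param omega0 eigenfrequency (1/s), scalar or length-n.
#' @return numeric scalar or length-n vector (1/s^2).
#' @export
normalized_orbital_energy <- function(r_com_n, r_cop_n, rdot_com_n, omega0) {
  if (is.matrix(rdot_com_n)) {
    0.5 * rowSums(rdot_com_n^2) -
      0.5 * rowSums((r_com_n - r_cop_n)^2) * omega0^2
  } else {
    0.5 * sum(rdot_com_n^2) - 0.5 * sum((r_com_n - r_cop_n)^2) * omega0^2
  }
}

#' Ground-plane reference trajectory
#'
#' Container for the time series the benchmarks consume: COM position and
#' velocity, CoP (valid during contact), COM height and the normalization
#' length.
#'
#' @param times strictly increasing sample times (s); ties are allowed only
#'   as duplicated boundary samples at support exchanges (pre/post CoP).
#' @param r_com n x 3 COM positions (m).
#' @param rdot_com n x 3 COM velocities (m/s).
#' @param r_cop n x 2 CoP positions (m; NA outside contact).
#' @param com_height length-n COM heights (m; defaults to `r_com[, 3]`).
#' @param leg_length normalization length (m).
#' @return An object of class `ground_ref_traj`.
#' @export
ground_ref_traj <- function(times, r_com, rdot_com, r_cop,
                            com_height = NULL, leg_length = NA_real_) {
  times <- as.numeric(times)
  r_com <- as.matrix(r_com); rdot_com <- as.matrix(rdot_com)
  r_cop <- as.matrix(r_cop)
  n <- length(times)
  stopifnot(nrow(r_com) == n, nrow(rdot_com) == n, nrow(r_cop) == n,
            ncol(r_com) == 3, ncol(rdot_com) == 3, ncol(r_cop) == 2)
  if (any(diff(times) < -1e-12)) stop("times must be non-decreasing")
  if (is.null(com_height)) com_height <- r_com[, 3]
  if (any(com_height <= 0, na.rm = TRUE)) stop("com_height must be positive")
  structure(list(times = times, r_com = r_com, rdot_com = rdot_com,
                 r_cop = r_cop, com_height = as.numeric(com_height),
                 leg_length = leg_length),
            class = "ground_ref_traj")
}

#' @export
print.ground_ref_traj <- function(x, ...) {
  cat(sprintf(paste0("Ground reference trajectory: %d samples over %.3f s, ",
                     "mean COM height %.3f m\n"),
              length(x$times), diff(range(x$times)), mean(x$com_height)))
  invisible(x)
}

#' ICaP trajectory over a ground reference trajectory
#'
#' @param traj a [ground_ref_traj()].
#' @param reference `"com"` (default): ICaP measured from the COM ground
#'   projection, which makes "CoP on the ICaP brings the pendulum to rest"
#'   an exact identity; or `"cop"`: the as-printed form based on the CoP.
#' @param omega_mode `"instantaneous"` (default): omega0 from the current
#'   COM height at each sample; or `"leg_length"`: constant omega0 from the
#'   normalization length.
#' @return n x 2 matrix of ICaP positions with attributes `reference` and
#'   `omega_mode`.
#' @export
icap_trajectory <- function(traj, reference = c("com", "cop"),
                            omega_mode = c("instantaneous", "leg_length")) {
  reference <- match.arg(reference)
  omega_mode <- match.arg(omega_mode)
  w0 <- .traj_omega0(traj, omega_mode)
  ref <- if (reference == "com") traj$r_com[, 1:2, drop = FALSE] else traj$r_cop
  out <- instantaneous_capture_point(ref, traj$rdot_com[, 1:2, drop = FALSE],
                                     w0)
  attr(out, "reference") <- reference
  attr(out, "omega_mode") <- omega_mode
  out
}

.traj_omega0 <- function(traj, omega_mode) {
  if (omega_mode == "instantaneous") angular_eigenfrequency(traj$com_height)
  else {
    if (!is.finite(traj$leg_length))
      stop("trajectory has no leg_length; cannot use omega_mode='leg_length'")
    angular_eigenfrequency(traj$leg_length)
  }
}

## index of the sample representing t+ (the post-impact side): the last
## sample with time <= t within tol, so duplicated boundary samples resolve
## to the post-exchange row
.post_index <- function(times, t, tol = 1e-9) {
  i <- which(times <= t + tol)
  if (length(i) == 0) return(NA_integer_)
  max(i)
}

#' Residual Orbital Energy at heel strikes
#'
#' Evaluates the normalized orbital energy right after each heel strike
#' (on the post-impact side of the transition: the CoP of the landing foot
#' and the post-impact COM velocity), normalized by the subject's leg
#' length. Returns per-event values, per-side means and the stride average.
#'
#' @param traj a [ground_ref_traj()].
#' @param events a [gait_events()] with heel-strike times.
#' @param leg_length normalization length (m); default: the trajectory's.
#' @param omega_mode see [icap_trajectory()]; `"instantaneous"` evaluates
#'   omega0 from the COM height at the event, `"leg_length"` uses the
#'   constant normalization length.
#' @return An object of class `orbital_energy_record`: data frame with
#'   columns `side`, `time`, `E_res` (1/s^2) plus attributes `omega_mode`,
#'   `leg_length`, `summary` (left/right/average).
#' @export
residual_orbital_energy <- function(traj, events, leg_length = NULL,
                                    omega_mode = c("instantaneous",
                                                   "leg_length")) {
  stopifnot(inherits(traj, "ground_ref_traj"), inherits(events, "gait_events"))
  omega_mode <- match.arg(omega_mode)
  l <- leg_length %||% traj$leg_length
  if (!is.finite(l) || l <= 0)
    stop("a positive leg_length is required for normalization")
  rows <- list()
  for (side in c("left", "right")) {
    for (t in events[[side]]$heel_strike) {
      i <- .post_index(traj$times, t)
      if (is.na(i) || t > traj$times[length(traj$times)] + 1e-9 ||
          t < traj$times[1] - 1e-9) {
        warning("heel strike at t = ", t, " outside trajectory span; skipped")
        next
      }
      if (any(!is.finite(traj$r_cop[i, ]))) {
        warning("no CoP at heel strike t = ", t, "; event skipped")
        next
      }
      w0 <- if (omega_mode == "instantaneous")
        angular_eigenfrequency(traj$com_height[i])
      else angular_eigenfrequency(l)
      e <- normalized_orbital_energy(traj$r_com[i, 1:2] / l,
                                     traj$r_cop[i, ] / l,
                                     traj$rdot_com[i, 1:2] / l, w0)
      rows[[length(rows) + 1]] <- data.frame(side = side, time = t, E_res = e)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(0), time = numeric(0), E_res = numeric(0))
  df <- df[order(df$time), , drop = FALSE]
  lm_ <- mean(df$E_res[df$side == "left"])
  rm_ <- mean(df$E_res[df$side == "right"])
  structure(df, omega_mode = omega_mode, leg_length = l,
            summary = c(left = lm_, right = rm_,
                        average = stride_average(lm_, rm_)),
            class = c("orbital_energy_record", "data.frame"))
}

#' Stride average of per-side heel-strike values
#'
#' The stride aggregate reported for the Residual Orbital Energy: the mean
#' of the left-heel-strike and right-heel-strike values.
#'
#' @param left,right per-side values (1/s^2).
#' @return `(left + right) / 2`.
#' @export
stride_average <- function(left, right) (left + right) / 2

#' @export
print.orbital_energy_record <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Residual orbital energy E'_res [1/s^2]\n")
  cat(sprintf("  Left HS   Right HS  Average\n  %.4f    %.4f    %.4f\n",
              s["left"], s["right"], s["average"]))
  cat(sprintf("  (%d events, omega mode: %s, leg length %.3f m)\n",
              nrow(x), attr(x, "omega_mode"), attr(x, "leg_length")))
  invisible(x)
}

## default upper/lower body split: the lower body is the pelvis and both
## legs; everything above the lumbo-sacral joint is upper body
default_body_split <- function(model, pelvis_in = c("lower", "upper")) {
  pelvis_in <- match.arg(pelvis_in)
  segs <- unique(names(model$seg_body))
  lower <- intersect(c("pelvis", "thigh_l", "shank_l", "foot_l",
                       "thigh_r", "shank_r", "foot_r"), segs)
  if (pelvis_in == "upper") lower <- setdiff(lower, "pelvis")
  list(lower = lower, upper = setdiff(segs, lower))
}

#' Decompose whole-body angular momentum into upper and lower body
#'
#' Computes, about the instantaneous whole-body COM, the angular momentum
#' of the upper body, the lower body and the full body at every sample, in
#' the three anatomical planes (frontal = x component, sagittal = y,
#' horizontal/transverse = z; a documented axis convention).
#'
#' @param model a `multibody_model`.
#' @param times sample times (s).
#' @param q,v matrices (rows = samples) of generalized positions/velocities.
#' @param split list with character vectors `upper` and `lower` forming a
#'   partition of the model's segments (default [default_body_split()]).
#' @return An object of class `am_decomposition`: list of `times` and an
#'   `n x 3 x 3` array `L` (dimensions: time, plane
#'   frontal/sagittal/horizontal, part upper/lower/full), kg m^2/s.
#' @export
decompose_angular_momentum <- function(model, times, q, v, split = NULL) {
  q <- as.matrix(q); v <- as.matrix(v)
  segs <- unique(names(model$seg_body))
  if (is.null(split)) split <- default_body_split(model)
  if (length(intersect(split$upper, split$lower)) > 0 ||
      !setequal(c(split$upper, split$lower), segs))
    stop("split must be a partition of the model's segments")
  n <- length(times)
  L <- array(0, c(n, 3, 3),
             dimnames = list(NULL, c("frontal", "sagittal", "horizontal"),
                             c("upper", "lower", "full")))
  for (i in seq_len(n)) {
    com <- com_state(model, q[i, ], v[i, ])$r_com
    up <- angular_momentum(model, q[i, ], v[i, ], split$upper, about = com)
    lo <- angular_momentum(model, q[i, ], v[i, ], split$lower, about = com)
    L[i, , "upper"] <- up
    L[i, , "lower"] <- lo
    L[i, , "full"] <- up + lo
  }
  structure(list(times = times, L = L, split = split),
            class = "am_decomposition")
}

#' @export
print.am_decomposition <- function(x, ...) {
  cat(sprintf("Angular-momentum decomposition: %d samples, %d upper / %d lower segments\n",
              length(x$times), length(x$split$upper), length(x$split$lower)))
  m <- apply(abs(x$L), 2:3, max)
  cat("  max |L| [kg m^2/s]:\n")
  print(round(m, 3))
  invisible(x)
}

#' @export
plot.am_decomposition <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (p in dimnames(x$L)[[2]]) {
    yl <- range(x$L[, p, ])
    graphics::plot(x$times, x$L[, p, "full"], type = "l", lwd = 2,
                   ylim = yl, xlab = "time [s]",
                   ylab = expression(L ~ "[kg m"^2 * "/s]"), main = p)
    graphics::lines(x$times, x$L[, p, "upper"], lty = 2)
    graphics::lines(x$times, x$L[, p, "lower"], lty = 3)
  }
  invisible(x)
}

#' Foot placement relative to the Instantaneous Capture Point
#'
#' For each heel strike, expresses the ICaP (and the COM ground projection)
#' at that instant in the landing foot's frame: origin at the heel, anterior
#' axis from the heel toward the forefoot mid-point, lateral axis to the
#' anatomical left of it. The `medial` column is side-aware (positive toward
#' the body midline); `lateral` is the raw left-positive component.
#'
#' @param traj a [ground_ref_traj()].
#' @param events a [gait_events()].
#' @param footprints list of per-heel-strike footprints: lists with `side`,
#'   `time`, and 2-vectors `heel`, `hallux`, `meta5` (ground positions, m).
#' @param reference,omega_mode passed to [icap_trajectory()].
#' @return An object of class `foot_placement_summary`: data frame with one
#'   row per matched heel strike (anterior/lateral/medial ICaP offsets and
#'   COM offsets, m).
#' @export
foot_placement_summary <- function(traj, events, footprints,
                                   reference = c("com", "cop"),
                                   omega_mode = c("instantaneous",
                                                  "leg_length")) {
  reference <- match.arg(reference)
  omega_mode <- match.arg(omega_mode)
  icap <- icap_trajectory(traj, reference, omega_mode)
  fp_side <- vapply(footprints, `[[`, "", "side")
  fp_time <- vapply(footprints, `[[`, 0, "time")
  rows <- list()
  for (side in c("left", "right")) {
    for (t in events[[side]]$heel_strike) {
      k <- which(fp_side == side & abs(fp_time - t) < 1e-6)
      if (length(k) == 0) {
        warning("no footprint for ", side, " heel strike at t = ", t,
                "; step skipped")
        next
      }
      fp <- footprints[[k[1]]]
      i <- .post_index(traj$times, t)
      if (is.na(i)) next
      fore <- (fp$hallux + fp$meta5) / 2
      a_hat <- fore - fp$heel
      a_hat <- a_hat / sqrt(sum(a_hat^2))
      l_hat <- c(-a_hat[2], a_hat[1])          # +90 deg: anatomical left
      s <- if (side == "left") -1 else 1        # medial = toward midline
      d_icap <- icap[i, ] - fp$heel
      d_com <- traj$r_com[i, 1:2] - fp$heel
      rows[[length(rows) + 1]] <- data.frame(
        side = side, time = t,
        anterior = sum(d_icap * a_hat), lateral = sum(d_icap * l_hat),
        medial = s * sum(d_icap * l_hat),
        com_anterior = sum(d_com * a_hat), com_lateral = sum(d_com * l_hat),
        com_medial = s * sum(d_com * l_hat))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(0), time = numeric(0), anterior = numeric(0),
               lateral = numeric(0), medial = numeric(0),
               com_anterior = numeric(0), com_lateral = numeric(0),
               com_medial = numeric(0))
  df <- df[order(df$time), , drop = FALSE]
  structure(df, reference = reference, omega_mode = omega_mode,
            class = c("foot_placement_summary", "data.frame"))
}

#' @export
print.foot_placement_summary <- function(x, ...) {
  cat(sprintf("Foot placement vs ICaP (%d steps, reference: %s)\n",
              nrow(x), attr(x, "reference")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
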