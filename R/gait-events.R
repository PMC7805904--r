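# Gait events and the stride phase schedule.

#' Gait events container
#'
#' Ordered event times per side: heel strike (heel gains contact), toe
#' strike (forefoot gains contact), toe off (all contact lost) and heel off
#' (heel leaves the ground while the forefoot stays). Heel off is not an
#' impact; it is carried because the stride phase schedule needs it to
#' delimit the toe-only support phases.
#'
#' @param left,right lists with numeric vectors `heel_strike`, `toe_strike`,
#'   `toe_off` and optionally `heel_off` (s).
#' @param validate check the per-side ordering heel strike < toe strike <
#'   next toe off.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left, right, validate = TRUE) {
  fill <- function(s) {
    for (nm in c("heel_strike", "toe_strike", "toe_off", "heel_off"))
      s[[nm]] <- sort(as.numeric(s[[nm]] %||% numeric(0)))
    s
  }
  left <- fill(left); right <- fill(right)
  ev <- structure(list(left = left, right = right), class = "gait_events")
  if (validate) {
    for (s in list(left, right)) {
      for (hs in s$heel_strike) {
        ts <- s$toe_strike[s$toe_strike > hs]
        to <- s$toe_off[s$toe_off > hs]
        if (length(ts) && length(to) && min(to) < min(ts))
          stop("gait event ordering violated: toe off before toe strike ",
               "after a heel strike at t = ", hs)
      }
    }
  }
  ev
}

#' @export
print.gait_events <- function(x, ...) {
  cat("Gait events (s)\n")
  for (s in c("left", "right")) {
    cat(sprintf("  %s: HS [%s] TS [%s] TO [%s]\n", s,
                paste(sprintf("%.3f", x[[s]]$heel_strike), collapse = ", "),
                paste(sprintf("%.3f", x[[s]]$toe_strike), collapse = ", "),
                paste(sprintf("%.3f", x[[s]]$toe_off), collapse = ", ")))
  }
  invisible(x)
}

## extract rising/falling threshold crossings from a logical contact signal
.rising <- function(t, on) t[which(diff(c(FALSE, on)) == 1)]
.falling <- function(t, on) t[which(diff(c(on, FALSE)) == -1 &
                                      c(on, FALSE)[-length(c(on, FALSE))])]

#' Detect gait events from contact forces or contact-point kinematics
#'
#' Force mode: `x` is a list with `times` and `forces`, an `n x k` matrix of
#' vertical contact-point forces with column names like `"left_heel"`;
#' events fire when per-point force crosses a threshold (default 2% of body
#' weight). Kinematic mode: `x` is a list with `times`, `model` and `q`
#' (matrix of configurations); a point is in contact when its height is
#' below `height_tol`.
#'
#' Per side: heel strike = heel force/contact rises; toe strike = forefoot
#' (hallux or meta5) rises; toe off = all points of the foot fall; heel off
#' = heel falls while the forefoot stays on.
#'
#' @param x input list (see above).
#' @param body_weight body weight in N (force mode).
#' @param force_frac force threshold as a fraction of body weight.
#' @param height_tol contact height threshold (m, kinematic mode).
#' @return A `gait_events` object (empty when nothing crosses).
#' @export
detect_gait_events <- function(x, body_weight = NULL, force_frac = 0.02,
                               height_tol = 0.005) {
  if (!is.null(x$forces)) {
    thr <- force_frac * (body_weight %||%
                           stop("body_weight required in force mode"))
    on <- x$forces > thr
  } else if (!is.null(x$model)) {
    model <- x$model
    ids <- model$contacts$id
    on <- matrix(FALSE, length(x$times), length(ids),
                 dimnames = list(NULL, ids))
    for (i in seq_along(x$times)) {
      cache <- fk_cache(model, x$q[i, ])
      for (k in seq_along(ids)) {
        r <- model$contacts[k, ]
        h <- body_point_world(cache, r$body, c(r$x, r$y, r$z))[3]
        on[i, k] <- h < height_tol
      }
    }
  } else stop("x must carry either $forces or $model")
  tt <- x$times
  side_events <- function(side) {
    heel <- on[, paste0(side, "_heel")]
    fore <- on[, paste0(side, "_hallux")] | on[, paste0(side, "_meta5")]
    any_on <- heel | fore
    list(heel_strike = .rising(tt, heel),
         toe_strike = .rising(tt, fore),
         toe_off = .falling(tt, any_on),
         heel_off = .falling(tt, heel))
  }
  if (!any(on)) {
    warning("no contact detected; returning empty events")
    empty <- list(heel_strike = numeric(0), toe_strike = numeric(0),
                  toe_off = numeric(0), heel_off = numeric(0))
    return(gait_events(empty, empty, validate = FALSE))
  }
  gait_events(side_events("left"), side_events("right"), validate = FALSE)
}

#' Build the 8-phase stride schedule from gait events
#'
#' A full stride beginning at left toe off is partitioned into 8 contact
#' phases separated by 7 interior boundaries, in the canonical order
#' right heel off, left heel strike, left toe strike, right toe off,
#' left heel off, right heel strike, right toe strike. The 4 touch-down
#' boundaries (the two heel strikes and two toe strikes) are transitions:
#' the generalized velocities jump there by the inelastic impact map.
#'
#' @param events a [gait_events()] covering one full stride that starts at a
#'   left toe off and ends at the next left toe off.
#' @param stride_start optional explicit start time (default: first left
#'   toe off).
#' @return An object of class `phase_schedule`: data frame with one row per
#'   phase (`phase`, `t_start`, `t_end`, `label`), attribute `contacts`
#'   (list of active contact-point ids per phase) and attribute
#'   `transitions` (data frame of touch-down events with gained contacts).
#' @export
build_phase_schedule <- function(events, stride_start = NULL) {
  stopifnot(inherits(events, "gait_events"))
  lto <- events$left$toe_off
  if (length(lto) < 2)
    stop("phase schedule: need two left toe-off events to span a stride")
  t0 <- stride_start %||% lto[1]
  T_end <- lto[lto > t0 + 1e-9][1]
  if (is.na(T_end))
    stop("phase schedule: no closing left toe off after stride start")
  pick <- function(v, lab) {
    v <- v[v > t0 + 1e-9 & v < T_end - 1e-9]
    if (length(v) == 0)
      stop("phase schedule: missing event in stride: ", lab)
    v[1]
  }
  b <- c(rho = pick(events$right$heel_off, "right heel off"),
         lhs = pick(events$left$heel_strike, "left heel strike"),
         lts = pick(events$left$toe_strike, "left toe strike"),
         rto = pick(events$right$toe_off, "right toe off"),
         lho = pick(events$left$heel_off, "left heel off"),
         rhs = pick(events$right$heel_strike, "right heel strike"),
         rts = pick(events$right$toe_strike, "right toe strike"))
  if (is.unsorted(b))
    stop("phase schedule: stride events out of canonical order (",
         paste(names(b), sprintf("%.3f", b), collapse = ", "), ")")
  tau <- c(t0, unname(b), T_end)
  lab <- c("R flat | L swing", "R toe | L swing", "R toe + L heel",
           "R toe + L flat", "L flat | R swing", "L toe | R swing",
           "L toe + R heel", "L toe + R flat")
  rfl <- c("right_heel", "right_hallux", "right_meta5")
  rtoe <- c("right_hallux", "right_meta5")
  lfl <- c("left_heel", "left_hallux", "left_meta5")
  ltoe <- c("left_hallux", "left_meta5")
  contacts <- list(rfl, rtoe, c(rtoe, "left_heel"), c(rtoe, lfl),
                   lfl, ltoe, c(ltoe, "right_heel"), c(ltoe, rfl))
  transitions <- data.frame(
    time = unname(b[c("lhs", "lts", "rhs", "rts")]),
    event = c("left_heel_strike", "left_toe_strike",
              "right_heel_strike", "right_toe_strike"),
    before_phase = c(2L, 3L, 6L, 7L), after_phase = c(3L, 4L, 7L, 8L),
    gained = I(list("left_heel", c("left_hallux", "left_meta5"),
                    "right_heel", c("right_hallux", "right_meta5")))
  )
  sched <- data.frame(phase = 1:8, t_start = tau[1:8], t_end = tau[2:9],
                      label = lab)
  structure(sched, contacts = contacts, transitions = transitions,
            class = c("phase_schedule", "data.frame"))
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("Stride phase schedule: %d phases, %d transitions, T = %.3f s\n",
              nrow(x), nrow(attr(x, "transitions")),
              x$t_end[nrow(x)] - x$t_start[1]))
  df <- as.data.frame(x)
  df$contacts <- vapply(attr(x, "contacts"), paste, "", collapse = "+")
  print(df, row.names = FALSE)
  invisible(x)
}

n_phases <- function(schedule) nrow(schedule)
n_transitions <- function(schedule) nrow(attr(schedule, "transitions"))
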