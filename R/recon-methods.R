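# Methods for the fitted reconstruction object and its independent
# verification.

#' @export
print.gait_recon <- function(x, ...) {
  cat("Gait reconstruction (multi-phase least-squares optimal control)\n")
  cat(sprintf("  %d phases over [%.3f, %.3f] s, %d DoF (%d actuated)\n",
              nrow(x$schedule), x$schedule$t_start[1],
              x$schedule$t_end[nrow(x$schedule)],
              x$model$n_dof, x$model$n_act))
  cat(sprintf("  objective: %.4e (tracking %.4e + regularization %.4e)\n",
              x$objective["total"], x$objective["tracking"],
              x$objective["regularization"]))
  cat(sprintf("  solver: %d iterations, converged: %s, |continuity| = %.2e\n",
              x$solver$iterations, x$solver$converged, x$constraint_norm))
  invisible(x)
}

#' @export
summary.gait_recon <- function(object, ...) {
  res <- residuals(object)
  per_dof <- sqrt(colMeans(res^2))
  names(per_dof) <- object$model$qnames
  out <- list(objective = object$objective,
              solver = object$solver,
              constraint_norm = object$constraint_norm,
              rms_tracking_per_dof = per_dof,
              torque_range = t(apply(object$u, 2, range)),
              n_frames = length(object$reference$times))
  class(out) <- "summary.gait_recon"
  out
}

#' @export
print.summary.gait_recon <- function(x, ...) {
  cat("Reconstruction summary\n")
  cat(sprintf("  frames tracked: %d; objective %.4e; converged: %s\n",
              x$n_frames, x$objective["total"], x$solver$converged))
  cat("  per-DoF RMS tracking residual [rad | m]:\n")
  print(round(x$rms_tracking_per_dof, 6))
  cat("  torque ranges [N m]:\n")
  print(round(x$torque_range, 2))
  invisible(x)
}

#' Control node values of a reconstruction
#'
#' @param object a `gait_recon`.
#' @param ... unused.
#' @return data frame with phase, node time and one column per actuated
#'   joint (N m).
#' @export
coef.gait_recon <- function(object, ...) {
  na <- object$model$n_act
  out <- do.call(rbind, lapply(seq_along(object$U), function(i) {
    df <- as.data.frame(object$U[[i]])
    names(df) <- object$model$qnames[object$model$actuated]
    cbind(phase = i, time = object$nodes[[i]], df)
  }))
  rownames(out) <- NULL
  out
}

#' @export
fitted.gait_recon <- function(object, ...) {
  t(vapply(object$reference$times, function(t) {
    hw <- .hermite_weights(object$times, t)
    k <- hw$k
    hw$w[1] * object$q[k, ] + hw$w[2] * object$v[k, ] +
      hw$w[3] * object$q[k + 1, ] + hw$w[4] * object$v[k + 1, ]
  }, numeric(object$model$n_dof)))
}

#' @export
residuals.gait_recon <- function(object, ...) {
  fitted(object) - object$reference$q
}

#' Evaluate a reconstruction at arbitrary times
#'
#' Linear interpolation of the reconstructed states and controls.
#'
#' @param object a `gait_recon`.
#' @param times numeric vector within the reconstructed span.
#' @param ... unused.
#' @return list with `times`, `q`, `v`, `u` matrices.
#' @export
predict.gait_recon <- function(object, times = object$reference$times, ...) {
  list(times = times,
       q = t(vapply(times, function(t)
         .interp_row(object$times, object$q, t), numeric(ncol(object$q)))),
       v = t(vapply(times, function(t)
         .interp_row(object$times, object$v, t), numeric(ncol(object$v)))),
       u = t(vapply(times, function(t)
         .interp_row(object$times, object$u, t), numeric(ncol(object$u)))))
}

#' @export
plot.gait_recon <- function(x, dofs = NULL, ...) {
  dofs <- dofs %||% seq_len(min(6, x$model$n_dof))
  op <- graphics::par(mfrow = c(length(dofs) + 1, 1),
                      mar = c(2.5, 4, 1, 0.5))
  on.exit(graphics::par(op))
  for (j in dofs) {
    graphics::plot(x$times, x$q[, j], type = "l", lwd = 2,
                   xlab = "", ylab = x$model$qnames[j])
    graphics::points(x$reference$times, x$reference$q[, j], pch = 20,
                     cex = 0.4, col = "grey40")
    graphics::abline(v = x$schedule$t_start[-1], lty = 3, col = "grey70")
  }
  graphics::matplot(x$times, x$u, type = "l", lty = 1,
                    xlab = "time [s]", ylab = "torque [N m]")
  invisible(x)
}

#' Independent verification of a reconstruction
#'
#' Re-integrates every phase from its initial state with the solved
#' controls and reports the worst state defect against the stored
#' trajectory, the transition-map residuals at the touch-downs (the
#' stored post-impact states against an independent [impact_map()]
#' evaluation of the stored pre-impact states), the minimum vertical
#' contact force (unilaterality), and any violations of configured
#' state/control bounds.
#'
#' @param result a `gait_recon`.
#' @param tolerances list with elements `defect`, `transition`
#'   (defaults 1e-4, 1e-6) used for the `ok` flags.
#' @param h_factor re-integration step as a fraction of the solver's step.
#'   The default 1 probes self-consistency; smaller values additionally
#'   probe the discretization, where phase-long open-loop re-integration
#'   of the unstable walking dynamics amplifies the step-size difference.
#' @return list of class `recon_check`.
#' @export
check_solution <- function(result, tolerances = list(), h_factor = 1) {
  tol <- utils::modifyList(list(defect = 1e-4, transition = 1e-6),
                           tolerances)
  model <- result$model
  schedule <- result$schedule
  contacts_l <- attr(schedule, "contacts")
  trans <- attr(schedule, "transitions")
  n <- model$n_dof
  max_defect <- 0
  ends <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    cs <- contact_set(model, contacts_l[[i]], result$x0[[i]][1:n])
    uf <- pwl_control(result$nodes[[i]], result$U[[i]])
    s <- integrate_phase(model, result$x0[[i]], function(t) uf(t), cs,
                         schedule$t_start[i], schedule$t_end[i],
                         h = result$config$h * h_factor, project = FALSE)
    # compare at the stored sample times of this phase
    idx <- which(result$phase == i)
    for (k in idx) {
      # cubic Hermite interpolation between re-integration nodes: the
      # stored samples live on the (finer) shooting-segment grids
      hw <- .hermite_weights(s$times, result$times[k])
      kk <- hw$k
      qs <- hw$w[1] * s$q[kk, ] + hw$w[2] * s$v[kk, ] +
        hw$w[3] * s$q[kk + 1, ] + hw$w[4] * s$v[kk + 1, ]
      max_defect <- max(max_defect,
                        max(abs(qs - result$q[k, ])))
    }
    ends[[i]] <- c(s$q[nrow(s$q), ], s$v[nrow(s$v), ])
  }
  trans_res <- numeric(0)
  for (i in seq_len(nrow(schedule) - 1)) {
    # stored end state of phase i (last sample before the boundary)
    idx <- which(result$phase == i)
    ke <- idx[length(idx)]
    xe <- c(result$q[ke, ], result$v[ke, ])
    ti <- which(trans$after_phase == i + 1)
    if (length(ti) == 1) {
      cs <- contact_set(model, contacts_l[[i + 1]], xe[1:n])
      im <- impact_map(model, xe[1:n], xe[n + 1:n], cs)
      map_v <- im$v_plus
    } else map_v <- xe[n + 1:n]
    trans_res <- c(trans_res,
                   max(abs(result$x0[[i + 1]] - c(xe[1:n], map_v))))
  }
  min_fz <- if (length(result$forces)) min(result$forces) else NA_real_
  bounds_ok <- TRUE
  if (!is.null(result$config$u_bounds)) {
    b <- result$config$u_bounds
    bounds_ok <- all(sweep(result$u, 2, b[1, ], ">=") &
                       sweep(result$u, 2, b[2, ], "<="))
  }
  out <- list(max_defect = max_defect,
              transition_residuals = trans_res,
              min_vertical_force = min_fz,
              unilateral_ok = is.na(min_fz) || min_fz > -1e-6,
              bounds_ok = bounds_ok,
              ok = max_defect < tol$defect &&
                (length(trans_res) == 0 || max(trans_res) < tol$transition))
  class(out) <- "recon_check"
  out
}

#' @export
print.recon_check <- function(x, ...) {
  cat("Reconstruction check\n")
  cat(sprintf("  max re-integration defect: %.3e\n", x$max_defect))
  cat(sprintf("  max transition residual:   %.3e\n",
              if (length(x$transition_residuals))
                max(x$transition_residuals) else 0))
  cat(sprintf("  min vertical contact force: %.2f N (unilateral ok: %s)\n",
              x$min_vertical_force, x$unilateral_ok))
  cat(sprintf("  bounds ok: %s; overall ok: %s\n", x$bounds_ok, x$ok))
  invisible(x)
}
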