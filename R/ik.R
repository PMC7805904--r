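# Whole-chain least-squares inverse kinematics: fit generalized coordinates
# to Cartesian marker positions frame by frame (damped Gauss-Newton on the
# chain Jacobian), warm-starting each frame from the previous one.

#' Marker set definition
#'
#' Maps marker names to body segments and fixed offsets in the segment
#' frame (the "virtual markers" of the model).
#'
#' @param df data frame with columns `name`, `segment`, `x`, `y`, `z` (m).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(df) {
  stopifnot(all(c("name", "segment", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate marker names")
  structure(df[, c("name", "segment", "x", "y", "z")],
            class = c("marker_set", "data.frame"))
}

#' Default marker set for a model
#'
#' Places three virtual markers per body segment (proximal, distal and an
#' out-of-axis point), enough to observe every degree of freedom of the
#' chain. Intended for synthetic data; laboratory marker sets are supplied
#' as configuration ([read_marker_set_yaml()]).
#'
#' @param model a `multibody_model`.
#' @return A [marker_set()].
#' @export
default_marker_set <- function(model) {
  rows <- list()
  segs <- setdiff(unique(names(model$seg_body)), model$fused)
  for (nm in segs) {
    s <- model$segments[[nm]]
    L <- max(s$length, 0.1)
    dir <- .seg_direction(s$type)
    # out-of-axis offset: lateral for sagittal observability, anterior for
    # axial rotation
    side <- c(0.3, 0.4, 0) * L
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(nm, c("_prox", "_dist", "_side")),
      segment = nm,
      x = c(0, dir[1] * L, side[1]),
      y = c(0, dir[2] * L, side[2]),
      z = c(0, dir[3] * L, side[3]))
  }
  marker_set(do.call(rbind, rows))
}

#' Fit one marker frame
#'
#' Damped Gauss-Newton minimization of the summed squared distances between
#' the model's virtual markers and the measured marker positions, over all
#' generalized coordinates.
#'
#' @param model a `multibody_model`.
#' @param mset a [marker_set()].
#' @param markers named m x 3 matrix of measured positions (m); rows with
#'   any NA are treated as invalid.
#' @param q_init starting configuration.
#' @param weights optional per-marker weights (named or in marker order).
#' @param damping Levenberg damping added to the Gauss-Newton normal
#'   matrix.
#' @param tol convergence threshold on the step norm.
#' @param max_iter iteration cap.
#' @return list with `q`, `residual` (RMS marker distance, m), `n_markers`
#'   used, `converged`.
#' @export
fit_frame <- function(model, mset, markers, q_init,
                      weights = NULL, damping = 1e-6, tol = 1e-10,
                      max_iter = 100L) {
  idx <- match(mset$name, rownames(markers))
  meas <- markers[idx, , drop = FALSE]
  valid <- !is.na(idx) & apply(is.finite(meas), 1, all)
  if (sum(valid) < 3) {
    warning("fewer than 3 valid markers; frame skipped")
    return(list(q = q_init, residual = NA_real_, n_markers = sum(valid),
                converged = FALSE))
  }
  ms <- mset[valid, , drop = FALSE]
  meas <- meas[valid, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(ms)) else {
    ww <- if (!is.null(names(weights))) weights[ms$name] else weights[valid]
    as.numeric(ww)
  }
  bodies <- model$seg_body[ms$segment]
  offs <- as.matrix(ms[, c("x", "y", "z")])
  # fold segment-attachment transforms in (fused segments)
  for (k in seq_len(nrow(ms))) {
    at <- model$seg_attach[[ms$segment[k]]]
    offs[k, ] <- x_point_inv(at$X, offs[k, ])
  }
  sw <- sqrt(rep(w, each = 3))
  q <- q_init
  cost_of <- function(q) {
    cache <- fk_cache(model, q)
    r <- numeric(3 * nrow(ms))
    for (k in seq_len(nrow(ms)))
      r[3 * k - 2:0] <- body_point_world(cache, bodies[k], offs[k, ]) -
        meas[k, ]
    list(r = r * sw, cache = cache, raw = r)
  }
  cur <- cost_of(q)
  converged <- FALSE
  lambda <- damping
  for (it in seq_len(max_iter)) {
    J <- matrix(0, 3 * nrow(ms), model$n_dof)
    for (k in seq_len(nrow(ms)))
      J[3 * k - 2:0, ] <- point_jacobian(model, cur$cache, bodies[k],
                                         offs[k, ])
    J <- J * sw
    A <- crossprod(J) + lambda * diag(model$n_dof)
    dq <- tryCatch(-solve(A, crossprod(J, cur$r)),
                   error = function(e) NULL)
    if (is.null(dq)) { lambda <- lambda * 10; next }
    cand <- cost_of(q + dq)
    if (sum(cand$r^2) <= sum(cur$r^2) + 1e-15) {
      q <- q + as.numeric(dq); cur <- cand
      lambda <- max(lambda / 3, damping)
      if (sqrt(sum(dq^2)) < tol) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  rms <- sqrt(mean(rowSums(matrix(cur$raw, ncol = 3, byrow = TRUE)^2)))
  list(q = q, residual = rms, n_markers = nrow(ms), converged = converged)
}

#' Fit a marker trajectory to a reference motion
#'
#' Runs [fit_frame()] over a time-ordered marker sequence, warm-starting
#' every frame from the previous solution.
#'
#' @param model a `multibody_model`.
#' @param mset a [marker_set()].
#' @param mdata marker data: list with `times` (length n), `markers`
#'   (n x m x 3 array, marker names in dimnames) and optional `valid`
#'   (n x m logical).
#' @param q_init configuration used to start the first frame (default:
#'   standing pose).
#' @param ... passed to [fit_frame()].
#' @return An object of class `reference_motion`: list with `times`, `q`
#'   (n x n_dof), `residuals` (m), `stats` (mean/sd of the residual), and
#'   `skipped` (indices of unfittable frames).
#' @export
fit_trajectory <- function(model, mset, mdata, q_init = NULL, ...) {
  times <- mdata$times
  if (length(times) < 1) stop("no frames to fit")
  if (any(diff(times) <= 0)) stop("marker frames must be strictly time-ordered")
  if (is.null(q_init)) q_init <- standing_pose(model)
  n <- length(times)
  Q <- matrix(NA_real_, n, model$n_dof)
  res <- numeric(n)
  skipped <- integer(0)
  q <- q_init
  mnames <- dimnames(mdata$markers)[[2]]
  for (i in seq_len(n)) {
    mk <- matrix(mdata$markers[i, , ], ncol = 3,
                 dimnames = list(mnames, c("x", "y", "z")))
    if (!is.null(mdata$valid)) mk[!mdata$valid[i, ], ] <- NA_real_
    fit <- fit_frame(model, mset, mk, q, ...)
    if (is.na(fit$residual)) {
      skipped <- c(skipped, i)
      res[i] <- NA_real_
      next
    }
    q <- fit$q
    Q[i, ] <- q
    res[i] <- fit$residual
  }
  ok <- setdiff(seq_len(n), skipped)
  if (length(ok) == 0) stop("all frames skipped; empty reference motion")
  structure(list(times = times[ok], q = Q[ok, , drop = FALSE],
                 residuals = res[ok],
                 stats = c(mean = mean(res[ok]), sd = stats::sd(res[ok])),
                 skipped = skipped, n_dof = model$n_dof),
            class = "reference_motion")
}

#' @export
print.reference_motion <- function(x, ...) {
  cat(sprintf("Reference motion: %d frames over %.3f s, %d DoF\n",
              length(x$times), diff(range(x$times)), x$n_dof))
  cat(sprintf("  marker fit residual: %.2f cm +/- %.2f (mean +/- SD)\n",
              100 * x$stats["mean"], 100 * x$stats["sd"]))
  if (length(x$skipped))
    cat(sprintf("  %d frames skipped\n", length(x$skipped)))
  invisible(x)
}
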