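# Contact constraints: point Jacobians, the acceleration-level bias term
# (contact Hessian), redundancy reduction, the constrained-dynamics KKT
# solve and the perfectly inelastic impact map.

#' Define an active contact set
#'
#' Selects contact points of the model (by id, e.g. `"left_heel"`) and
#' records their anchor positions: the world position each point is
#' constrained to. Anchors default to the point positions at the supplied
#' configuration, optionally projected onto the ground plane z = 0.
#'
#' @param model a `multibody_model`.
#' @param ids character vector of contact point ids (subset of
#'   `model$contacts$id`); may be empty.
#' @param q configuration used to evaluate anchors (default: standing pose).
#' @param project_ground if `TRUE`, anchor z is set to 0.
#' @return A `contact_set` data frame (possibly 0 rows).
#' @export
contact_set <- function(model, ids, q = NULL, project_ground = FALSE) {
  if (length(ids) == 0) {
    cs <- model$contacts[0, ]
    cs$ax <- cs$ay <- cs$az <- numeric(0)
    return(structure(cs, class = c("contact_set", "data.frame")))
  }
  if (!all(ids %in% model$contacts$id))
    stop("unknown contact ids: ",
         paste(setdiff(ids, model$contacts$id), collapse = ", "))
  cs <- model$contacts[match(ids, model$contacts$id), ]
  if (is.null(q)) q <- standing_pose(model)
  cache <- fk_cache(model, q)
  anch <- t(vapply(seq_len(nrow(cs)), function(i)
    body_point_world(cache, cs$body[i], c(cs$x[i], cs$y[i], cs$z[i])),
    numeric(3)))
  if (project_ground) anch[, 3] <- 0
  cs$ax <- anch[, 1]; cs$ay <- anch[, 2]; cs$az <- anch[, 3]
  structure(cs, class = c("contact_set", "data.frame"))
}

## stacked 3 x n_dof world-frame Jacobian of one body-fixed point
point_jacobian <- function(model, cache, body, p_local) {
  J <- matrix(0, 3, model$n_dof)
  p_w <- body_point_world(cache, body, p_local)
  i <- body
  while (i != 0L) {
    S <- joint_subspace(model$jtype[i])
    E0t <- t(cache$X0[[i]]$E)
    if (any(S[1:3] != 0)) {           # revolute: a x (p - o)
      a_w <- as.numeric(E0t %*% S[1:3])
      o_w <- cache$X0[[i]]$r
      J[, i] <- cross3(a_w, p_w - o_w)
    } else {                          # prismatic
      J[, i] <- as.numeric(E0t %*% S[4:6])
    }
    i <- model$parent[i]
  }
  J
}

## constraint rows for a contact set: G (m x n), plus world positions,
## velocities and classical bias accelerations (the latter only if v given)
contact_kinematics <- function(model, q, v = NULL, contacts, cache = NULL) {
  dims <- model$contact_dims
  np <- nrow(contacts)
  if (is.null(cache)) cache <- fk_cache(model, q, v)
  G <- matrix(0, np * length(dims), model$n_dof)
  pos <- matrix(0, np, 3); velw <- matrix(0, np, 3)
  bias <- matrix(0, np, 3)
  avp <- NULL
  if (!is.null(v)) {                 # velocity-product accelerations
    avp <- vector("list", model$nb)
    for (i in seq_len(model$nb)) {
      S <- joint_subspace(model$jtype[i])
      p <- model$parent[i]
      ap <- if (p == 0L) numeric(6) else avp[[p]]
      avp[[i]] <- as.numeric(cache$Xup[[i]] %*% ap) +
        as.numeric(crm(cache$v[[i]]) %*% (S * v[i]))
    }
  }
  for (k in seq_len(np)) {
    b <- contacts$body[k]
    pl <- c(contacts$x[k], contacts$y[k], contacts$z[k])
    Jp <- point_jacobian(model, cache, b, pl)
    rows <- (k - 1) * length(dims) + seq_along(dims)
    G[rows, ] <- Jp[dims, , drop = FALSE]
    pos[k, ] <- body_point_world(cache, b, pl)
    if (!is.null(v)) {
      velw[k, ] <- body_point_velocity(cache, b, pl)
      vb <- cache$v[[b]]; ab <- avp[[b]]
      acl <- ab[4:6] + cross3(ab[1:3], pl) +
        cross3(vb[1:3], vb[4:6] + cross3(vb[1:3], pl))
      bias[k, ] <- as.numeric(t(cache$X0[[b]]$E) %*% acl)
    }
  }
  rn <- as.vector(t(outer(contacts$id, c("x", "y", "z")[dims], paste,
                          sep = ".")))
  rownames(G) <- rn
  list(G = G, pos = pos, vel = velw, bias = bias, dims = dims, cache = cache)
}

## structural per-foot row basis: for the canonical heel/hallux/meta5 foot
## geometry the retained constraint rows are fixed by the active contact
## configuration alone (full point constraint for the first point, selected
## in-plane rows for the others), so the reduced basis does not depend on
## numerical rank decisions. This keeps the constrained dynamics and the
## impact map smooth across configurations where rows become parallel
## (e.g. the heel and forefoot x-rows of a flat foot, which coincide
## exactly at zero foot pitch). Returns NULL for unrecognized geometries,
## in which case the caller falls back to the numerical reduction.
.structural_rows <- function(contacts, dims) {
  nd <- length(dims)
  rows <- integer(0)
  idx_of <- function(k, d) (k - 1L) * nd + match(d, dims)
  for (segname in unique(contacts$segment)) {
    ks <- which(contacts$segment == segname)
    pts <- contacts$point[ks]
    if (!all(pts %in% c("heel", "hallux", "meta5")) || anyDuplicated(pts))
      return(NULL)
    has <- function(p) p %in% pts
    pick <- function(pt, d) idx_of(ks[match(pt, pts)], d)
    if (length(ks) == 1) {
      rows <- c(rows, idx_of(ks[1], dims))
    } else if (nd == 2) {                    # planar (x, z)
      if (has("heel")) {
        toe <- if (has("hallux")) "hallux" else "meta5"
        rows <- c(rows, pick("heel", 1), pick("heel", 3), pick(toe, 3))
      } else {
        toe <- if (has("hallux")) "hallux" else "meta5"
        rows <- c(rows, pick(toe, 1), pick(toe, 3))
      }
    } else {                                 # spatial (x, y, z)
      if (has("heel")) {
        rows <- c(rows, pick("heel", 1), pick("heel", 2), pick("heel", 3))
        if (has("hallux"))
          rows <- c(rows, pick("hallux", 2), pick("hallux", 3))
        if (has("meta5"))
          rows <- c(rows,
                    if (!has("hallux")) pick("meta5", 1),
                    pick("meta5", 3))
      } else {
        first <- if (has("hallux")) "hallux" else "meta5"
        rows <- c(rows, pick(first, 1), pick(first, 2), pick(first, 3))
        if (has("hallux") && has("meta5"))
          rows <- c(rows, pick("meta5", 1), pick("meta5", 3))
      }
    }
  }
  sort(rows)
}

## retained constraint rows for a contact set: the structural per-foot
## basis when the geometry is canonical and well-conditioned, otherwise
## the numerical pivoted reduction
reduce_contact_rows <- function(G, contacts, dims) {
  rows <- .structural_rows(contacts, dims)
  if (!is.null(rows)) {
    sv <- svd(G[rows, , drop = FALSE], nu = 0, nv = 0)$d
    if (sv[length(sv)] > 1e-8 * max(sv[1], 1)) return(rows)
  }
  independent_rows(G)
}

## deterministic redundancy reduction by greedy column-pivoted selection:
## repeatedly keep the row with the largest residual against the span of
## the rows already kept (ties broken by listed order), until no residual
## exceeds the tolerance. Unlike a first-come scan this never retains a
## nearly dependent row while a well-conditioned one is available, so the
## reduced basis - and with it the constrained dynamics - stays stable
## under infinitesimal configuration changes (e.g. a flat foot, where the
## heel and forefoot x-rows coincide exactly at zero foot pitch).
## Returns sorted indices of retained rows.
independent_rows <- function(G, tol = 1e-8) {
  if (nrow(G) == 0) return(integer(0))
  keep <- integer(0)
  R <- G
  norms0 <- sqrt(rowSums(G^2))
  repeat {
    rn <- sqrt(rowSums(R^2))
    j <- which.max(rn)
    if (rn[j] <= tol * max(1, norms0[j])) break
    keep <- c(keep, j)
    q <- R[j, ] / rn[j]
    R <- R - outer(as.numeric(R %*% q), q)
    R[j, ] <- 0
    if (length(keep) == ncol(G)) break
  }
  sort(keep)
}

#' Contact Hessian (acceleration-level constraint bias)
#'
#' The term gamma = -Gdot(q) v appearing on the right-hand side of the
#' constrained-dynamics KKT system, evaluated as minus the classical
#' acceleration of the constrained contact points under zero generalized
#' acceleration. Quadratic in `v`.
#'
#' @param model a `multibody_model`.
#' @param q,v generalized positions and velocities.
#' @param contacts a [contact_set()].
#' @return numeric vector, one entry per (unreduced) constraint row.
#' @export
contact_hessian <- function(model, q, v, contacts) {
  ck <- contact_kinematics(model, q, v, contacts)
  -as.vector(t(ck$bias[, ck$dims, drop = FALSE]))
}

#' Constrained forward dynamics (KKT solve)
#'
#' Solves the mixed system `[H G^T; G 0] [a; -lambda] = [tau - C; gamma]`
#' for the generalized accelerations and contact forces, after reducing the
#' contact rows to an independent basis (rigid flat-foot contact makes the
#' raw per-point rows redundant).
#'
#' @param model a `multibody_model`.
#' @param q,v generalized positions and velocities.
#' @param tau actuated joint torques (length `n_act`) or a full generalized
#'   force vector (length `n_dof`).
#' @param contacts a [contact_set()]; may be empty (unconstrained dynamics).
#' @param gravity logical; include gravity (default `TRUE`).
#' @return An object of class `dynamics_eval`: list with `a`, `lambda`
#'   (forces on the retained rows), `H`, `C`, `G` (reduced), `gamma`
#'   (reduced), `rows` (names of retained rows), `forces` (per-point world
#'   force matrix) and `contacts`.
#' @export
constrained_forward_dynamics <- function(model, q, v, tau, contacts = NULL,
                                         gravity = TRUE,
                                         want_forces = TRUE) {
  if (any(!is.finite(q)) || any(!is.finite(v)) || any(!is.finite(tau)))
    stop("non-finite state or torque input")
  n <- model$n_dof
  Q <- generalized_force(model, tau)
  cache <- fk_cache(model, q, v)
  H <- crba(model, q, cache)
  C <- rnea(model, q, v, numeric(n), cache = cache, gravity = gravity)
  if (is.null(contacts) || nrow(contacts) == 0) {
    a <- solve(H, Q - C)
    return(structure(list(a = a, lambda = numeric(0), H = H, C = C,
                          G = matrix(0, 0, n), gamma = numeric(0),
                          rows = character(0),
                          forces = matrix(0, 0, 3), contacts = contacts),
                     class = "dynamics_eval"))
  }
  ck <- contact_kinematics(model, q, v, contacts, cache = cache)
  gamma_full <- -as.vector(t(ck$bias[, ck$dims, drop = FALSE]))
  keep <- reduce_contact_rows(ck$G, contacts, ck$dims)
  G <- ck$G[keep, , drop = FALSE]
  gam <- gamma_full[keep]
  nc <- nrow(G)
  K <- rbind(cbind(H, t(G)), cbind(G, matrix(0, nc, nc)))
  sol <- tryCatch(solve(K, c(Q - C, gam)),
                  error = function(e) stop("degenerate contact configuration: ",
                                           conditionMessage(e)))
  a <- sol[1:n]
  lambda <- -sol[n + seq_len(nc)]
  # per-point forces: the reduced multipliers are redistributed onto the
  # full (redundant) row set by the minimum-norm representative, which
  # shares load symmetrically across the contact points of a rigid foot;
  # the resultant wrench per body is unchanged. Skipped in integration and
  # linearization hot paths.
  forces <- if (want_forces) {
    lam_full <- .min_norm_rows(ck$G, t(G) %*% lambda)
    .row_forces(contacts, rownames(ck$G), lam_full, ck$dims)
  } else matrix(0, 0, 3)
  structure(list(a = a, lambda = lambda, H = H, C = C, G = G, gamma = gam,
                 rows = rownames(ck$G)[keep],
                 forces = forces,
                 contacts = contacts),
            class = "dynamics_eval")
}

## minimum-norm row multipliers reproducing a generalized contact force:
## solve min ||y|| s.t. t(G_full) y = f via the SVD pseudo-inverse
.min_norm_rows <- function(G_full, f) {
  sv <- svd(t(G_full))
  keep <- sv$d > 1e-10 * max(sv$d, 1e-300)
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((t(sv$u[, keep, drop = FALSE]) %*% f) / sv$d[keep]))
}

## expand per-row multipliers into per-point world force vectors (resultant
## per contact point; well-defined up to the per-foot wrench equivalence)
.row_forces <- function(contacts, rows, lambda, dims) {
  F <- matrix(0, nrow(contacts), 3,
              dimnames = list(contacts$id, c("x", "y", "z")))
  for (j in seq_along(rows)) {
    parts <- strsplit(rows[j], ".", fixed = TRUE)[[1]]
    d <- match(parts[length(parts)], c("x", "y", "z"))
    id <- paste(parts[-length(parts)], collapse = ".")
    F[id, d] <- F[id, d] + lambda[j]
  }
  F
}

generalized_force <- function(model, tau) {
  n <- model$n_dof
  if (length(tau) == n) return(as.numeric(tau))
  if (length(tau) == model$n_act) {
    Q <- numeric(n); Q[model$actuated] <- tau
    return(Q)
  }
  stop("tau must have length n_act (", model$n_act, ") or n_dof (", n, ")")
}

#' Perfectly inelastic impact map
#'
#' Computes the post-impact generalized velocities and contact impulses when
#' the given contact points are (newly) constrained:
#' `[H G^T; G 0] [v_plus; -Lambda] = [H v_minus; 0]`. The map zeroes the
#' constrained point velocities, conserves the momentum projection
#' orthogonal to the constraints, and never increases kinetic energy.
#'
#' @param model a `multibody_model`.
#' @param q configuration at the impact instant.
#' @param v_minus pre-impact generalized velocities.
#' @param contacts a [contact_set()] of the active contacts after the impact
#'   (gained plus persisting).
#' @return list with `v_plus`, `Lambda` (impulses on retained rows), `rows`,
#'   and `energy_loss` (J, >= 0).
#' @export
impact_map <- function(model, q, v_minus, contacts) {
  n <- model$n_dof
  cache <- fk_cache(model, q)
  H <- crba(model, q, cache)
  if (is.null(contacts) || nrow(contacts) == 0)
    return(list(v_plus = v_minus, Lambda = numeric(0), rows = character(0),
                energy_loss = 0))
  ck <- contact_kinematics(model, q, v = NULL, contacts, cache = cache)
  keep <- reduce_contact_rows(ck$G, contacts, ck$dims)
  G <- ck$G[keep, , drop = FALSE]
  nc <- nrow(G)
  K <- rbind(cbind(H, t(G)), cbind(G, matrix(0, nc, nc)))
  sol <- tryCatch(solve(K, c(as.numeric(H %*% v_minus), numeric(nc))),
                  error = function(e) stop("degenerate contact configuration: ",
                                           conditionMessage(e)))
  v_plus <- sol[1:n]
  Lambda <- -sol[n + seq_len(nc)]
  de <- 0.5 * sum(v_minus * (H %*% v_minus)) -
    0.5 * sum(v_plus * (H %*% v_plus))
  list(v_plus = v_plus, Lambda = Lambda, rows = rownames(ck$G)[keep],
       energy_loss = de)
}

## position- and velocity-level constraint residuals for an active set
constraint_residuals <- function(model, q, v, contacts) {
  ck <- contact_kinematics(model, q, v, contacts)
  anch <- cbind(contacts$ax, contacts$ay, contacts$az)
  gpos <- as.vector(t((ck$pos - anch)[, ck$dims, drop = FALSE]))
  gvel <- as.numeric(ck$G %*% v)
  list(g = gpos, Gv = gvel, G = ck$G)
}

## project (q, v) back onto the constraint manifold (least-norm corrections);
## used for drift control during integration
project_state <- function(model, q, v, contacts, tol = 1e-8, max_iter = 10) {
  if (is.null(contacts) || nrow(contacts) == 0) return(list(q = q, v = v))
  for (it in seq_len(max_iter)) {
    ck <- contact_kinematics(model, q, v = NULL, contacts)
    anch <- cbind(contacts$ax, contacts$ay, contacts$az)
    g <- as.vector(t((ck$pos - anch)[, ck$dims, drop = FALSE]))
    keep <- reduce_contact_rows(ck$G, contacts, ck$dims)
    G <- ck$G[keep, , drop = FALSE]
    g <- g[keep]
    if (max(abs(g)) < tol) break
    q <- q - as.numeric(t(G) %*% solve(G %*% t(G), g))
  }
  ck <- contact_kinematics(model, q, v = NULL, contacts)
  keep <- reduce_contact_rows(ck$G, contacts, ck$dims)
  G <- ck$G[keep, , drop = FALSE]
  gv <- as.numeric(G %*% v)
  v <- v - as.numeric(t(G) %*% solve(G %*% t(G), gv))
  list(q = q, v = v)
}

## center of pressure from per-point world contact forces (weighted by
## vertical force); NA when total vertical force is ~0
cop_from_forces <- function(points_world, forces) {
  fz <- forces[, 3]
  if (sum(fz) < 1e-9) return(c(NA_real_, NA_real_))
  c(sum(points_world[, 1] * fz), sum(points_world[, 2] * fz)) / sum(fz)
}
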