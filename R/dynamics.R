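# Recursive rigid-body dynamics: kinematics cache, RNEA, CRBA, COM state,
# angular momentum and energies.

## forward-kinematics cache: per internal body the parent->body motion
## transform (6x6), the world->body coordinate transform (E, r) and, when
## velocities are supplied, the body spatial velocity in body coordinates.
fk_cache <- function(model, q, v = NULL) {
  nb <- model$nb
  Xup <- vector("list", nb); X0 <- vector("list", nb)
  vel <- if (is.null(v)) NULL else vector("list", nb)
  for (i in seq_len(nb)) {
    Xl <- xmul(joint_xform(model$jtype[i], q[i]), model$Xtree[[i]])
    Xup[[i]] <- x_motion(Xl)
    p <- model$parent[i]
    X0[[i]] <- if (p == 0L) Xl else xmul(Xl, X0[[p]])
    if (!is.null(v)) {
      S <- joint_subspace(model$jtype[i])
      vp <- if (p == 0L) numeric(6) else vel[[p]]
      vel[[i]] <- as.numeric(Xup[[i]] %*% vp) + S * v[i]
    }
  }
  list(Xup = Xup, X0 = X0, v = vel)
}

## recursive Newton-Euler: generalized forces needed to produce qdd at (q, qd)
## including gravity (as a fictitious base acceleration) unless disabled.
rnea <- function(model, q, qd, qdd, cache = NULL, gravity = TRUE) {
  nb <- model$nb
  if (is.null(cache)) cache <- fk_cache(model, q, qd)
  Xup <- cache$Xup
  vel <- cache$v
  if (is.null(vel)) {
    cache <- fk_cache(model, q, qd)
    Xup <- cache$Xup; vel <- cache$v
  }
  a0 <- if (gravity) c(0, 0, 0, -model$gravity) else numeric(6)
  acc <- vector("list", nb); f <- vector("list", nb)
  for (i in seq_len(nb)) {
    S <- joint_subspace(model$jtype[i])
    p <- model$parent[i]
    ap <- if (p == 0L) a0 else acc[[p]]
    acc[[i]] <- as.numeric(Xup[[i]] %*% ap) + S * qdd[i] +
      as.numeric(crm(vel[[i]]) %*% (S * qd[i]))
    f[[i]] <- as.numeric(model$I[[i]] %*% acc[[i]]) +
      as.numeric(crf(vel[[i]]) %*% (model$I[[i]] %*% vel[[i]]))
  }
  tau <- numeric(nb)
  for (i in rev(seq_len(nb))) {
    S <- joint_subspace(model$jtype[i])
    tau[i] <- sum(S * f[[i]])
    p <- model$parent[i]
    if (p != 0L) f[[p]] <- f[[p]] + as.numeric(t(Xup[[i]]) %*% f[[i]])
  }
  tau
}

## nonlinear effects C(q, v): RNEA with zero accelerations (gravity included)
nonlinear_effects <- function(model, q, qd, cache = NULL) {
  rnea(model, q, qd, numeric(model$nb), cache = cache, gravity = TRUE)
}

## composite rigid-body algorithm: joint-space mass matrix H(q)
crba <- function(model, q, cache = NULL) {
  nb <- model$nb
  if (is.null(cache)) cache <- fk_cache(model, q)
  Xup <- cache$Xup
  Ic <- model$I
  H <- matrix(0, nb, nb)
  for (i in rev(seq_len(nb))) {
    p <- model$parent[i]
    if (p != 0L) Ic[[p]] <- Ic[[p]] + t(Xup[[i]]) %*% Ic[[i]] %*% Xup[[i]]
    S <- joint_subspace(model$jtype[i])
    fh <- as.numeric(Ic[[i]] %*% S)
    H[i, i] <- sum(S * fh)
    j <- i
    while (model$parent[j] != 0L) {
      fh <- as.numeric(t(Xup[[j]]) %*% fh)
      j <- model$parent[j]
      H[i, j] <- H[j, i] <- sum(joint_subspace(model$jtype[j]) * fh)
    }
  }
  H
}

## world position of a point given in body-local coordinates
body_point_world <- function(cache, body, p_local) {
  x_point_inv(cache$X0[[body]], p_local)
}

## world velocity of a body-fixed point (requires velocity cache)
body_point_velocity <- function(cache, body, p_local) {
  v <- cache$v[[body]]
  vb <- v[4:6] + cross3(v[1:3], p_local)
  as.numeric(t(cache$X0[[body]]$E) %*% vb)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Whole-body center of mass position and velocity
#'
#' Mass-weighted average of the segment COM positions (and velocities) over
#' all body segments, evaluated by forward kinematics.
#'
#' @param model a `multibody_model`.
#' @param q,v generalized positions and velocities (`v` optional).
#' @return list with `r_com` (m, world frame) and, if `v` is given,
#'   `rdot_com` (m/s); also `mass` (kg).
#' @export
com_state <- function(model, q, v = NULL) {
  cache <- fk_cache(model, q, v)
  segs <- unique(names(model$seg_body))
  m_tot <- 0; r <- c(0, 0, 0); rd <- c(0, 0, 0)
  for (nm in segs) {
    s <- model$segments[[nm]]
    at <- model$seg_attach[[nm]]
    c_local <- x_point_inv(at$X, s$com_offset)  # segment COM in body frame
    m_tot <- m_tot + s$mass
    r <- r + s$mass * body_point_world(cache, at$body, c_local)
    if (!is.null(v))
      rd <- rd + s$mass * body_point_velocity(cache, at$body, c_local)
  }
  out <- list(r_com = r / m_tot, mass = m_tot)
  if (!is.null(v)) out$rdot_com <- rd / m_tot
  out
}

#' Angular momentum of a segment subset about a point
#'
#' Sums, over the requested segments, the segment spin momentum (inertia
#' about the segment COM times segment angular velocity) and the orbital term
#' m (r - about) x rdot, all expressed in world coordinates.
#'
#' @param model a `multibody_model`.
#' @param q,v generalized positions and velocities.
#' @param segments character vector of segment names (default: all).
#' @param about 3-vector reference point in world coordinates (default: the
#'   instantaneous whole-body COM).
#' @return 3-vector, kg m^2/s.
#' @export
angular_momentum <- function(model, q, v, segments = NULL, about = NULL) {
  cache <- fk_cache(model, q, v)
  all_segs <- unique(names(model$seg_body))
  if (is.null(segments)) segments <- all_segs
  if (length(segments) == 0) return(c(0, 0, 0))
  if (!all(segments %in% all_segs))
    stop("unknown segments: ",
         paste(setdiff(segments, all_segs), collapse = ", "))
  if (is.null(about)) about <- com_state(model, q, v)$r_com
  L <- c(0, 0, 0)
  for (nm in segments) {
    s <- model$segments[[nm]]
    at <- model$seg_attach[[nm]]
    X0s <- xmul(at$X, cache$X0[[at$body]])      # world -> segment frame
    vs <- as.numeric(x_motion(at$X) %*% cache$v[[at$body]])
    omega_s <- vs[1:3]
    vcom_s <- vs[4:6] + cross3(omega_s, s$com_offset)
    r_c <- x_point_inv(X0s, s$com_offset)
    rdot_c <- as.numeric(t(X0s$E) %*% vcom_s)
    spin <- as.numeric(t(X0s$E) %*% (s$inertia %*% omega_s))
    L <- L + spin + s$mass * cross3(r_c - about, rdot_c)
  }
  L
}

## kinetic and potential energy (compiled body inertias; fused segments
## already folded in)
kinetic_energy <- function(model, q, v, cache = NULL) {
  if (is.null(cache)) cache <- fk_cache(model, q, v)
  e <- 0
  for (i in seq_len(model$nb))
    e <- e + 0.5 * sum(cache$v[[i]] * (model$I[[i]] %*% cache$v[[i]]))
  e
}

potential_energy <- function(model, q) {
  cs <- com_state(model, q)
  -cs$mass * sum(model$gravity * cs$r_com)
}

#' Neutral standing pose
#'
#' All joint angles zero, base translated vertically so the foot soles touch
#' the ground plane z = 0.
#'
#' @param model a `multibody_model`.
#' @return generalized position vector `q`.
#' @export
standing_pose <- function(model) {
  q <- numeric(model$n_dof)
  cache <- fk_cache(model, q)
  zmin <- min(vapply(seq_len(nrow(model$contacts)), function(i) {
    r <- model$contacts[i, ]
    body_point_world(cache, r$body, c(r$x, r$y, r$z))[3]
  }, 0))
  iz <- which(model$jtype[seq_len(model$base_dof)] == "Pz")
  q[iz] <- -zmin
  q
}
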