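# Multibody model construction.
#
# Internally every model is a kinematic tree of elementary 1-DoF joints
# (Rx/Ry/Rz revolute, Px/Py/Pz prismatic); composite joints (the 6-DoF
# floating base and the anatomical 3-DoF ball joints) are chains of
# elementary joints connected by massless intermediate bodies, with the
# segment inertia attached to the last body of the chain. This makes the
# recursive dynamics algorithms uniform: one generalized coordinate per
# internal body.
#
# Joint axis conventions (a package convention, not a measured fact):
#   * floating base: translation Px, Py, Pz then rotation Rz (yaw), Rx
#     (roll), Ry (pitch) - gimbal lock at roll = +/-90 deg, far outside
#     walking postures;
#   * 3-DoF anatomical joints: Ry (flexion/extension), Rx (ab/adduction),
#     Rz (axial rotation);
#   * knees and elbows: Ry.

.base_dof_spatial <- c("Px", "Py", "Pz", "Rz", "Rx", "Ry")
.base_dof_planar <- c("Px", "Pz", "Ry")
.ball <- c("Ry", "Rx", "Rz")

## default foot contact-point template, in the foot frame (origin at the
## ankle, x anterior, z up); fractions of foot length L, ankle height h.
## side is +1 for left (lateral = +y), -1 for right.
.foot_contact_points <- function(L, h, side_sign) {
  data.frame(
    point = c("heel", "hallux", "meta5"),
    x = c(-0.25 * L, 0.75 * L, 0.50 * L),
    y = side_sign * c(0, -0.10 * L, 0.18 * L),
    z = c(-h, -h, -h)
  )
}

## blueprint -> compiled model ------------------------------------------------

compile_model <- function(blueprint, segments, type = "custom") {
  bp <- blueprint
  nb <- length(bp$base$dof) +
    sum(vapply(bp$joints, function(j) length(j$types), 0L))
  parent <- integer(nb); jtype <- character(nb)
  Xtree <- vector("list", nb); Ibody <- vector("list", nb)
  qnames <- character(nb)
  seg_body <- integer(0)
  zero6 <- matrix(0, 6, 6)

  k <- 0L
  add_chain <- function(par, types, offset, label) {
    for (i in seq_along(types)) {
      k <<- k + 1L
      parent[k] <<- par
      jtype[k] <<- types[i]
      Xtree[[k]] <<- if (i == 1) xforms(diag(3), offset) else xforms()
      Ibody[[k]] <<- zero6
      qnames[k] <<- paste0(label, "_", types[i])
      par <- k
    }
    k
  }
  seg_inertia <- function(name) {
    s <- segments[[name]]
    mcI(s$mass, s$com_offset, s$inertia)
  }

  seg_attach <- list()  # per segment: carrying body + fixed body->segment xform

  b <- add_chain(0L, bp$base$dof, c(0, 0, 0), bp$base$segment)
  Ibody[[b]] <- seg_inertia(bp$base$segment)
  seg_body[bp$base$segment] <- b
  seg_attach[[bp$base$segment]] <- list(body = b, X = xforms())

  for (j in bp$joints) {
    if (!j$parent %in% names(seg_body))
      stop("joint ", j$name, ": parent segment not yet in tree: ", j$parent)
    b <- add_chain(seg_body[[j$parent]], j$types, j$offset, j$name)
    Ibody[[b]] <- seg_inertia(j$child)
    seg_body[j$child] <- b
    seg_attach[[j$child]] <- list(body = b, X = xforms())
  }

  # rigidly fused segments: fold their inertia into the carrying body
  fused_names <- character(0)
  for (f in bp$fused %||% list()) {
    host <- seg_body[[f$parent]]
    Xf <- xmul(xforms(diag(3), f$offset), seg_attach[[f$parent]]$X)
    X <- x_motion(Xf)  # host body frame -> child segment frame
    Ibody[[host]] <- Ibody[[host]] + t(X) %*% seg_inertia(f$child) %*% X
    seg_body[f$child] <- host
    seg_attach[[f$child]] <- list(body = host, X = Xf)
    fused_names <- c(fused_names, f$child)
  }

  contacts <- bp$contacts
  contacts$body <- seg_body[contacts$segment]

  base_dof <- length(bp$base$dof)
  model <- structure(list(
    nb = nb, parent = parent, jtype = jtype, Xtree = Xtree, I = Ibody,
    qnames = qnames, n_dof = nb, base_dof = base_dof,
    actuated = if (nb > base_dof) seq.int(base_dof + 1L, nb) else integer(0),
    n_act = nb - base_dof,
    segments = segments, seg_body = seg_body, seg_attach = seg_attach,
    fused = fused_names,
    contacts = contacts,
    contact_dims = if (isTRUE(bp$planar)) c(1L, 3L) else 1:3,
    planar = isTRUE(bp$planar),
    gravity = c(0, 0, -9.81),
    blueprint = bp, type = type
  ), class = "multibody_model")
  model$total_mass <- sum(vapply(unique(names(seg_body)), function(nm)
    segments[[nm]]$mass, 0))
  model
}

## skeleton geometry shared by the spatial models
.spatial_blueprint <- function(segments, reduced = FALSE) {
  H <- attr(segments, "anthro")$total_height
  len <- function(nm) segments[[nm]]$length
  hip_half <- 0.052 * H
  shoulder_half <- 0.120 * H
  ankle_h <- 0.039 * H

  joints <- list(
    list(name = "lumbo_sacral", parent = "pelvis", child = "mid_trunk",
         types = .ball, offset = c(0, 0, len("pelvis"))),
    list(name = "hip_l", parent = "pelvis", child = "thigh_l",
         types = .ball, offset = c(0, hip_half, 0)),
    list(name = "knee_l", parent = "thigh_l", child = "shank_l",
         types = "Ry", offset = c(0, 0, -len("thigh_l"))),
    list(name = "ankle_l", parent = "shank_l", child = "foot_l",
         types = .ball, offset = c(0, 0, -len("shank_l"))),
    list(name = "hip_r", parent = "pelvis", child = "thigh_r",
         types = .ball, offset = c(0, -hip_half, 0)),
    list(name = "knee_r", parent = "thigh_r", child = "shank_r",
         types = "Ry", offset = c(0, 0, -len("thigh_r"))),
    list(name = "ankle_r", parent = "shank_r", child = "foot_r",
         types = .ball, offset = c(0, 0, -len("shank_r")))
  )
  fused <- list()
  if (reduced) {
    fused <- c(fused, list(list(parent = "mid_trunk", child = "upper_trunk",
                                offset = c(0, 0, len("mid_trunk")))))
    up_parent <- "mid_trunk"
    up_base <- c(0, 0, len("mid_trunk"))  # xiphoid level in mid-trunk frame
  } else {
    joints <- c(joints, list(
      list(name = "xiphoid", parent = "mid_trunk", child = "upper_trunk",
           types = .ball, offset = c(0, 0, len("mid_trunk")))))
    up_parent <- "upper_trunk"
    up_base <- c(0, 0, 0)
  }
  Lup <- len("upper_trunk")
  joints <- c(joints, list(
    list(name = "cervicale", parent = up_parent, child = "head",
         types = .ball, offset = up_base + c(0, 0, Lup)),
    list(name = "shoulder_l", parent = up_parent, child = "upper_arm_l",
         types = .ball, offset = up_base + c(0, shoulder_half, Lup)),
    list(name = "elbow_l", parent = "upper_arm_l", child = "forearm_l",
         types = "Ry", offset = c(0, 0, -len("upper_arm_l"))),
    list(name = "shoulder_r", parent = up_parent, child = "upper_arm_r",
         types = .ball, offset = up_base + c(0, -shoulder_half, Lup)),
    list(name = "elbow_r", parent = "upper_arm_r", child = "forearm_r",
         types = "Ry", offset = c(0, 0, -len("upper_arm_r")))
  ))
  if (reduced) {
    fused <- c(fused,
      list(list(parent = "forearm_l", child = "hand_l",
                offset = c(0, 0, -len("forearm_l"))),
           list(parent = "forearm_r", child = "hand_r",
                offset = c(0, 0, -len("forearm_r")))))
  } else {
    joints <- c(joints, list(
      list(name = "wrist_l", parent = "forearm_l", child = "hand_l",
           types = .ball, offset = c(0, 0, -len("forearm_l"))),
      list(name = "wrist_r", parent = "forearm_r", child = "hand_r",
           types = .ball, offset = c(0, 0, -len("forearm_r")))))
  }

  cp <- rbind(
    cbind(segment = "foot_l", side = "left",
          .foot_contact_points(len("foot_l"), ankle_h, +1)),
    cbind(segment = "foot_r", side = "right",
          .foot_contact_points(len("foot_r"), ankle_h, -1))
  )
  cp$id <- paste(cp$side, cp$point, sep = "_")

  list(base = list(segment = "pelvis", dof = .base_dof_spatial),
       joints = joints, fused = fused, contacts = cp, planar = FALSE)
}

#' Build the full 16-segment whole-body model
#'
#' Assembles the 43-DoF tree: a 6-DoF floating base at the pelvis, 3-DoF
#' ball joints at the hips, ankles, lumbo-sacral junction, xiphoid,
#' cervicale, shoulders and wrists, and 1-DoF knees and elbows. Each foot
#' carries three contact points (heel, hallux, meta5) spanning a rigid
#' triangle.
#'
#' @param segments a `segment_params` object from [de_leva_parameters()].
#' @return A `multibody_model` with `n_dof = 43`.
#' @export
build_full_model <- function(segments) {
  stopifnot(inherits(segments, "segment_params"))
  need <- .segment_list()$name
  if (!all(need %in% names(segments)))
    stop("missing segments: ", paste(setdiff(need, names(segments)),
                                     collapse = ", "))
  compile_model(.spatial_blueprint(segments, reduced = FALSE), segments,
                type = "full")
}

#' Build the reduced 13-segment whole-body model
#'
#' The full model with the xiphoid joint and both wrists locked: the upper
#' trunk is rigidly fused to the middle trunk and the hands to the forearms
#' (composite inertia via the parallel-axis theorem; total mass unchanged).
#'
#' @inheritParams build_full_model
#' @return A `multibody_model` with `n_dof = 34`.
#' @export
build_reduced_model <- function(segments) {
  stopifnot(inherits(segments, "segment_params"))
  compile_model(.spatial_blueprint(segments, reduced = TRUE), segments,
                type = "reduced")
}

#' Build the planar 7-segment walker
#'
#' Sagittal-plane test model: head, arms and trunk are fused into a single
#' HAT segment on a 3-DoF planar base (x, z, pitch), with 1-DoF hips, knees
#' and ankles (9 DoF, 6 actuated). Contact points are constrained in x and z
#' only.
#'
#' @inheritParams build_full_model
#' @return A `multibody_model` with `n_dof = 9`.
#' @export
build_planar_walker <- function(segments) {
  stopifnot(inherits(segments, "segment_params"))
  H <- attr(segments, "anthro")$total_height
  len <- function(nm) segments[[nm]]$length
  ankle_h <- 0.039 * H
  joints <- list(
    list(name = "hip_l", parent = "pelvis", child = "thigh_l",
         types = "Ry", offset = c(0, 0.052 * H, 0)),
    list(name = "knee_l", parent = "thigh_l", child = "shank_l",
         types = "Ry", offset = c(0, 0, -len("thigh_l"))),
    list(name = "ankle_l", parent = "shank_l", child = "foot_l",
         types = "Ry", offset = c(0, 0, -len("shank_l"))),
    list(name = "hip_r", parent = "pelvis", child = "thigh_r",
         types = "Ry", offset = c(0, -0.052 * H, 0)),
    list(name = "knee_r", parent = "thigh_r", child = "shank_r",
         types = "Ry", offset = c(0, 0, -len("thigh_r"))),
    list(name = "ankle_r", parent = "shank_r", child = "foot_r",
         types = "Ry", offset = c(0, 0, -len("shank_r")))
  )
  Lp <- len("pelvis"); Lm <- len("mid_trunk"); Lu <- len("upper_trunk")
  fused <- list(
    list(parent = "pelvis", child = "mid_trunk", offset = c(0, 0, Lp)),
    list(parent = "pelvis", child = "upper_trunk", offset = c(0, 0, Lp + Lm)),
    list(parent = "pelvis", child = "head", offset = c(0, 0, Lp + Lm + Lu)),
    list(parent = "pelvis", child = "upper_arm_l",
         offset = c(0, 0.120 * H, Lp + Lm + Lu)),
    list(parent = "pelvis", child = "upper_arm_r",
         offset = c(0, -0.120 * H, Lp + Lm + Lu)),
    list(parent = "pelvis", child = "forearm_l",
         offset = c(0, 0.120 * H, Lp + Lm + Lu - len("upper_arm_l"))),
    list(parent = "pelvis", child = "forearm_r",
         offset = c(0, -0.120 * H, Lp + Lm + Lu - len("upper_arm_r"))),
    list(parent = "pelvis", child = "hand_l",
         offset = c(0, 0.120 * H,
                    Lp + Lm + Lu - len("upper_arm_l") - len("forearm_l"))),
    list(parent = "pelvis", child = "hand_r",
         offset = c(0, -0.120 * H,
                    Lp + Lm + Lu - len("upper_arm_r") - len("forearm_r")))
  )
  cp <- rbind(
    cbind(segment = "foot_l", side = "left",
          .foot_contact_points(len("foot_l"), ankle_h, +1)),
    cbind(segment = "foot_r", side = "right",
          .foot_contact_points(len("foot_r"), ankle_h, -1))
  )
  # planar model: align meta5 with the hallux sagittally so toe-only
  # contact leaves the heel-rise pivot free (x/z constraints only)
  cp$x[cp$point == "meta5"] <- cp$x[cp$point == "hallux"]
  cp$id <- paste(cp$side, cp$point, sep = "_")
  compile_model(list(base = list(segment = "pelvis", dof = .base_dof_planar),
                     joints = joints, fused = fused, contacts = cp,
                     planar = TRUE),
                segments, type = "planar")
}

#' @export
print.multibody_model <- function(x, ...) {
  cat(sprintf("Multibody model (%s): %d DoF (%d actuated), %d segments, %.2f kg\n",
              x$type, x$n_dof, x$n_act, length(unique(names(x$seg_body))),
              x$total_mass))
  cat("  contact points:", paste(x$contacts$id, collapse = ", "), "\n")
  invisible(x)
}

#' Export a model description to YAML
#'
#' Writes the construction blueprint (base, joints, fused segments, contact
#' points) together with the segment inertial parameters, so that the model
#' can be rebuilt exactly with [read_model_yaml()].
#'
#' @param model a `multibody_model`.
#' @param path output file path.
#' @export
write_model_yaml <- function(model, path) {
  segs <- lapply(model$segments, function(s)
    list(name = s$name, type = s$type, side = s$side %||% NULL,
         mass = s$mass, com_offset = as.numeric(s$com_offset),
         inertia = as.numeric(s$inertia), length = s$length))
  bp <- model$blueprint
  bp$joints <- lapply(bp$joints, function(j)
    list(name = j$name, parent = j$parent, child = j$child,
         types = as.list(j$types), offset = as.numeric(j$offset)))
  bp$contacts <- lapply(seq_len(nrow(bp$contacts)), function(i)
    as.list(bp$contacts[i, c("segment", "side", "point", "x", "y", "z", "id")]))
  out <- list(type = model$type,
              anthro = unclass(attr(model$segments, "anthro")),
              blueprint = bp, segments = segs)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Rebuild a model from a YAML description written by [write_model_yaml()]
#'
#' @param path YAML file path.
#' @return A `multibody_model`.
#' @export
read_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  segs <- lapply(x$segments, function(s)
    list(name = s$name, type = s$type, side = s$side %||% NA_character_,
         mass = s$mass, com_offset = as.numeric(s$com_offset),
         inertia = matrix(as.numeric(s$inertia), 3, 3), length = s$length))
  names(segs) <- vapply(segs, `[[`, "", "name")
  class(segs) <- "segment_params"
  a <- x$anthro
  attr(segs, "anthro") <- subject_anthropometry(a$sex, a$total_mass,
                                                a$total_height, a$leg_length,
                                                a$prosthesis)
  bp <- x$blueprint
  bp$joints <- lapply(bp$joints, function(j) {
    j$types <- unlist(j$types); j$offset <- as.numeric(j$offset); j
  })
  bp$contacts <- do.call(rbind, lapply(bp$contacts, function(r)
    data.frame(segment = r$segment, side = r$side, point = r$point,
               x = r$x, y = r$y, z = r$z, id = r$id)))
  compile_model(bp, segs, type = x$type)
}
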