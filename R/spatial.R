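# Spatial (6-D) vector algebra for rigid-body dynamics.
#
# Conventions (fixed throughout the package):
#   * 6-D vectors are angular-first: (wx, wy, wz, vx, vy, vz).
#   * A coordinate transform is stored as list(E, r): frame B is obtained from
#     frame A by translating the origin by r (expressed in A) and rotating by
#     E (the rotation that maps A-coordinates to B-coordinates), so a point
#     transforms as p_B = E %*% (p_A - r).
#   * World axes: x anterior (walking direction), y lateral (left positive),
#     z vertical up; gravity acts along -z.

## elementary rotations (coordinate transforms)
rotx <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3)
}

roty <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3)
}

rotz <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3)
}

## skew-symmetric cross-product matrix: skew(a) %*% b == a x b
skew <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

## plain coordinate transform constructors/operations
xforms <- function(E = diag(3), r = c(0, 0, 0)) list(E = E, r = as.numeric(r))

# composite: apply X1 (A -> B), then X2 (B -> C); returns A -> C
xmul <- function(X2, X1) {
  list(E = X2$E %*% X1$E, r = X1$r + as.numeric(t(X1$E) %*% X2$r))
}

xinv <- function(X) {
  list(E = t(X$E), r = as.numeric(-X$E %*% X$r))
}

x_point <- function(X, p) as.numeric(X$E %*% (p - X$r))        # A -> B
x_point_inv <- function(X, p) as.numeric(t(X$E) %*% p + X$r)   # B -> A

## 6x6 motion transform matrix from list(E, r)
x_motion <- function(X) {
  M <- matrix(0, 6, 6)
  ErX <- -X$E %*% skew(X$r)
  M[1:3, 1:3] <- X$E
  M[4:6, 4:6] <- X$E
  M[4:6, 1:3] <- ErX
  M
}

## spatial cross products: crm for motion vectors, crf = -t(crm) for forces
crm <- function(v) {
  M <- matrix(0, 6, 6)
  Sw <- skew(v[1:3])
  M[1:3, 1:3] <- Sw
  M[4:6, 4:6] <- Sw
  M[4:6, 1:3] <- skew(v[4:6])
  M
}

crf <- function(v) -t(crm(v))

## spatial inertia about the frame origin: mass m, COM at c (local), rotational
## inertia Ic (3x3, about the COM)
mcI <- function(m, c, Ic) {
  C <- skew(c)
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- Ic + m * C %*% t(C)
  M[1:3, 4:6] <- m * C
  M[4:6, 1:3] <- m * t(C)
  M[4:6, 4:6] <- m * diag(3)
  M
}

## decompose a 6x6 spatial inertia into (m, c, Ic)
mcI_decompose <- function(I6) {
  m <- I6[4, 4]
  mC <- I6[1:3, 4:6]
  c <- c(mC[3, 2], mC[1, 3], mC[2, 1]) / m
  C <- skew(c)
  Ic <- I6[1:3, 1:3] - m * C %*% t(C)
  list(m = m, c = c, Ic = Ic)
}

## joint transform and motion subspace for elementary 1-DoF joints
joint_xform <- function(jtype, q) {
  switch(jtype,
    Rx = xforms(rotx(q)),
    Ry = xforms(roty(q)),
    Rz = xforms(rotz(q)),
    Px = xforms(diag(3), c(q, 0, 0)),
    Py = xforms(diag(3), c(0, q, 0)),
    Pz = xforms(diag(3), c(0, 0, q)),
    stop("unknown joint type: ", jtype)
  )
}

joint_subspace <- function(jtype) {
  switch(jtype,
    Rx = c(1, 0, 0, 0, 0, 0),
    Ry = c(0, 1, 0, 0, 0, 0),
    Rz = c(0, 0, 1, 0, 0, 0),
    Px = c(0, 0, 0, 1, 0, 0),
    Py = c(0, 0, 0, 0, 1, 0),
    Pz = c(0, 0, 0, 0, 0, 1),
    stop("unknown joint type: ", jtype)
  )
}
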