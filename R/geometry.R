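# Projection-sphere geometry: directions, point-group symmetry, geodesic
# distances and sampling of the asymmetric unit.
#
# Conventions: Euler angles are ZYZ (rot, tilt, psi) in degrees, as in the
# common SPA metadata dialect; internally all distances are radians. A
# particle's projection direction depends only on (rot, tilt).

DEG2RAD <- pi / 180

#' Convert the first two Euler angles to a projection direction
#'
#' The projection direction of an orientation (rot, tilt, psi) is the unit
#' vector the map is viewed along; it does not depend on the in-plane angle
#' psi.
#'
#' @param rot Azimuthal (first ZYZ) Euler angle, degrees.
#' @param tilt Polar (second ZYZ) Euler angle, degrees.
#' @return A unit 3-vector \code{(sin t cos r, sin t sin r, cos t)}.
#'   Vectorised: with n angles, an n x 3 matrix.
#' @seealso [direction_to_euler()] for the inverse.
#' @export
euler_to_direction <- function(rot, tilt) {
  r <- rot * DEG2RAD
  t <- tilt * DEG2RAD
  d <- cbind(sin(t) * cos(r), sin(t) * sin(r), cos(t))
  colnames(d) <- c("x", "y", "z")
  if (nrow(d) == 1L) drop(d) else d
}

#' Recover (rot, tilt) from a projection direction
#'
#' @param d Unit 3-vector, or an n x 3 matrix of unit rows.
#' @return A list with elements \code{rot} and \code{tilt} in degrees,
#'   tilt in [0, 180], rot in [-180, 180).
#' @export
direction_to_euler <- function(d) {
  d <- rbind(d)
  tilt <- acos(pmin(1, pmax(-1, d[, 3]))) / DEG2RAD
  rot <- atan2(d[, 2], d[, 1]) / DEG2RAD
  rot[rot >= 180] <- rot[rot >= 180] - 360
  rot[abs(sin(tilt * DEG2RAD)) < 1e-12] <- 0   # pole: rot undefined
  list(rot = rot, tilt = tilt)
}

## Rotation matrix about an arbitrary unit axis (Rodrigues)
rot_axis <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle_rad); s <- sin(angle_rad)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c + s * ux + (1 - c) * tcrossprod(u)
}

rot_z <- function(a) rot_axis(c(0, 0, 1), a)

## Intrinsic ZYZ Euler rotation: Rz(rot) %*% Ry(tilt) %*% Rz(psi).
## Maps image-frame coordinates into map-frame coordinates; the viewing
## direction is euler_matrix(...) %*% c(0,0,1).
euler_matrix <- function(rot, tilt, psi) {
  rot_z(rot * DEG2RAD) %*% rot_axis(c(0, 1, 0), tilt * DEG2RAD) %*%
    rot_z(psi * DEG2RAD)
}

## Close a generator set under composition (finite point groups only)
close_group <- function(gens, tol = 1e-9) {
  ops <- list(diag(3))
  key <- function(m) paste(round(m / tol) * tol, collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    k <- key(g)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      ops[[length(ops) + 1L]] <- g
      for (h in ops) {
        queue <- c(queue, list(g %*% h, h %*% g))
      }
      if (length(ops) > 120) stop("symmetry group failed to close; bad generators")
    }
  }
  ops
}

#' Point-group symmetry of a map
#'
#' Builds the list of rotation matrices for the common single-particle point
#' groups: cyclic \code{Cn}, dihedral \code{Dn} (two-fold axes perpendicular
#' to z), tetrahedral \code{T}, octahedral \code{O} and icosahedral \code{I}
#' (two-fold axis along z, a five-fold axis through an icosahedron vertex at
#' (0, 1, phi)).
#'
#' @param label Point-group label, e.g. \code{"C1"}, \code{"C4"}, \code{"D2"},
#'   \code{"T"}, \code{"O"}, \code{"I"}.
#' @return An object of class \code{SymmetryGroup}: list with \code{label},
#'   \code{order} and \code{ops} (list of 3x3 rotation matrices, identity
#'   first).
#' @export
symmetry_group <- function(label = "C1") {
  label <- toupper(trimws(label))
  phi <- (1 + sqrt(5)) / 2
  gens <-
    if (grepl("^C[0-9]+$", label)) {
      n <- as.integer(sub("^C", "", label))
      if (n < 1) stop("invalid cyclic order")
      if (n == 1) list() else list(rot_z(2 * pi / n))
    } else if (grepl("^D[0-9]+$", label)) {
      n <- as.integer(sub("^D", "", label))
      if (n < 1) stop("invalid dihedral order")
      list(rot_z(2 * pi / n), rot_axis(c(1, 0, 0), pi))
    } else if (label == "T") {
      list(rot_z(pi), rot_axis(c(1, 1, 1), 2 * pi / 3))
    } else if (label == "O") {
      list(rot_z(pi / 2), rot_axis(c(1, 1, 1), 2 * pi / 3))
    } else if (label == "I") {
      list(rot_z(pi), rot_axis(c(0, 1, phi), 2 * pi / 5))
    } else stop("unknown point-group label: ", label)
  ops <- close_group(gens)
  structure(list(label = label, order = length(ops), ops = ops),
            class = "SymmetryGroup")
}

#' @export
print.SymmetryGroup <- function(x, ...) {
  cat("SymmetryGroup", x$label, "with", x$order, "rotation operator(s)\n")
  invisible(x)
}

## Stack the group operators applied to direction rows: returns a list of
## matrices, one per operator.
apply_ops <- function(dirs, sym) {
  dirs <- rbind(dirs)
  lapply(sym$ops, function(R) dirs %*% t(R))
}

#' Symmetry-aware geodesic distance between projection directions
#'
#' Great-circle angle \code{arccos(p . R q)} minimised over the rotation
#' operators \code{R} of the point group. Antipodal directions are distinct
#' (no handedness identification).
#'
#' @param p,q Unit 3-vectors (or n x 3 matrices; recycled row-wise).
#' @param sym A [symmetry_group()]; default C1 (plain great-circle angle).
#' @return Distance(s) in radians, in [0, pi].
#' @export
geodesic_distance <- function(p, q, sym = symmetry_group("C1")) {
  p <- rbind(p); q <- rbind(q)
  n <- max(nrow(p), nrow(q))
  if (nrow(p) < n) p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  if (nrow(q) < n) q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  best <- rep(Inf, n)
  for (R in sym$ops) {
    dot <- rowSums(p * (q %*% t(R)))
    best <- pmin(best, acos(pmin(1, pmax(-1, dot))))
  }
  best
}

## Full pairwise symmetry-aware distance matrix between rows of a and b
geodesic_cross <- function(a, b, sym) {
  a <- rbind(a); b <- rbind(b)
  best <- matrix(Inf, nrow(a), nrow(b))
  for (R in sym$ops) {
    dot <- a %*% t(b %*% t(R))
    best <- pmin(best, acos(pmin(1, pmax(-1, dot))))
  }
  best
}

#' Canonical asymmetric-unit representative of a direction
#'
#' Among all symmetry images of a direction, picks the one with
#' lexicographically largest (z, x, y) coordinates; this defines the
#' asymmetric unit used for grid construction and random sampling.
#'
#' @param d Unit 3-vector or n x 3 matrix.
#' @param sym A [symmetry_group()].
#' @return Same shape as the input, canonicalised.
#' @export
canonicalize_direction <- function(d, sym) {
  single <- is.null(dim(d))
  d <- rbind(d)
  if (sym$order == 1L) return(if (single) drop(d) else d)
  imgs <- apply_ops(d, sym)     # list over ops of n x 3
  best <- imgs[[1]]
  tol <- 1e-9
  for (k in seq_along(imgs)[-1]) {
    cand <- imgs[[k]]
    # lexicographic (z, x, y) comparison with tolerance
    dz <- cand[, 3] - best[, 3]
    dx <- cand[, 1] - best[, 1]
    dy <- cand[, 2] - best[, 2]
    better <- dz > tol | (abs(dz) <= tol & (dx > tol | (abs(dx) <= tol & dy > tol)))
    best[better, ] <- cand[better, , drop = FALSE]
  }
  if (single) drop(best) else best
}

#' Test membership in the canonical asymmetric unit
#'
#' @inheritParams canonicalize_direction
#' @return Logical vector: TRUE where the direction equals its canonical
#'   representative within 1e-6.
#' @export
in_asymmetric_unit <- function(d, sym) {
  d <- rbind(d)
  rowSums(abs(canonicalize_direction(d, sym) - d)) < 1e-6
}

#' Uniform random directions within the asymmetric unit
#'
#' Draws i.i.d. directions uniform by area on the sphere and maps each to its
#' canonical asymmetric-unit representative (every canonical point has
#' exactly |group| uniform preimages, so the restriction stays uniform).
#'
#' @param n Number of directions.
#' @param sym A [symmetry_group()].
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An n x 3 matrix of unit rows inside the asymmetric unit.
#' @export
random_directions_in_au <- function(n, sym = symmetry_group("C1"), seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    a <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - z^2))
    d <- cbind(x = s * cos(a), y = s * sin(a), z = z)
    canonicalize_direction(d, sym)
  })
}

## Evaluate expr under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Near-uniform grid of projection directions over the asymmetric unit
#'
#' Equal-area spiral (Fibonacci) sampling of the full sphere at an angular
#' pitch close to \code{delta}, filtered to the canonical asymmetric unit.
#' Every point of the asymmetric unit lies within 1.5 delta (symmetry-aware
#' geodesic) of some grid node.
#'
#' @param delta Angular sampling rate in degrees (0 < delta <= 30).
#' @param sym A [symmetry_group()].
#' @return An object of class \code{ProjectionGrid}: list with
#'   \code{directions} (n x 3), \code{delta}, \code{sym_label}.
#' @export
sample_projection_grid <- function(delta = 5, sym = symmetry_group("C1")) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 30)
    stop("invalid angular sampling rate: delta must be in (0, 30] degrees")
  dr <- delta * DEG2RAD
  # hexagonal-packing point count for mean nearest-neighbour spacing ~ delta
  n <- max(12L, as.integer(ceiling(8 * pi / (sqrt(3) * dr^2))))
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  gold <- pi * (3 - sqrt(5))
  a <- gold * (seq_len(n) - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(x = s * cos(a), y = s * sin(a), z = z)
  if (sym$order > 1L) dirs <- dirs[in_asymmetric_unit(dirs, sym), , drop = FALSE]
  structure(list(directions = dirs, delta = delta, sym_label = sym$label),
            class = "ProjectionGrid")
}

#' @export
print.ProjectionGrid <- function(x, ...) {
  cat("ProjectionGrid:", nrow(x$directions), "directions at", x$delta,
      "deg pitch, symmetry", x$sym_label, "\n")
  invisible(x)
}
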