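# Small 3-vector helpers used by the protonation and fixture-template code.
# All take/return plain numeric length-3 vectors; angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg2rad <- function(x) x * pi / 180

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
angle_deg <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place atom D from internal coordinates (NeRF construction)
#'
#' Returns coordinates of atom D bonded to `c` such that |c-D| = `bond`,
#' the angle b-c-D equals `angle` and the dihedral a-b-c-D equals `torsion`.
#' @noRd
place_dihedral <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d_loc <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- vunit(c - b)
  ab <- vunit(b - a)
  n <- vunit(vcross(ab, bc))
  m <- vcross(n, bc)
  c + d_loc[1] * bc + d_loc[2] * m + d_loc[3] * n
}

#' Random rigid transform (rotation + translation) applied to an n x 3 matrix
#' @noRd
apply_rigid <- function(xyz, rot, shift) {
  sweep(xyz %*% t(rot), 2, -shift)
}

#' Rotation matrix from axis (unit vector) and angle in degrees
#' @noRd
rotation_matrix <- function(axis, angle) {
  u <- vunit(axis)
  th <- deg2rad(angle)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Union-find connected components over integer node ids 1..n given an
# edge matrix (2 columns). Returns integer component membership, components
# numbered by first appearance.
components_from_edges <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1])
      rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  match(roots, unique(roots))
}
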