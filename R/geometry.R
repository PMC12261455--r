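#' Distance-geometry primitives
#'
#' Bond lengths, bond angles and torsion angles for four consecutive bonded
#' atoms A-B-C-D can all be written in terms of the six pairwise distances
#' d_AB, d_BC, d_CD, d_AC, d_BD, d_AD. Because pairwise distances are
#' invariant under translation and rotation, so is everything built on them.
#' These are the primitives behind every 3D feature in the package.
#'
#' @name geometry
NULL

# clamp a cosine that may have drifted slightly outside [-1, 1];
# drift beyond `slack` signals genuinely inconsistent distances
clamp_cos <- function(x, slack = 1e-9) {
  if (is.na(x)) return(x)
  if (x > 1 + slack || x < -1 - slack) {
    stop(sprintf("cosine %g outside [-1, 1] beyond tolerance: inconsistent distances", x),
         call. = FALSE)
  }
  min(1, max(-1, x))
}

#' Euclidean distance between two 3D points
#'
#' @param p,q numeric length-3 coordinate vectors (Angstrom).
#' @return nonnegative distance in Angstrom.
#' @export
pairwise_distance <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Bond angle cosine from three distances
#'
#' The cosine of the angle at B in the triple A-B-C, by the law of cosines:
#' `(d_ab^2 + d_bc^2 - d_ac^2) / (2 d_ab d_bc)`. Values within 1e-9 of the
#' boundary are clamped to `[-1, 1]`; values farther outside raise an error
#' (the three distances do not form a triangle).
#'
#' @param d_ab,d_bc the two bond lengths at the vertex (must be > 0).
#' @param d_ac the opposite distance.
#' @return cosine in `[-1, 1]`.
#' @examples
#' bond_angle_cos(1, 1, sqrt(2)) # right angle -> 0
#' @export
bond_angle_cos <- function(d_ab, d_bc, d_ac) {
  if (d_ab <= 0 || d_bc <= 0) {
    stop("bond lengths must be positive", call. = FALSE)
  }
  clamp_cos((d_ab^2 + d_bc^2 - d_ac^2) / (2 * d_ab * d_bc))
}

#' Torsion cosine from six pairwise distances
#'
#' Computes the cosine of the torsion (dihedral) angle of the bonded chain
#' A-B-C-D from the six pairwise distances alone, without coordinates.
#' Writing theta1 for the bond angle A-B-C and theta2 for B-C-D, the
#' perpendicular offsets of A and D from the B-C axis are
#' `rho_A = d_ab sin(theta1)` and `rho_D = d_cd sin(theta2)`, and the axial
#' positions are fixed by the law of cosines; expanding `d_ad^2` then gives
#' `cos(phi) = U / L` with
#' `U = rho_A^2 + rho_D^2 + (x_A - x_D)^2 - d_ad^2` and
#' `L = 2 rho_A rho_D`. The convention matches the usual plane-normal
#' dihedral: a planar cis chain (A and D on the same side) has
#' `cos(phi) = 1`, a planar trans chain -1. When either bonded triple is
#' collinear (`L` below `tol`) the torsion is undefined and `defined` is
#' `FALSE` rather than an error, so callers can choose a policy.
#'
#' Note that the cosine alone cannot distinguish +phi from -phi: mirror-image
#' (enantiomeric) conformers yield identical values. This is inherent to any
#' distance-only description.
#'
#' @param d_ab,d_bc,d_cd,d_ac,d_bd,d_ad the six pairwise distances.
#' @param tol degeneracy tolerance on `L`.
#' @return list with `cos_phi` (`NA` when undefined), `U`, `L`, `defined`.
#' @examples
#' # planar cis quadruple A=(0,1,0) B=(0,0,0) C=(1,0,0) D=(1,1,0)
#' torsion_cos_distances(1, 1, 1, sqrt(2), sqrt(2), 1)$cos_phi # 1
#' @export
torsion_cos_distances <- function(d_ab, d_bc, d_cd, d_ac, d_bd, d_ad,
                                  tol = 1e-12) {
  stopifnot(d_ab > 0, d_bc > 0, d_cd > 0, d_ac > 0, d_bd > 0, d_ad > 0)
  cos1 <- bond_angle_cos(d_ab, d_bc, d_ac)       # angle at B (A-B-C)
  cos2 <- bond_angle_cos(d_bc, d_cd, d_bd)       # angle at C (B-C-D)
  rho_a <- d_ab * sqrt(max(0, 1 - cos1^2))
  rho_d <- d_cd * sqrt(max(0, 1 - cos2^2))
  # axial coordinates along B->C
  x_a <- (d_ab^2 + d_bc^2 - d_ac^2) / (2 * d_bc)
  x_d <- (d_bc^2 + d_bd^2 - d_cd^2) / (2 * d_bc)
  u <- rho_a^2 + rho_d^2 + (x_a - x_d)^2 - d_ad^2
  l <- 2 * rho_a * rho_d
  if (l <= tol) {
    return(list(cos_phi = NA_real_, U = u, L = l, defined = FALSE))
  }
  list(cos_phi = clamp_cos(u / l), U = u, L = l, defined = TRUE)
}

#' Torsion cosine from coordinates (plane-normal oracle)
#'
#' The textbook dihedral: cosine of the angle between the normal of plane
#' A-B-C and the normal of plane B-C-D, computed with cross products on the
#' raw coordinates. Serves as an independent check of
#' [torsion_cos_distances()].
#'
#' @param p_a,p_b,p_c,p_d length-3 coordinate vectors.
#' @return cosine, or `NA` if either atom triple is collinear.
#' @export
torsion_cos_vector <- function(p_a, p_b, p_c, p_d) {
  cross <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  n1 <- cross(p_b - p_a, p_c - p_b)
  n2 <- cross(p_c - p_b, p_d - p_c)
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) return(NA_real_)
  clamp_cos(sum(n1 * n2) / (l1 * l2))
}

#' Full distance geometry of a four-atom chain
#'
#' Packages the six pairwise distances of a bonded quadruple A-B-C-D together
#' with the two bond-angle cosines and the torsion cosine (with its
#' numerator U and denominator L) as one tidy row.
#'
#' @param coords 4 x 3 matrix of coordinates for A, B, C, D in chain order.
#' @return one-row tibble with columns `d_ab`, `d_bc`, `d_cd`, `d_ac`,
#'   `d_bd`, `d_ad`, `cos_theta1`, `cos_theta2`, `cos_phi`, `U`, `L`,
#'   `defined`.
#' @examples
#' quadruple_geometry(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
#' @export
quadruple_geometry <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  d <- function(i, j) pairwise_distance(coords[i, ], coords[j, ])
  d_ab <- d(1, 2); d_bc <- d(2, 3); d_cd <- d(3, 4)
  d_ac <- d(1, 3); d_bd <- d(2, 4); d_ad <- d(1, 4)
  tors <- torsion_cos_distances(d_ab, d_bc, d_cd, d_ac, d_bd, d_ad)
  tibble::tibble(
    d_ab = d_ab, d_bc = d_bc, d_cd = d_cd,
    d_ac = d_ac, d_bd = d_bd, d_ad = d_ad,
    cos_theta1 = bond_angle_cos(d_ab, d_bc, d_ac),
    cos_theta2 = bond_angle_cos(d_bc, d_cd, d_bd),
    cos_phi = tors$cos_phi, U = tors$U, L = tors$L,
    defined = tors$defined
  )
}
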