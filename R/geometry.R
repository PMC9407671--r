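# Low-level 3D geometry: vectors, dihedrals, internal-to-Cartesian backbone
# construction, optimal superposition, and neighbor search.
#
# All coordinates are in Angstrom; all user-facing angles in degrees.

`%||%` <- function(a, b) if (is.null(a)) b else a

DEG <- pi / 180

## Ideal peptide geometry (Engh-Huber-style averages).
PEPTIDE_GEOMETRY <- list(
  b_n_ca  = 1.458, # N-CA bond
  b_ca_c  = 1.525, # CA-C bond
  b_c_n   = 1.329, # C-N peptide bond
  b_c_o   = 1.231, # C=O bond
  a_n_ca_c = 111.2,
  a_ca_c_n = 116.2,
  a_c_n_ca = 121.7,
  a_ca_c_o = 120.5
)

## Ideal backbone dihedrals used for regular secondary structure.
IDEAL_DIHEDRALS <- list(
  helix  = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle, in degrees in (-180, 180], about the b2 axis of the
#' points p1-p2-p3-p4 (IUPAC sign convention).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(unit_vec(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  v1 <- unit_vec(p1 - p2)
  v2 <- unit_vec(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms a-b-c, returns the position d such that
#' |c-d| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) = torsion.
#'
#' @param a,b,c Numeric 3-vectors of already-placed atoms.
#' @param bond Bond length c-d (Angstrom).
#' @param angle Bond angle b-c-d (degrees).
#' @param torsion Dihedral a-b-c-d (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * DEG
  tor <- torsion * DEG
  bc <- unit_vec(c - b)
  n <- unit_vec(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized peptide backbone from dihedral angles
#'
#' Constructs N/CA/C/O coordinates residue by residue with ideal bond lengths
#' and angles, given per-residue phi/psi (and optional omega) dihedrals.
#' `phi[1]` is unused (undefined for the first residue); `psi[n]` only
#' orients the final carbonyl.
#'
#' @param phi,psi Numeric vectors of equal length n (degrees).
#' @param omega Peptide-bond dihedrals, length n (last entry unused);
#'   defaults to trans (180).
#' @return A `backbone` object: list of n x 3 matrices `N`, `CA`, `C`, `O`.
#' @export
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  if (is.null(omega)) omega <- rep(180, n)
  g <- PEPTIDE_GEOMETRY
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(g$a_n_ca_c * DEG), sin(g$a_n_ca_c * DEG), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, omega[i - 1])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  structure(list(N = N, CA = CA, C = C, O = O), class = "backbone")
}

#' Number of residues in a backbone
#' @param bb A `backbone` object.
#' @export
n_res <- function(bb) nrow(bb$CA)

#' Backbone phi/psi dihedrals
#'
#' @param bb A `backbone` object.
#' @return Data frame with columns `phi`, `psi` (degrees; NA where undefined,
#'   i.e. phi of the first and psi of the last residue).
#' @export
backbone_dihedrals <- function(bb) {
  n <- n_res(bb)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in seq_len(n)) {
      if (i > 1) {
        phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      }
      if (i < n) {
        psi[i] <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
      }
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Flatten a backbone to a coordinate matrix
#'
#' @param bb A `backbone` object.
#' @param atoms Which backbone atoms, in per-residue order.
#' @return (n_res * length(atoms)) x 3 matrix, residues in order, atoms in
#'   the requested order within each residue.
#' @export
backbone_coords <- function(bb, atoms = c("N", "CA", "C", "O")) {
  n <- n_res(bb)
  out <- matrix(NA_real_, n * length(atoms), 3)
  for (i in seq_len(n)) {
    for (k in seq_along(atoms)) {
      out[(i - 1) * length(atoms) + k, ] <- bb[[atoms[k]]][i, ]
    }
  }
  out
}

backbone_from_coords <- function(xyz, atoms = c("N", "CA", "C", "O")) {
  na <- length(atoms)
  stopifnot(nrow(xyz) %% na == 0)
  n <- nrow(xyz) / na
  bb <- lapply(seq_along(atoms), function(k) xyz[seq(k, by = na, length.out = n), , drop = FALSE])
  names(bb) <- atoms
  structure(bb, class = "backbone")
}

#' Rebuild backbone amide hydrogens geometrically
#'
#' Places each amide H 1.01 Angstrom from N, in the peptide plane, anti to
#' the preceding carbonyl carbon (the bisector construction). The first
#' residue (no preceding C') gets NA.
#'
#' @param bb A `backbone` object.
#' @return n x 3 matrix of H positions (row 1 is NA).
#' @export
rebuild_amide_h <- function(bb) {
  n <- n_res(bb)
  H <- matrix(NA_real_, n, 3)
  if (n >= 2) {
    for (i in 2:n) {
      d <- unit_vec(bb$N[i, ] - bb$C[i - 1, ]) + unit_vec(bb$N[i, ] - bb$CA[i, ])
      H[i, ] <- bb$N[i, ] + 1.01 * unit_vec(d)
    }
  }
  H
}

#' Virtual C-beta positions from backbone geometry
#'
#' Standard tetrahedral construction from N, CA, C. Used for residue-level
#' contact scoring; glycine callers should substitute CA.
#'
#' @param bb A `backbone` object.
#' @return n x 3 matrix of idealized CB positions.
#' @export
virtual_cbeta <- function(bb) {
  n <- n_res(bb)
  CB <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ca <- bb$CA[i, ]
    v1 <- ca - bb$N[i, ]
    v2 <- bb$C[i, ] - ca
    a <- vcross(v1, v2)
    # standard virtual-CB construction (L-amino-acid chirality)
    CB[i, ] <- ca - 0.58273431 * a + 0.56802827 * v1 - 0.54067466 * v2
  }
  CB
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `mobile` onto `target`,
#' with a proper rotation enforced (no reflection).
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows, n >= 3.
#' @return List with `transform` (a `rigid_transform`: 3x3 `rotation`,
#'   3-vector `translation`) and `rmsd` (Angstrom) of the superposed points.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3) {
    stop("mobile and target must be n x 3 matrices with equal n")
  }
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  mc <- colMeans(mobile)
  tc <- colMeans(target)
  P <- sweep(mobile, 2, mc)
  Q <- sweep(target, 2, tc)
  H <- t(P) %*% Q
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-8)) {
    stop("degenerate (collinear) point set: rotation is not determined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(tc - R %*% mc)
  moved <- sweep(mobile %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric 3-vector (Angstrom).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9) stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix (or `backbone`).
#' @param tf A `rigid_transform`.
#' @export
apply_transform <- function(xyz, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(xyz, "backbone")) {
    out <- lapply(unclass(xyz), function(m) apply_transform(m, tf))
    return(structure(out, class = "backbone"))
  }
  sweep(as.matrix(xyz) %*% t(tf$rotation), 2, tf$translation, "+")
}

invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

compose_transform <- function(tf2, tf1) {
  # returns the transform equivalent to applying tf1 first, then tf2
  rigid_transform(tf2$rotation %*% tf1$rotation,
                  as.numeric(tf2$rotation %*% tf1$translation) + tf2$translation)
}

## Rotation matrix taking direction a to direction b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  v <- vcross(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) vcross(a, c(1, 0, 0)) else vcross(a, c(0, 1, 0))
    p <- unit_vec(p)
    return(2 * outer(p, p) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / sum(v * v))
}

#' Radius of gyration of a coordinate set
#' @param xyz n x 3 matrix.
#' @export
radius_of_gyration <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' All atom pairs within a distance cutoff (cell-list search)
#'
#' Finds every pair (i in A, j in B) with distance <= cutoff using a spatial
#' grid of cell size `cutoff`; results are identical to the all-pairs scan.
#'
#' @param a,b n x 3 coordinate matrices.
#' @param cutoff Distance cutoff (Angstrom).
#' @return Data frame with columns `i`, `j`, `d`.
#' @export
neighbor_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(cutoff > 0)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  cell <- cutoff
  ka <- floor(a / cell)
  kb <- floor(b / cell)
  keyb <- paste(kb[, 1], kb[, 2], kb[, 3])
  bcells <- split(seq_len(nrow(b)), keyb)
  keya <- paste(ka[, 1], ka[, 2], ka[, 3])
  acells <- split(seq_len(nrow(a)), keya)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  for (cellkey in names(acells)) {
    ia <- acells[[cellkey]]
    cc <- ka[ia[1], ]
    nbr_keys <- paste(cc[1] + offs[, 1], cc[2] + offs[, 2], cc[3] + offs[, 3])
    ib <- unlist(bcells[nbr_keys], use.names = FALSE)
    if (length(ib) == 0) next
    dx <- outer(a[ia, 1], b[ib, 1], "-")
    dy <- outer(a[ia, 2], b[ib, 2], "-")
    dz <- outer(a[ia, 3], b[ib, 3], "-")
    d2 <- dx * dx + dy * dy + dz * dz
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      k <- k + 1L
      out_i[[k]] <- ia[hit[, 1]]
      out_j[[k]] <- ib[hit[, 2]]
      out_d[[k]] <- sqrt(d2[hit])
    }
  }
  if (k == 0L) return(empty)
  data.frame(i = unlist(out_i), j = unlist(out_j), d = unlist(out_d))
}
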