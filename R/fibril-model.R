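# Fibril assembly model: ordered layers per protofilament, the screw
# operator (rise/twist) relating consecutive layers, the virtual "next
# layer" a capping design must occupy, and dihedral-based secondary
# structure.

#' Construct a screw-symmetry operator
#'
#' The layer-to-layer operator of a fibril: a rotation by `twist` about an
#' axis through `axis_point` along `axis_dir`, followed by a translation of
#' `rise` along the axis.
#'
#' @param rise Axial rise (Angstrom, signed along `axis_dir`).
#' @param twist Twist (degrees, in (-180, 180]).
#' @param axis_point A point on the axis.
#' @param axis_dir Unit axis direction.
#' @param rmsd Residual rmsd of the superposition the operator was fitted
#'   from (NA for constructed operators).
#' @export
screw_symmetry <- function(rise, twist, axis_point = c(0, 0, 0),
                           axis_dir = c(0, 0, 1), rmsd = NA_real_) {
  axis_dir <- as.numeric(axis_dir)
  stopifnot(is.finite(rise), is.finite(twist), length(axis_dir) == 3)
  if (abs(vnorm(axis_dir) - 1) > 1e-9) stop("axis_dir must be a unit vector")
  if (twist <= -180 || twist > 180) {
    twist <- ((twist + 180) %% 360) - 180
    if (twist == -180) twist <- 180
  }
  structure(list(rise = rise, twist = twist,
                 axis_point = as.numeric(axis_point),
                 axis_dir = axis_dir, rmsd = rmsd),
            class = "screw_symmetry")
}

#' @export
print.screw_symmetry <- function(x, ...) {
  cat(sprintf("screw_symmetry: rise %.3f A, twist %.3f deg (fit rmsd %s)\n",
              x$rise, x$twist,
              if (is.na(x$rmsd)) "NA" else sprintf("%.2e", x$rmsd)))
  invisible(x)
}

rodrigues_rotation <- function(axis, angle_deg) {
  u <- unit_vec(as.numeric(axis))
  th <- angle_deg * DEG
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Screw operator (or its k-th power) as a rigid transform
#'
#' @param sym A `screw_symmetry`.
#' @param k Integer power; negative applies the inverse operator.
#' @return A `rigid_transform`.
#' @export
screw_transform <- function(sym, k = 1) {
  R <- rodrigues_rotation(sym$axis_dir, k * sym$twist)
  p <- sym$axis_point
  tr <- p - as.numeric(R %*% p) + k * sym$rise * sym$axis_dir
  rigid_transform(R, tr)
}

#' Fit the screw symmetry relating two fibril layers
#'
#' Computes the least-squares rigid transform mapping the backbone of
#' `layer_i` onto `layer_j`, then decomposes it into an axis, a twist about
#' the axis and a rise along it. The axis is oriented so that the rise is
#' non-negative (the operator maps layer i "up" to layer j).
#'
#' For near-zero twist (< 0.1 degrees) the rotation axis is numerically
#' undefined; the translation direction is used as the axis.
#'
#' @param layer_i,layer_j `backbone` objects (or n x 3 matrices of matched
#'   backbone atoms) with equal residue counts.
#' @return A `screw_symmetry` with the residual superposition `rmsd`.
#' @export
fit_screw_symmetry <- function(layer_i, layer_j) {
  X <- if (inherits(layer_i, "backbone")) backbone_coords(layer_i) else as.matrix(layer_i)
  Y <- if (inherits(layer_j, "backbone")) backbone_coords(layer_j) else as.matrix(layer_j)
  if (nrow(X) != nrow(Y)) stop("layers have mismatched backbone atom counts")
  fit <- kabsch_superpose(X, Y)
  R <- fit$transform$rotation
  t <- fit$transform$translation
  cos_th <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_th) / DEG
  # For noisy data at small twist the rotation-axis extraction amplifies
  # coordinate noise (the axis of a ~1 degree rotation is poorly
  # determined), while the translation direction deviates from the true
  # axis only by ~theta * r_lateral / rise. Use the translation direction
  # whenever the superposition shows real noise and the twist is small;
  # the exact decomposition is kept for (near-)noiseless data.
  if (fit$rmsd > 1e-4 && theta < 5 && vnorm(t) > 0.5) {
    u <- unit_vec(t)
    av <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    twist <- atan2(sum(av * u) / 2, cos_th) / DEG
    rise <- sum(t * u)
    if (rise < 0) { u <- -u; rise <- -rise; twist <- -twist }
    return(screw_symmetry(rise, twist, colMeans(X), u, fit$rmsd))
  }
  if (theta < 0.1) {
    if (vnorm(t) < 1e-12) {
      u <- c(0, 0, 1)  # identity operator; axis arbitrary
    } else {
      u <- unit_vec(t)
    }
    av <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    twist <- if (vnorm(av) < 1e-12) 0 else theta * sign(sum(av * u) + 1e-300)
    rise <- sum(t * u)
    if (rise < 0) { u <- -u; rise <- -rise; twist <- -twist }
    return(screw_symmetry(rise, twist, colMeans(X), u, fit$rmsd))
  }
  if (theta > 179) {
    e <- eigen(R)
    j <- which.min(abs(Re(e$values) - 1))
    u <- unit_vec(Re(e$vectors[, j]))
  } else {
    u <- unit_vec(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  twist <- theta
  rise <- sum(t * u)
  if (rise < 0) { u <- -u; rise <- -rise; twist <- -twist }
  # axis point: minimum-norm solution of (I - R) p = t_perp
  t_perp <- t - rise * u
  A <- diag(3) - R
  s <- svd(A)
  dinv <- ifelse(s$d > 1e-9 * max(s$d), 1 / s$d, 0)
  p <- as.numeric(s$v %*% (dinv * (t(s$u) %*% t_perp)))
  screw_symmetry(rise, twist, p, u, fit$rmsd)
}

#' Group fibril chains into ordered protofilaments
#'
#' Clusters the chains of a fibril structure into protofilaments and orders
#' each bottom-to-top along the fibril axis. Chains are first grouped by
#' sequence identity; the axis is taken from the screw fit of the closest
#' stacking-compatible chain pair (twist below `max_stack_twist`); chains
#' are then split into protofilaments by their lateral (off-axis) position
#' and ordered by their axial projection.
#'
#' @param model A `structure_model` with at least two identical-sequence
#'   chains.
#' @param chain_groups Optional explicit grouping: list of chain-id vectors,
#'   one per protofilament (bypasses the clustering).
#' @param rmsd_threshold Maximum backbone rmsd (Angstrom) for two chains to
#'   count as conformationally identical layers.
#' @param lateral_threshold Lateral distance (Angstrom) cut for splitting
#'   protofilaments.
#' @param max_stack_twist Largest |twist| (degrees) regarded as layer
#'   stacking when choosing the axis-defining pair.
#' @return A `fibril_assembly`: protofilaments (ordered chain-id vectors),
#'   per-protofilament `screw_symmetry`, and the model.
#' @export
group_layers <- function(model, chain_groups = NULL, rmsd_threshold = 2.0,
                         lateral_threshold = 5.0, max_stack_twist = 30) {
  chains <- chain_ids(model)
  bbs <- lapply(chains, function(ch) chain_backbone(model, ch))
  names(bbs) <- chains
  seqs <- vapply(chains, function(ch) chain_sequence(model, ch), "")
  keep <- seqs %in% names(which(table(seqs) >= 2))
  if (sum(keep) < 2) stop("cannot infer fibril layers: fewer than 2 chains with identical sequences")
  chains <- chains[keep]; seqs <- seqs[keep]; bbs <- bbs[keep]

  if (is.null(chain_groups)) {
    cents <- t(vapply(bbs, function(b) colMeans(b$bb$CA), numeric(3)))
    # axis from the closest same-sequence pair that stacks (small twist)
    best <- NULL; best_d <- Inf
    for (i in seq_along(chains)) {
      for (j in seq_along(chains)) {
        if (j <= i || seqs[i] != seqs[j]) next
        if (nrow(bbs[[i]]$bb$CA) != nrow(bbs[[j]]$bb$CA)) next
        d <- vnorm(cents[i, ] - cents[j, ])
        if (d < best_d) {
          sym <- fit_screw_symmetry(bbs[[i]]$bb, bbs[[j]]$bb)
          if (abs(sym$twist) <= max_stack_twist && sym$rmsd <= rmsd_threshold &&
              sym$rise > 0.5) {
            best <- sym; best_d <- d
          }
        }
      }
    }
    if (is.null(best)) stop("cannot infer fibril axis: no stacking-compatible chain pair found")
    u <- best$axis_dir
    ctr <- colMeans(cents)
    s <- as.numeric((cents - matrix(ctr, nrow(cents), 3, byrow = TRUE)) %*% u)
    lat <- cents - matrix(ctr, nrow(cents), 3, byrow = TRUE) - outer(s, u)
    groups <- if (length(chains) == 2) {
      if (vnorm(lat[1, ] - lat[2, ]) <= lateral_threshold) c(1L, 1L) else c(1L, 2L)
    } else {
      stats::cutree(stats::hclust(stats::dist(lat), method = "single"),
                    h = lateral_threshold)
    }
    chain_groups <- lapply(sort(unique(groups)), function(g) {
      ids <- chains[groups == g]
      ids[order(s[groups == g])]
    })
  } else {
    sym0 <- fit_screw_symmetry(bbs[[chain_groups[[1]][1]]]$bb,
                               bbs[[chain_groups[[1]][2]]]$bb)
    u <- sym0$axis_dir
  }

  pf_syms <- vector("list", length(chain_groups))
  for (g in seq_along(chain_groups)) {
    ids <- chain_groups[[g]]
    if (length(ids) < 2) stop("protofilament with fewer than 2 layers: ", paste(ids, collapse = ","))
    sym <- fit_screw_symmetry(bbs[[ids[1]]]$bb, bbs[[ids[2]]]$bb)
    if (sum(sym$axis_dir * u) < 0) {
      # orient all protofilament operators consistently with the global axis
      sym <- screw_symmetry(-sym$rise, -sym$twist, sym$axis_point,
                            -sym$axis_dir, sym$rmsd)
    }
    pf_syms[[g]] <- sym
  }
  structure(list(protofilaments = chain_groups, symmetry = pf_syms,
                 model = model),
            class = "fibril_assembly")
}

#' @export
print.fibril_assembly <- function(x, ...) {
  cat(sprintf("fibril_assembly: %d protofilament(s)\n", length(x$protofilaments)))
  for (g in seq_along(x$protofilaments)) {
    s <- x$symmetry[[g]]
    cat(sprintf("  pf %d: %d layers [%s], rise %.3f A, twist %.3f deg\n",
                g, length(x$protofilaments[[g]]),
                paste(x$protofilaments[[g]], collapse = ","),
                s$rise, s$twist))
  }
  invisible(x)
}

#' Consensus screw symmetry along a protofilament
#'
#' Fits the screw operator for every consecutive layer pair of a
#' protofilament and averages rise and twist (axis and axis point from the
#' first pair). For noisy structures this pools the information of all
#' layer pairs instead of relying on a single one.
#'
#' @param assembly A `fibril_assembly`.
#' @param protofilament Protofilament index.
#' @return A `screw_symmetry` with extra fields `rise_sd`, `twist_sd`,
#'   `n_pairs`.
#' @export
consensus_symmetry <- function(assembly, protofilament = 1) {
  ids <- assembly$protofilaments[[protofilament]]
  ref <- assembly$symmetry[[protofilament]]
  rises <- twists <- numeric(length(ids) - 1)
  first <- NULL
  for (k in seq_len(length(ids) - 1)) {
    sym <- fit_screw_symmetry(chain_backbone(assembly$model, ids[k])$bb,
                              chain_backbone(assembly$model, ids[k + 1])$bb)
    if (sum(sym$axis_dir * ref$axis_dir) < 0) {
      sym <- screw_symmetry(-sym$rise, -sym$twist, sym$axis_point,
                            -sym$axis_dir, sym$rmsd)
    }
    if (is.null(first)) first <- sym
    rises[k] <- sym$rise; twists[k] <- sym$twist
  }
  out <- screw_symmetry(mean(rises), mean(twists), first$axis_point,
                        first$axis_dir, first$rmsd)
  out$rise_sd <- stats::sd(rises)
  out$twist_sd <- stats::sd(twists)
  out$n_pairs <- length(rises)
  out
}

#' Generate the virtual next layer at a fibril end
#'
#' Applies the protofilament's screw operator to the tip layer (or its
#' inverse at the minus end), producing the coordinates a new monomer -- or
#' a capping inhibitor's strand -- would occupy.
#'
#' @param assembly A `fibril_assembly`.
#' @param protofilament Protofilament index (1-based).
#' @param end `"plus"` (largest axial projection) or `"minus"`.
#' @return A single-chain `structure_model` (chain id `"v"`).
#' @export
virtual_next_layer <- function(assembly, protofilament = 1, end = c("plus", "minus")) {
  end <- match.arg(end)
  if (protofilament < 1 || protofilament > length(assembly$protofilaments)) {
    stop("unknown protofilament: ", protofilament)
  }
  ids <- assembly$protofilaments[[protofilament]]
  sym <- assembly$symmetry[[protofilament]]
  tip <- if (end == "plus") ids[length(ids)] else ids[1]
  k <- if (end == "plus") 1 else -1
  at <- chain_atoms(assembly$model, tip)
  xyz <- apply_transform(as.matrix(at[, c("x", "y", "z")]), screw_transform(sym, k))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$chain <- "v"
  structure_model(at, source = sprintf("virtual layer (%s end, pf %d)", end, protofilament))
}

## Dihedral basins for secondary-structure assignment (degrees).
in_helix_basin <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 & psi > -80 & psi < -5
}
in_strand_basin <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi > -180 & phi < -90 &
    ((psi > 90 & psi <= 180) | (psi >= -180 & psi < -170))
}

#' Assign secondary structure from backbone dihedrals
#'
#' Labels each residue H (helix), E (strand) or L (loop/other) from its
#' phi/psi dihedrals, then relabels runs shorter than a minimum length
#' (`min_h` for H, `min_e` for E) as L. Terminal residues with undefined
#' dihedrals are L. A simple, testable convention; no hydrogen-bond pattern
#' (DSSP-style) assignment is attempted.
#'
#' @param bb A `backbone` object (e.g. from [chain_backbone()]).
#' @param min_h,min_e Minimum run lengths kept as H / E.
#' @return Character vector of per-residue labels in \{H, E, L\}.
#' @export
assign_secondary_structure <- function(bb, min_h = 4, min_e = 3) {
  n <- n_res(bb)
  if (n < 3) return(rep("L", n))
  d <- backbone_dihedrals(bb)
  lab <- rep("L", n)
  lab[in_helix_basin(d$phi, d$psi)] <- "H"
  lab[in_strand_basin(d$phi, d$psi)] <- "E"
  smooth_ss_runs(lab, min_h = min_h, min_e = min_e)
}

smooth_ss_runs <- function(lab, min_h = 4, min_e = 3) {
  r <- rle(lab)
  drop <- (r$values == "H" & r$lengths < min_h) |
          (r$values == "E" & r$lengths < min_e)
  r$values[drop] <- "L"
  inverse.rle(r)
}

#' Contiguous runs of a secondary-structure label
#'
#' @param ss Character vector of H/E/L labels.
#' @param label Which label to extract runs of.
#' @return Data frame with `start`, `end`, `length` (1-based residue indices).
#' @export
ss_runs <- function(ss, label = "E") {
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values == label
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}
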