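# Funnel scoring of docked poses: backbone hydrogen-bond satisfaction at
# the fibril tip, interface atom counts, a residue-contact binding-energy
# surrogate (ddg), dihedral-based residue propensity (p_aa_p), greedy
# interface sequence optimization, point-mutation rescoring, and design
# ranking.

CENTROID_HARD_DIST <- 1.8   # deep overlap of a centroid blob, Angstrom
HBOND_DIST_CUTOFF <- 3.5    # N...O, Angstrom
HBOND_ANGLE_CUTOFF <- 120   # N-H...O angle at H, degrees
INTERFACE_CUTOFF <- 5.0     # Angstrom
CONTACT_CUTOFF <- 8.0       # CB-CB, Angstrom

pkg_table_env <- new.env(parent = emptyenv())

load_pkg_table <- function(name, loader) {
  if (is.null(pkg_table_env[[name]])) {
    path <- system.file("extdata", name, package = "fibrilcap")
    if (!nzchar(path)) stop("packaged table not found: ", name)
    pkg_table_env[[name]] <- loader(path)
  }
  pkg_table_env[[name]]
}

#' Packaged residue-pair contact potential
#'
#' Symmetric 20x20 table of dimensionless contact energies (lower = more
#' favorable) used as the binding-energy surrogate. Shipped as a versioned
#' data file so it can be swapped.
#'
#' @param path Optional path to an alternative table (TSV: `aa` column +
#'   one column per residue).
#' @return Named 20x20 matrix.
#' @export
contact_table <- function(path = NULL) {
  loader <- function(p) {
    df <- utils::read.delim(p, comment.char = "#", check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$aa
    if (max(abs(m - t(m))) > 1e-8) stop("contact table is not symmetric")
    m
  }
  if (!is.null(path)) return(loader(path))
  load_pkg_table("contact_potential_v1.tsv", loader)
}

#' Packaged centroid side-chain model parameters
#'
#' Per-residue effective centroid radius and CA->centroid extension
#' (Angstrom) for the single-pseudo-atom side-chain model.
#'
#' @return Data frame with `aa`, `radius`, `ca_cb_ext`.
#' @export
centroid_params <- function() {
  load_pkg_table("centroid_radii_v1.tsv", function(p) {
    utils::read.delim(p, comment.char = "#")
  })
}

#' Packaged backbone-dihedral residue propensity table
#'
#' P(amino acid | coarse Ramachandran bin), one column per bin
#' (alphaR, beta, alphaL, ppii, other), each summing to one.
#'
#' @return Matrix (20 residues x 5 bins).
#' @export
propensity_table <- function() {
  load_pkg_table("dihedral_propensity_v1.tsv", function(p) {
    df <- utils::read.delim(p, comment.char = "#", check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$aa
    m
  })
}

#' Coarse Ramachandran bin of a phi/psi pair
#'
#' Five bins: right-handed alpha (`alphaR`), beta sheet (`beta`),
#' left-handed alpha (`alphaL`), polyproline-II (`ppii`) and `other`.
#' Returns NA for undefined (terminal) dihedrals.
#'
#' @param phi,psi Dihedrals in degrees.
#' @return Character vector of bin names.
#' @export
rama_bin <- function(phi, psi) {
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  out[ok] <- "other"
  aR <- ok & phi > -140 & phi < -30 & psi > -80 & psi < 30
  be <- ok & phi >= -180 & phi <= -90 & (psi >= 90 | psi <= -150)
  pp <- ok & phi > -90 & phi < -30 & psi >= 90 & psi <= 180
  aL <- ok & phi > 30 & phi < 100 & psi > -30 & psi < 80
  out[be] <- "beta"; out[pp] <- "ppii"; out[aR] <- "alphaR"; out[aL] <- "alphaL"
  out
}

## Per-residue backbone frame table for one or more chains of a model:
## coordinates of N/CA/C/O plus the rebuilt amide H (NA for chain-initial
## residues), residue identity and chain bookkeeping.
residue_frames <- function(model, chains = NULL) {
  if (is.null(chains)) chains <- chain_ids(model)
  parts <- lapply(chains, function(ch) {
    cb <- chain_backbone(model, ch)
    H <- rebuild_amide_h(cb$bb)
    n <- n_res(cb$bb)
    list(df = data.frame(chain = ch, resno = cb$resno, resid = cb$resid,
                         pos = seq_len(n)),
         N = cb$bb$N, CA = cb$bb$CA, C = cb$bb$C, O = cb$bb$O, H = H)
  })
  structure(list(
    df = do.call(rbind, lapply(parts, `[[`, "df")),
    N = do.call(rbind, lapply(parts, `[[`, "N")),
    CA = do.call(rbind, lapply(parts, `[[`, "CA")),
    C = do.call(rbind, lapply(parts, `[[`, "C")),
    O = do.call(rbind, lapply(parts, `[[`, "O")),
    H = do.call(rbind, lapply(parts, `[[`, "H"))
  ), class = "residue_frames")
}

frames_subset <- function(fr, keep) {
  structure(list(df = fr$df[keep, , drop = FALSE],
                 N = fr$N[keep, , drop = FALSE], CA = fr$CA[keep, , drop = FALSE],
                 C = fr$C[keep, , drop = FALSE], O = fr$O[keep, , drop = FALSE],
                 H = fr$H[keep, , drop = FALSE]), class = "residue_frames")
}

#' Detect backbone-backbone hydrogen bonds
#'
#' A bond is reported between a donor amide (N-H) and an acceptor carbonyl
#' O when the N...O distance is at most 3.5 Angstrom and the N-H...O angle
#' at the hydrogen is at least 120 degrees. Amide hydrogens are rebuilt
#' geometrically (1.01 Angstrom from N, in the peptide plane, anti to the
#' preceding C'). Proline and chain-initial residues do not donate. Each
#' donor keeps one acceptor: the closest (ties: lower residue index).
#' Donor/acceptor pairs on the same chain within two sequence positions
#' are excluded.
#'
#' @param donors,acceptors `residue_frames` (from the same or different
#'   molecules).
#' @param dist_cutoff,angle_cutoff Geometric criteria.
#' @return Data frame: donor/acceptor chain, residue number and frame row,
#'   distance (Angstrom), angle (degrees).
#' @export
detect_backbone_hbonds <- function(donors, acceptors,
                                   dist_cutoff = HBOND_DIST_CUTOFF,
                                   angle_cutoff = HBOND_ANGLE_CUTOFF) {
  can_donate <- donors$df$resid != "PRO" & !is.na(donors$H[, 1])
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_row = integer(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0), acceptor_row = integer(0),
                      distance = numeric(0), angle = numeric(0))
  if (!any(can_donate)) return(empty)
  dsub <- which(can_donate)
  pr <- neighbor_pairs(donors$N[dsub, , drop = FALSE], acceptors$O, dist_cutoff)
  if (nrow(pr) == 0) return(empty)
  pr$i <- dsub[pr$i]
  same_chain <- donors$df$chain[pr$i] == acceptors$df$chain[pr$j]
  near_seq <- same_chain & abs(donors$df$pos[pr$i] - acceptors$df$pos[pr$j]) <= 2
  pr <- pr[!near_seq, , drop = FALSE]
  if (nrow(pr) == 0) return(empty)
  ang <- vapply(seq_len(nrow(pr)), function(k) {
    bond_angle(donors$N[pr$i[k], ], donors$H[pr$i[k], ], acceptors$O[pr$j[k], ])
  }, 0)
  pr <- pr[ang >= angle_cutoff, , drop = FALSE]
  ang <- ang[ang >= angle_cutoff]
  if (nrow(pr) == 0) return(empty)
  # one best acceptor per donor: shortest distance, ties lower residue index
  ord <- order(pr$i, pr$d, acceptors$df$pos[pr$j])
  pr <- pr[ord, , drop = FALSE]; ang <- ang[ord]
  keep <- !duplicated(pr$i)
  pr <- pr[keep, , drop = FALSE]; ang <- ang[keep]
  data.frame(donor_chain = donors$df$chain[pr$i],
             donor_resno = donors$df$resno[pr$i],
             donor_row = pr$i,
             acceptor_chain = acceptors$df$chain[pr$j],
             acceptor_resno = acceptors$df$resno[pr$j],
             acceptor_row = pr$j,
             distance = pr$d, angle = ang)
}

#' Hydrogen-bond satisfaction of a capped fibril tip
#'
#' Inventories the backbone donors and acceptors of the tip layer's site
#' window that the ideal next monomer would satisfy (all of them dangle
#' across the missing layer by construction), then recounts with the posed
#' scaffold in place. `hb_satisfied + hb_unsat` always equals the
#' inventory size.
#'
#' @param assembly A `fibril_assembly`.
#' @param pose A `docked_pose` (hard-clash free).
#' @return Named integer vector `c(hb_satisfied =, hb_unsat =)`.
#' @export
tip_hbond_satisfaction <- function(assembly, pose) {
  site <- pose$site
  tip <- tip_chain(assembly, site$protofilament, site$fib_end)
  tip_fr <- residue_frames(assembly$model, tip)
  win <- tip_fr$df$pos >= site$start & tip_fr$df$pos <= site$end
  tip_win <- frames_subset(tip_fr, win)
  vl <- virtual_next_layer(assembly, site$protofilament, site$fib_end)
  vl_fr <- residue_frames(vl)
  # inventory: window donors/acceptors whose ideal-next-monomer partner
  # also lies inside the site window -- the bonds a window-length capping
  # strand is responsible for (edge residues can bond one position past
  # the window; those belong to the neighboring site)
  d_bonds <- detect_backbone_hbonds(tip_win, vl_fr)
  d_bonds <- d_bonds[vl_fr$df$pos[d_bonds$acceptor_row] >= site$start &
                       vl_fr$df$pos[d_bonds$acceptor_row] <= site$end, , drop = FALSE]
  inv_d <- unique(d_bonds$donor_row)
  a_bonds <- detect_backbone_hbonds(vl_fr, tip_win)
  a_bonds <- a_bonds[vl_fr$df$pos[a_bonds$donor_row] >= site$start &
                       vl_fr$df$pos[a_bonds$donor_row] <= site$end, , drop = FALSE]
  inv_a <- unique(a_bonds$acceptor_row)
  sc_fr <- residue_frames(pose$posed)
  sat_d <- unique(detect_backbone_hbonds(tip_win, sc_fr)$donor_row)
  sat_a <- unique(detect_backbone_hbonds(sc_fr, tip_win)$acceptor_row)
  satisfied <- length(intersect(inv_d, sat_d)) + length(intersect(inv_a, sat_a))
  total <- length(inv_d) + length(inv_a)
  c(hb_satisfied = satisfied, hb_unsat = total - satisfied)
}

#' Count scaffold heavy atoms in the binding interface
#'
#' Heavy atoms of the posed scaffold within `cutoff` (closed boundary) of
#' any fibril heavy atom.
#'
#' @param pose A `docked_pose`.
#' @param assembly A `fibril_assembly`.
#' @param cutoff Angstrom.
#' @export
interface_atom_count <- function(pose, assembly, cutoff = INTERFACE_CUTOFF) {
  sc <- heavy_coords(pose$posed)
  fb <- heavy_coords(assembly$model)
  pr <- neighbor_pairs(sc, fb, cutoff)
  length(unique(pr$i))
}

## CB-proxy coordinates (virtual CB; CA for glycine) and one-letter
## sequence for every residue of a set of chains.
cbeta_proxies <- function(model, chains = NULL) {
  if (is.null(chains)) chains <- chain_ids(model)
  out <- lapply(chains, function(ch) {
    cb <- chain_backbone(model, ch)
    xyz <- virtual_cbeta(cb$bb)
    aa <- AA1[cb$resid]
    gly <- aa == "G"
    xyz[gly, ] <- cb$bb$CA[gly, , drop = FALSE]
    if (any(is.na(aa))) stop("unknown residue type in chain ", ch)
    list(xyz = xyz, aa = aa, chain = ch)
  })
  list(xyz = do.call(rbind, lapply(out, `[[`, "xyz")),
       aa = unname(unlist(lapply(out, `[[`, "aa"))),
       chain = rep(vapply(out, `[[`, "", "chain"),
                   vapply(out, function(o) length(o$aa), 0L)))
}

#' Residue-contact binding-energy surrogate (ddg)
#'
#' Sum of contact-potential entries over inter-molecular residue pairs
#' whose CB-CB distance (CA for glycine) is at most 8 Angstrom. Lower is
#' better. A rank-ordering surrogate, not a physical energy.
#'
#' @param pose A `docked_pose`.
#' @param assembly A `fibril_assembly`.
#' @param table Contact table (default: packaged [contact_table()]).
#' @param scaffold_seq Optional sequence override for the scaffold (used
#'   during optimization).
#' @export
ddg_surrogate <- function(pose, assembly, table = contact_table(),
                          scaffold_seq = NULL) {
  sc <- cbeta_proxies(pose$posed)
  if (!is.null(scaffold_seq)) {
    aa <- strsplit(scaffold_seq, "")[[1]]
    stopifnot(length(aa) == length(sc$aa))
    # glycine proxies move between CA and CB when the sequence changes
    cb <- chain_backbone(pose$posed, chain_ids(pose$posed)[1])
    xyz <- virtual_cbeta(cb$bb)
    xyz[aa == "G", ] <- cb$bb$CA[aa == "G", , drop = FALSE]
    sc$xyz <- xyz; sc$aa <- aa
  }
  fb <- cbeta_proxies(assembly$model)
  pr <- neighbor_pairs(sc$xyz, fb$xyz, CONTACT_CUTOFF)
  if (nrow(pr) == 0) return(0)
  e <- table[cbind(sc$aa[pr$i], fb$aa[pr$j])]
  if (any(is.na(e))) stop("unknown residue type in contact table lookup")
  sum(e)
}

#' Backbone-dihedral residue propensity score (p_aa_p)
#'
#' Mean over residues of log P(aa | Ramachandran bin) from the packaged
#' propensity table. Residues with undefined (terminal) dihedrals are
#' skipped; higher is better. Returns NA when no residue can be scored.
#'
#' @param scaffold A `scaffold` with sequence, or any object with `bb` and
#'   `sequence` fields.
#' @export
paap_score <- function(scaffold) {
  bb <- scaffold$bb
  aa <- strsplit(scaffold$sequence, "")[[1]]
  d <- backbone_dihedrals(bb)
  bins <- rama_bin(d$phi, d$psi)
  ok <- !is.na(bins)
  if (!any(ok)) {
    warning("no residues with defined dihedrals: empty propensity score")
    return(NA_real_)
  }
  P <- propensity_table()
  p <- P[cbind(aa[ok], bins[ok])]
  if (any(is.na(p))) stop("unknown residue type in propensity lookup")
  mean(log(p))
}

#' Side-chain centroid pseudo-atoms of a posed scaffold
#'
#' Centroids sit a fixed residue-specific distance from CA along the
#' CA->CB direction, with a residue-specific effective radius (glycine has
#' no centroid). The single-pseudo-atom model makes steric effects of
#' point mutations expressible without rotamers.
#'
#' @param model Single-chain `structure_model` of the scaffold.
#' @param sequence Optional sequence override.
#' @return Data frame with `pos`, `aa`, `x`, `y`, `z`, `radius`.
#' @export
sidechain_centroids <- function(model, sequence = NULL) {
  ch <- chain_ids(model)[1]
  cb <- chain_backbone(model, ch)
  aa <- if (is.null(sequence)) unname(AA1[cb$resid]) else strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n_res(cb$bb))
  par <- centroid_params()
  r <- par$radius[match(aa, par$aa)]
  ext <- par$ca_cb_ext[match(aa, par$aa)]
  if (any(is.na(r))) stop("unknown residue type in centroid table")
  cbx <- virtual_cbeta(cb$bb)
  ca <- cb$bb$CA
  dir <- cbx - ca
  len <- sqrt(rowSums(dir^2))
  pos <- ca + dir / pmax(len, 1e-9) * ext
  keep <- aa != "G"
  data.frame(pos = which(keep), aa = aa[keep],
             x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
             radius = r[keep])
}

## Centroid-vs-fibril clash counts. A centroid is a coarse average
## side-chain position, so only deep penetration (< 1.8 A to a heavy atom)
## counts as hard; soft is < 0.8 * (centroid radius + atom vdW radius).
## In-register cross-beta stacking puts a down-pointing centroid ~2.3 A
## above the next layer's CA -- a contact, not an overlap.
centroid_clash_counts <- function(centroids, assembly) {
  at <- assembly$model$atoms
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(centroids) == 0) return(c(hard = 0L, soft = 0L))
  rb <- vdw_radius(at$elesy)
  cut <- max(SOFT_CLASH_FACTOR * (max(centroids$radius) + max(rb)),
             CENTROID_HARD_DIST)
  pr <- neighbor_pairs(as.matrix(centroids[, c("x", "y", "z")]),
                       as.matrix(at[, c("x", "y", "z")]), cut)
  if (nrow(pr) == 0) return(c(hard = 0L, soft = 0L))
  hard <- pr$d < CENTROID_HARD_DIST
  soft <- !hard & pr$d < SOFT_CLASH_FACTOR * (centroids$radius[pr$i] + rb[pr$j])
  c(hard = sum(hard), soft = sum(soft))
}

#' Funnel configuration
#'
#' Thresholds and cutoffs of the design funnel. The paper-style funnel
#' filters on hard clashes, unsatisfied tip hydrogen bonds and interface
#' atom count, then sorts by the binding-energy surrogate.
#'
#' @param hb_unsat_max Largest tolerated unsatisfied tip H-bond count.
#' @param interface_atoms_min Smallest tolerated interface atom count.
#' @param interface_cutoff,contact_cutoff,hbond_dist,hbond_angle Geometric
#'   cutoffs (Angstrom / degrees).
#' @export
funnel_config <- function(hb_unsat_max = 2, interface_atoms_min = 40,
                          interface_cutoff = INTERFACE_CUTOFF,
                          contact_cutoff = CONTACT_CUTOFF,
                          hbond_dist = HBOND_DIST_CUTOFF,
                          hbond_angle = HBOND_ANGLE_CUTOFF) {
  list(hb_unsat_max = hb_unsat_max, interface_atoms_min = interface_atoms_min,
       interface_cutoff = interface_cutoff, contact_cutoff = contact_cutoff,
       hbond_dist = hbond_dist, hbond_angle = hbond_angle)
}

#' Read a funnel configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#' @param path YAML file.
#' @export
read_funnel_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  cfg <- funnel_config()
  bad <- setdiff(names(vals), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(vals)] <- vals
  cfg
}

#' Score a docked pose with all funnel metrics
#'
#' @param pose A `docked_pose`.
#' @param assembly A `fibril_assembly`.
#' @param config A [funnel_config()].
#' @return One-row data frame: id, site/end provenance, graft rmsd, hard
#'   and soft clashes (atom-atom plus centroid), H-bond satisfaction,
#'   interface atoms, ddg surrogate and p_aa_p.
#' @export
score_pose <- function(pose, assembly, config = funnel_config()) {
  hb <- tip_hbond_satisfaction(assembly, pose)
  cen <- sidechain_centroids(pose$posed, pose$scaffold$sequence)
  ccl <- centroid_clash_counts(cen, assembly)
  data.frame(
    id = pose$scaffold_id,
    site_index = pose$site$site_index,
    fib_end = pose$site$fib_end,
    protofilament = pose$site$protofilament,
    orientation = pose$orientation,
    graft_rmsd = pose$graft_rmsd,
    hard_clashes = pose$hard_clashes + ccl[["hard"]],
    soft_clashes = pose$soft_clashes + ccl[["soft"]],
    hb_satisfied = hb[["hb_satisfied"]],
    hb_unsat = hb[["hb_unsat"]],
    interface_atoms = interface_atom_count(pose, assembly, config$interface_cutoff),
    ddg = ddg_surrogate(pose, assembly),
    paap = paap_score(pose$scaffold)
  )
}

## Scaffold residue positions contributing atoms to the interface.
interface_positions <- function(pose, assembly, cutoff = INTERFACE_CUTOFF) {
  at <- pose$posed$atoms
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  fb <- heavy_coords(assembly$model)
  pr <- neighbor_pairs(as.matrix(at[, c("x", "y", "z")]), fb, cutoff)
  sort(unique(at$resno[unique(pr$i)]))
}

#' Greedy interface sequence optimization
#'
#' Sweeps the mutable positions in fixed order (lowest index first); at
#' each position tries the 19 non-cysteine amino acids and accepts the
#' best ddg-surrogate improvement whose centroid pseudo-atom adds no hard
#' clash with the fibril. Stops when a full sweep changes nothing. The
#' returned score trajectory is monotone non-increasing.
#'
#' @param pose A `docked_pose`.
#' @param assembly A `fibril_assembly`.
#' @param mutable Scaffold positions to optimize (default: interface
#'   positions).
#' @param table Contact table.
#' @param max_sweeps Sweep limit.
#' @return List: `pose` (sequence updated), `sequence`, `trajectory`
#'   (ddg after initial state and each accepted mutation).
#' @export
optimize_interface_sequence <- function(pose, assembly, mutable = NULL,
                                        table = contact_table(),
                                        max_sweeps = 10) {
  if (is.null(mutable)) mutable <- interface_positions(pose, assembly)
  seq_v <- strsplit(pose$scaffold$sequence, "")[[1]]
  cur <- ddg_surrogate(pose, assembly, table)
  traj <- cur
  if (length(mutable) == 0) {
    return(list(pose = pose, sequence = paste(seq_v, collapse = ""),
                trajectory = traj))
  }
  candidates <- setdiff(AA1, "C")
  # the surrogate is a sum of independent per-position contributions
  # (inter-molecular pairs only), so precompute, for every scaffold
  # position, the contact energy of each candidate residue and the
  # centroid hard-clash verdict; a candidate evaluation is then O(1)
  fb <- cbeta_proxies(assembly$model)
  ch <- chain_ids(pose$posed)[1]
  cb <- chain_backbone(pose$posed, ch)
  xyz_cb <- virtual_cbeta(cb$bb)
  xyz_ca <- cb$bb$CA
  n_pos <- n_res(cb$bb)
  contrib <- matrix(0, length(AA1), n_pos, dimnames = list(AA1, NULL))
  for (p in seq_len(n_pos)) {
    pr <- neighbor_pairs(xyz_cb[p, , drop = FALSE], fb$xyz, CONTACT_CUTOFF)
    if (nrow(pr) > 0) {
      contrib[, p] <- rowSums(table[, fb$aa[pr$j], drop = FALSE])
    }
    prg <- neighbor_pairs(xyz_ca[p, , drop = FALSE], fb$xyz, CONTACT_CUTOFF)
    contrib["G", p] <- if (nrow(prg) > 0) sum(table["G", fb$aa[prg$j]]) else 0
  }
  # centroid position is residue-independent (fixed CA->CB extension), so
  # the hard-clash verdict per position is too; glycine has no centroid
  par <- centroid_params()
  ext <- par$ca_cb_ext[match("A", par$aa)]
  dirs <- xyz_cb - xyz_ca
  lens <- sqrt(rowSums(dirs^2))
  cen_xyz <- xyz_ca + dirs / pmax(lens, 1e-9) * ext
  fbh <- heavy_coords(assembly$model)
  cen_hard <- vapply(seq_len(n_pos), function(p) {
    nrow(neighbor_pairs(cen_xyz[p, , drop = FALSE], fbh, CENTROID_HARD_DIST)) > 0
  }, TRUE)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (p in sort(mutable)) {
      best_aa <- seq_v[p]; best_ddg <- cur
      base <- cur - unname(contrib[seq_v[p], p])
      for (aa in candidates) {
        if (aa == seq_v[p]) next
        if (aa != "G" && cen_hard[p]) next
        val <- base + unname(contrib[aa, p])
        if (val < best_ddg - 1e-12) { best_ddg <- val; best_aa <- aa }
      }
      if (best_aa != seq_v[p]) {
        seq_v[p] <- best_aa
        cur <- best_ddg
        traj <- c(traj, cur)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  new_seq <- paste(seq_v, collapse = "")
  pose$scaffold$sequence <- new_seq
  pose$posed <- update_model_sequence(pose$posed, new_seq)
  list(pose = pose, sequence = new_seq, trajectory = traj)
}

## Rewrite residue names of a single-chain model to match a new sequence.
update_model_sequence <- function(model, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  at <- model$atoms
  keys <- residue_keys(at)
  idx <- match(keys, unique(keys))
  stopifnot(length(aa) == max(idx))
  at$resid <- unname(AA3_FROM_1[aa[idx]])
  structure_model(at, source = model$source)
}

#' Rescore a pose under point mutations
#'
#' Mutations use author numbering on the scaffold (e.g. `"A42R"`); the
#' reference residue must match. Side chains are modeled as single
#' centroid pseudo-atoms, so a mutation swaps the centroid radius/type and
#' every funnel metric is recomputed.
#'
#' @param pose A `docked_pose`.
#' @param assembly A `fibril_assembly`.
#' @param mutations Character vector like `c("A42R", "V44Y")`.
#' @param config A [funnel_config()].
#' @return List with `before`, `after` (one-row score frames) and `delta`
#'   (after - before for numeric metrics).
#' @export
mutate_and_rescore <- function(pose, assembly, mutations,
                               config = funnel_config()) {
  seq_v <- strsplit(pose$scaffold$sequence, "")[[1]]
  resno <- sort(unique(pose$posed$atoms$resno))
  for (mut in mutations) {
    m <- regmatches(mut, regexec("^([A-Y])([0-9]+)([A-Y])$", mut))[[1]]
    if (length(m) != 4) stop("malformed mutation: ", mut)
    ref <- m[2]; num <- as.integer(m[3]); new <- m[4]
    p <- match(num, resno)
    if (is.na(p)) stop("no residue numbered ", num, " in the scaffold")
    if (seq_v[p] != ref) {
      stop(sprintf("reference mismatch in %s: position %d is %s", mut, num, seq_v[p]))
    }
    if (new == "C") stop("cysteine is never assigned in capping designs")
    seq_v[p] <- new
  }
  before <- score_pose(pose, assembly, config)
  pose2 <- pose
  pose2$scaffold$sequence <- paste(seq_v, collapse = "")
  pose2$posed <- update_model_sequence(pose2$posed, pose2$scaffold$sequence)
  after <- score_pose(pose2, assembly, config)
  num_cols <- vapply(before, is.numeric, TRUE)
  delta <- after[num_cols] - before[num_cols]
  list(before = before, after = after, delta = delta, pose = pose2)
}

#' Rank scored designs through the funnel
#'
#' Hard filters first (no hard clashes, `hb_unsat` at most the threshold,
#' `interface_atoms` at least the threshold), then sort by ddg surrogate
#' ascending, ties by `hb_satisfied` descending, then by design id: a
#' deterministic total order invariant to input order.
#'
#' @param scores Data frame of [score_pose()] rows.
#' @param config A [funnel_config()].
#' @return The filtered table, ordered, with a `composite_rank` column.
#' @export
rank_designs <- function(scores, config = funnel_config()) {
  if (is.null(scores) || nrow(scores) == 0) {
    return(data.frame())
  }
  keep <- scores$hard_clashes == 0 &
    scores$hb_unsat <= config$hb_unsat_max &
    scores$interface_atoms >= config$interface_atoms_min
  out <- scores[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  ord <- order(out$ddg, -out$hb_satisfied, out$id)
  out <- out[ord, , drop = FALSE]
  out$composite_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
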