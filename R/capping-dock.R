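# Capping dock: enumerate candidate binding sites on the fibril tip and
# graft scaffold beta-strands onto the virtual next layer by backbone
# superposition, producing clash-filtered docked poses.

## Fixed van der Waals radii (Angstrom) for heavy atoms.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
HARD_CLASH_DIST <- 2.5
SOFT_CLASH_FACTOR <- 0.8

vdw_radius <- function(elesy) {
  r <- VDW_RADII[elesy]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Enumerate candidate binding sites on a tip layer
#'
#' Sites are contiguous residue windows lying wholly inside beta-strand (E)
#' runs of the tip layer's secondary structure. In `sliding` mode every
#' window of length `window` inside each E run is a site; in `per_strand`
#' mode each full E run is one site.
#'
#' @param tip_ss Character vector of per-residue H/E/L labels for the tip
#'   layer.
#' @param window Window length (residues); must be >= `min_window`.
#' @param mode `"sliding"` or `"per_strand"`.
#' @param min_window Smallest admissible window.
#' @return Data frame with `site_index`, `start`, `end`, `length` (1-based
#'   residue indices into the tip layer). Empty (with a warning) when the
#'   tip has no E runs long enough.
#' @export
enumerate_binding_sites <- function(tip_ss, window = 6,
                                    mode = c("sliding", "per_strand"),
                                    min_window = 4) {
  mode <- match.arg(mode)
  if (window < min_window) stop("window below minimum of ", min_window)
  runs <- ss_runs(tip_ss, "E")
  out <- list()
  if (mode == "sliding") {
    for (r in seq_len(nrow(runs))) {
      if (runs$length[r] < window) next
      for (s in runs$start[r]:(runs$end[r] - window + 1)) {
        out[[length(out) + 1]] <- data.frame(start = s, end = s + window - 1)
      }
    }
  } else {
    for (r in seq_len(nrow(runs))) {
      if (runs$length[r] < min_window) next
      out[[length(out) + 1]] <- data.frame(start = runs$start[r], end = runs$end[r])
    }
  }
  if (length(out) == 0) {
    warning("no binding sites: tip layer has no beta runs of length >= ", window)
    return(data.frame(site_index = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  df <- do.call(rbind, out)
  df$length <- df$end - df$start + 1
  df <- cbind(site_index = seq_len(nrow(df)), df)
  df
}

## Tip chain id of a protofilament end.
tip_chain <- function(assembly, protofilament, end) {
  ids <- assembly$protofilaments[[protofilament]]
  if (end == "plus") ids[length(ids)] else ids[1]
}

#' Enumerate binding sites on a fibril assembly end
#'
#' Convenience wrapper: assigns secondary structure on the tip layer and
#' attaches protofilament/end labels to [enumerate_binding_sites()] output.
#'
#' @param assembly A `fibril_assembly`.
#' @param protofilament Protofilament index.
#' @param end `"plus"` or `"minus"`.
#' @inheritParams enumerate_binding_sites
#' @export
enumerate_sites <- function(assembly, protofilament = 1,
                            end = c("plus", "minus"), window = 6,
                            mode = c("sliding", "per_strand"), min_window = 4) {
  end <- match.arg(end)
  tip <- tip_chain(assembly, protofilament, end)
  cb <- chain_backbone(assembly$model, tip)
  ss <- assign_secondary_structure(cb$bb)
  sites <- enumerate_binding_sites(ss, window = window, mode = mode,
                                   min_window = min_window)
  if (nrow(sites) > 0) {
    sites$protofilament <- protofilament
    sites$fib_end <- end
  }
  sites
}

#' Count hard and soft steric clashes between two atom sets
#'
#' Hard clashes are heavy-atom pairs closer than 2.5 Angstrom; soft clashes
#' are pairs not hard-clashing but closer than 0.8 x the sum of their van
#' der Waals radii. Computed with a cell-list grid; identical to the
#' all-pairs answer.
#'
#' @param a,b `structure_model`s, or data frames with `elesy`, `x`, `y`, `z`.
#' @return Named integer vector `c(hard =, soft =)`.
#' @export
clash_counts <- function(a, b) {
  at_a <- if (inherits(a, "structure_model")) a$atoms else a
  at_b <- if (inherits(b, "structure_model")) b$atoms else b
  at_a <- at_a[!(at_a$elesy %in% c("H", "D")), , drop = FALSE]
  at_b <- at_b[!(at_b$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at_a) == 0 || nrow(at_b) == 0) stop("empty coordinate set")
  ra <- vdw_radius(at_a$elesy)
  rb <- vdw_radius(at_b$elesy)
  max_cut <- SOFT_CLASH_FACTOR * (max(ra) + max(rb))
  pr <- neighbor_pairs(as.matrix(at_a[, c("x", "y", "z")]),
                       as.matrix(at_b[, c("x", "y", "z")]),
                       max(max_cut, HARD_CLASH_DIST))
  if (nrow(pr) == 0) return(c(hard = 0L, soft = 0L))
  hard <- pr$d < HARD_CLASH_DIST
  soft <- !hard & pr$d < SOFT_CLASH_FACTOR * (ra[pr$i] + rb[pr$j])
  c(hard = sum(hard), soft = sum(soft))
}

## Backbone window (N,CA,C,O rows) of residues start..end of a backbone.
window_coords <- function(bb, start, end) {
  idx <- start:end
  sub <- structure(list(N = bb$N[idx, , drop = FALSE],
                        CA = bb$CA[idx, , drop = FALSE],
                        C = bb$C[idx, , drop = FALSE],
                        O = bb$O[idx, , drop = FALSE]), class = "backbone")
  backbone_coords(sub)
}

## Reverse residue order of a backbone window coordinate block.
reverse_window <- function(xyz, atoms_per_res = 4) {
  n <- nrow(xyz) / atoms_per_res
  idx <- unlist(lapply(rev(seq_len(n)), function(i) {
    (i - 1) * atoms_per_res + seq_len(atoms_per_res)
  }))
  xyz[idx, , drop = FALSE]
}

#' Graft a scaffold strand onto a tip binding site
#'
#' Superposes a window-length stretch of one scaffold strand element onto
#' the corresponding backbone of the virtual next layer restricted to the
#' site window, moves the whole scaffold by the fitted transform, and
#' counts steric clashes against the real fibril atoms. Both parallel and
#' antiparallel placements of the strand are tried; the lower-rmsd
#' clash-passing one is kept. When the strand element is longer than the
#' window, the minimum-rmsd stretch wins (ties: lowest start index).
#' A pose with hard clashes is flagged `accepted = FALSE`.
#'
#' @param scaffold A `scaffold` with sequence assigned.
#' @param strand_choice Which strand (E) element of the scaffold to graft
#'   (index among its E elements).
#' @param site One row of [enumerate_sites()] output.
#' @param assembly A `fibril_assembly`.
#' @return A `docked_pose`: transform, graft rmsd, orientation, clash
#'   counts, the posed scaffold model (chain "Z"), and provenance.
#' @export
graft_scaffold <- function(scaffold, strand_choice = 1, site, assembly) {
  stopifnot(inherits(scaffold, "scaffold"), inherits(assembly, "fibril_assembly"))
  e_elems <- scaffold$elements[scaffold$elements$kind == "E", , drop = FALSE]
  if (strand_choice < 1 || strand_choice > nrow(e_elems)) {
    stop("scaffold has no strand element ", strand_choice)
  }
  el <- e_elems[strand_choice, ]
  w <- site$end - site$start + 1
  if (el$end - el$start + 1 < w) {
    stop("scaffold strand shorter than the site window")
  }
  vl <- virtual_next_layer(assembly, site$protofilament, site$fib_end)
  vb <- chain_backbone(vl, "v")
  if (site$end > n_res(vb$bb)) stop("site window outside the tip layer")
  target <- window_coords(vb$bb, site$start, site$end)

  # best stretch per orientation (ties: lowest start index), then prefer the
  # lower-rmsd clash-passing orientation
  cands <- list()
  for (orient in c("parallel", "antiparallel")) {
    b <- NULL
    for (s0 in el$start:(el$end - w + 1)) {
      mob <- window_coords(scaffold$bb, s0, s0 + w - 1)
      if (orient == "antiparallel") mob <- reverse_window(mob)
      fit <- kabsch_superpose(mob, target)
      if (is.null(b) || fit$rmsd < b$rmsd - 1e-12) {
        b <- list(orientation = orient, stretch_start = s0,
                  transform = fit$transform, rmsd = fit$rmsd)
      }
    }
    posed <- transform_model(scaffold_to_model(scaffold, chain = "Z"), b$transform)
    cl <- clash_counts(posed, assembly$model)
    b$posed <- posed; b$hard <- cl[["hard"]]; b$soft <- cl[["soft"]]
    cands[[orient]] <- b
  }
  ord <- order(vapply(cands, function(x) x$hard > 0, TRUE),
               vapply(cands, function(x) x$rmsd, 0))
  pick <- cands[[ord[1]]]
  structure(list(
    scaffold_id = scaffold$id %||% sprintf("%s_seed%d", scaffold$class_id, scaffold$seed),
    scaffold = scaffold,
    site = site,
    strand_choice = strand_choice,
    orientation = pick$orientation,
    stretch_start = pick$stretch_start,
    transform = pick$transform,
    graft_rmsd = pick$rmsd,
    hard_clashes = pick$hard,
    soft_clashes = pick$soft,
    accepted = pick$hard == 0,
    posed = pick$posed
  ), class = "docked_pose")
}

#' @export
print.docked_pose <- function(x, ...) {
  cat(sprintf(
    "docked_pose: %s -> site %d (%s end, pf %d), %s, graft rmsd %.3g A, clashes %d hard / %d soft%s\n",
    x$scaffold_id, x$site$site_index, x$site$fib_end, x$site$protofilament,
    x$orientation, x$graft_rmsd, x$hard_clashes, x$soft_clashes,
    if (x$accepted) "" else " [REJECTED]"))
  invisible(x)
}

#' Write a docked pose as a fibril + scaffold complex
#'
#' Fibril chains keep their ids; the scaffold is chain "Z".
#'
#' @param pose A `docked_pose`.
#' @param assembly The `fibril_assembly` the pose was docked against.
#' @param path Output file (PDB or mmCIF by extension).
#' @export
write_pose_complex <- function(pose, assembly, path) {
  write_structure(merge_models(assembly$model, pose$posed,
                               source = "docked complex"), path)
}
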