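# Ground-truth synthetic fixtures: idealized fibrils with known rise/twist
# and strand layout, perfect complementary cappers, and noisy kinetic /
# binding curves. Every fixture carries machine-readable ground truth so
# recovery tests never compare against hard-coded numbers.

#' Specify a synthetic fibril
#'
#' @param n_layers Layers per protofilament (>= 3).
#' @param strands List of strand descriptors: `length` (residues, >= 4),
#'   `direction` (+1 along +x, -1 antiparallel), `offset` (lateral y
#'   position, Angstrom).
#' @param loop_length Residues in the connecting loops.
#' @param rise Axial rise per layer (Angstrom; cross-beta stacking regime,
#'   default 4.75).
#' @param twist Twist per layer (degrees, default -1.2).
#' @param n_protofilaments 1 or 2 (two related by a C2 rotation about the
#'   fibril axis).
#' @param pf_shift Lateral offset of each protofilament from the axis when
#'   `n_protofilaments == 2`.
#' @param noise_sd Gaussian coordinate noise (Angstrom; 0 = ideal).
#' @param seed Seed for the noise stream.
#' @return A `fibril_spec`.
#' @export
fibril_spec <- function(n_layers = 6,
                        strands = list(list(length = 12, direction = 1, offset = 0),
                                       list(length = 10, direction = -1, offset = 9)),
                        loop_length = 3, rise = 4.75, twist = -1.2,
                        n_protofilaments = 1, pf_shift = 6,
                        noise_sd = 0, seed = 1) {
  stopifnot(n_layers >= 3, n_protofilaments %in% c(1, 2),
            rise >= 4.0, rise <= 5.5, loop_length >= 1, noise_sd >= 0)
  for (s in strands) {
    stopifnot(s$length >= 4, s$direction %in% c(1, -1), is.numeric(s$offset))
  }
  structure(list(n_layers = n_layers, strands = strands,
                 loop_length = loop_length, rise = rise, twist = twist,
                 n_protofilaments = n_protofilaments, pf_shift = pf_shift,
                 noise_sd = noise_sd, seed = seed),
            class = "fibril_spec")
}

## Ideal strand oriented with its axis along +/- x and carbonyls
## alternating along +/- z (the cross-beta hydrogen-bonding direction),
## CA centroid at the origin.
oriented_ideal_strand <- function(len, direction = 1) {
  bb <- build_backbone(rep(IDEAL_DIHEDRALS$strand["phi"], len),
                       rep(IDEAL_DIHEDRALS$strand["psi"], len))
  ax <- bb$CA[len, ] - bb$CA[1, ]
  bb <- apply_transform(bb, rigid_transform(rotation_between(ax, c(direction, 0, 0)),
                                            c(0, 0, 0)))
  co <- bb$O - bb$C
  sgn <- rep(c(1, -1), length.out = len)
  w <- colSums(co * sgn)
  w[1] <- 0  # keep the alignment purely about the strand axis
  bb <- apply_transform(bb, rigid_transform(rotation_between(w, c(0, 0, 1)), c(0, 0, 0)))
  apply_transform(bb, rigid_transform(diag(3), -colMeans(bb$CA)))
}

## Loop backbone along a quadratic Bezier between two anchor points.
bezier_loop <- function(from, to, control, k) {
  ts <- seq(0, 1, length.out = k + 2)[2:(k + 1)]
  bez <- function(t) (1 - t)^2 * from + 2 * t * (1 - t) * control + t^2 * to
  dbez <- function(t) 2 * (1 - t) * (control - from) + 2 * t * (to - control)
  N <- CA <- C <- O <- matrix(NA_real_, k, 3)
  for (j in seq_len(k)) {
    ctr <- bez(ts[j])
    tan <- unit_vec(dbez(ts[j]))
    nrm <- vcross(tan, c(0, 0, 1))
    if (vnorm(nrm) < 1e-6) nrm <- vcross(tan, c(0, 1, 0))
    nrm <- unit_vec(nrm)
    CA[j, ] <- ctr
    N[j, ] <- ctr - 1.2 * tan + 0.3 * nrm
    C[j, ] <- ctr + 1.2 * tan + 0.3 * nrm
    O[j, ] <- C[j, ] + 1.23 * nrm
  }
  structure(list(N = N, CA = CA, C = C, O = O), class = "backbone")
}

cat_backbones <- function(bbs) {
  structure(list(N = do.call(rbind, lapply(bbs, `[[`, "N")),
                 CA = do.call(rbind, lapply(bbs, `[[`, "CA")),
                 C = do.call(rbind, lapply(bbs, `[[`, "C")),
                 O = do.call(rbind, lapply(bbs, `[[`, "O"))),
            class = "backbone")
}

## One fibril layer: rigidly placed ideal strands joined by loop arcs.
## Returns the backbone plus per-residue SS labels.
build_fibril_layer <- function(spec) {
  parts <- list()
  labels <- character(0)
  strands <- spec$strands
  placed <- list()
  for (i in seq_along(strands)) {
    s <- strands[[i]]
    bb <- oriented_ideal_strand(s$length, s$direction)
    bb <- apply_transform(bb, rigid_transform(diag(3), c(0, s$offset, 0)))
    placed[[i]] <- bb
  }
  for (i in seq_along(strands)) {
    if (i > 1) {
      prev <- placed[[i - 1]]
      nx <- placed[[i]]
      from <- prev$C[nrow(prev$C), ]
      to <- nx$N[1, ]
      side <- if (strands[[i - 1]]$direction > 0) 1 else -1
      control <- c(side * (max(abs(from[1]), abs(to[1])) + 5),
                   (from[2] + to[2]) / 2, (from[3] + to[3]) / 2)
      lp <- bezier_loop(from, to, control, spec$loop_length)
      parts[[length(parts) + 1]] <- lp
      labels <- c(labels, rep("L", spec$loop_length))
    }
    parts[[length(parts) + 1]] <- placed[[i]]
    labels <- c(labels, rep("E", strands[[i]]$length))
  }
  list(bb = cat_backbones(parts), labels = labels)
}

## Alternating A/V sequence (strand-compatible) for fixture layers.
fixture_sequence <- function(n) paste(rep(c("A", "V"), length.out = n), collapse = "")

#' Generate an idealized fibril with known ground truth
#'
#' Builds `n_layers` copies of an idealized beta-strand layer related by an
#' exact screw operator (rotation `twist` about the z axis plus `rise`
#' along it); a two-protofilament fibril adds a C2-related copy. Optional
#' Gaussian coordinate noise is applied to the emitted model only -- the
#' ground truth stays exact.
#'
#' @param spec A [fibril_spec()].
#' @return List with `model` (a `structure_model`; chains bottom-to-top per
#'   protofilament) and `truth` (exact `symmetry`, per-residue `ss` labels,
#'   true strand windows `site_runs`, the held-out `next_layer_above` /
#'   `next_layer_below` backbones per protofilament, chain ids per
#'   protofilament, and the spec).
#' @export
make_ideal_fibril <- function(spec = fibril_spec()) {
  stopifnot(inherits(spec, "fibril_spec"))
  layer <- build_fibril_layer(spec)
  n_aa <- n_res(layer$bb)
  if (spec$n_protofilaments == 2) {
    layer$bb <- apply_transform(layer$bb,
                                rigid_transform(diag(3), c(0, spec$pf_shift, 0)))
  }
  sym <- screw_symmetry(spec$rise, spec$twist, c(0, 0, 0), c(0, 0, 1))
  seqc <- fixture_sequence(n_aa)
  pf_layer0 <- list(layer$bb)
  if (spec$n_protofilaments == 2) {
    c2 <- rigid_transform(rodrigues_rotation(c(0, 0, 1), 180), c(0, 0, 0))
    pf_layer0[[2]] <- apply_transform(layer$bb, c2)
  }
  models <- list()
  chain_sets <- list()
  ci <- 0
  for (pf in seq_len(spec$n_protofilaments)) {
    ids <- character(spec$n_layers)
    for (k in seq_len(spec$n_layers)) {
      ci <- ci + 1
      id <- LETTERS[ci]
      ids[k] <- id
      bbk <- apply_transform(pf_layer0[[pf]], screw_transform(sym, k - 1))
      models[[ci]] <- model_from_backbone(bbk, chain = id, sequence = seqc,
                                          source = "synthetic fibril layer")
    }
    chain_sets[[pf]] <- ids
  }
  model <- do.call(merge_models, c(models, list(source = "synthetic ideal fibril")))
  if (spec$noise_sd > 0) {
    model$atoms[, c("x", "y", "z")] <- with_seed(spec$seed, {
      model$atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(model$atoms), 0, spec$noise_sd),
               ncol = 3)
    })
  }
  next_above <- lapply(pf_layer0, function(b) {
    apply_transform(b, screw_transform(sym, spec$n_layers))
  })
  next_below <- lapply(pf_layer0, function(b) {
    apply_transform(b, screw_transform(sym, -1))
  })
  truth <- list(symmetry = sym, ss = layer$labels,
                site_runs = ss_runs(layer$labels, "E"),
                next_layer_above = next_above,
                next_layer_below = next_below,
                chains = chain_sets, sequence = seqc, spec = spec)
  list(model = model, truth = truth)
}

#' Which end label of an inferred assembly is the generator's top
#'
#' [group_layers()] orients the axis from data, so its "plus" end may be
#' either the generator's top (+z) or bottom layer. Returns the end label
#' (`"plus"`/`"minus"`) whose tip chain is the generator's top layer.
#'
#' @param assembly A `fibril_assembly` inferred from a [make_ideal_fibril()]
#'   model.
#' @param truth The matching ground truth.
#' @param protofilament Protofilament index (in `truth$chains` order).
#' @export
generator_top_end <- function(assembly, truth, protofilament = 1) {
  top_id <- utils::tail(truth$chains[[protofilament]], 1)
  pf_match <- which(vapply(assembly$protofilaments,
                           function(ids) top_id %in% ids, TRUE))
  if (length(pf_match) != 1) stop("top layer chain not found in assembly")
  ids <- assembly$protofilaments[[pf_match]]
  if (ids[length(ids)] == top_id) "plus" else "minus"
}

## NeRF continuation helpers: grow a backbone forward (C-terminal) or
## backward (N-terminal) from an existing fragment with given dihedrals.
extend_backbone_forward <- function(bb, phi, psi, psi_junction) {
  g <- PEPTIDE_GEOMETRY
  n0 <- n_res(bb)
  k <- length(phi)
  if (k == 0) return(bb)
  N <- rbind(bb$N, matrix(NA_real_, k, 3)); CA <- rbind(bb$CA, matrix(NA_real_, k, 3))
  C <- rbind(bb$C, matrix(NA_real_, k, 3)); O <- rbind(bb$O, matrix(NA_real_, k, 3))
  psis <- c(psi_junction, psi)
  for (j in seq_len(k)) {
    i <- n0 + j
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n, g$a_ca_c_n, psis[j])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca, g$a_c_n_ca, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c, g$a_n_ca_c, phi[j])
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi[j] + 180)
  }
  structure(list(N = N, CA = CA, C = C, O = O), class = "backbone")
}

extend_backbone_backward <- function(bb, phi, psi, phi_junction) {
  g <- PEPTIDE_GEOMETRY
  k <- length(phi)
  if (k == 0) return(bb)
  n_new <- k + n_res(bb)
  N <- rbind(matrix(NA_real_, k, 3), bb$N); CA <- rbind(matrix(NA_real_, k, 3), bb$CA)
  C <- rbind(matrix(NA_real_, k, 3), bb$C); O <- rbind(matrix(NA_real_, k, 3), bb$O)
  phis <- c(phi, phi_junction)
  for (j in k:1) {
    C[j, ] <- place_atom(C[j + 1, ], CA[j + 1, ], N[j + 1, ], g$b_c_n, g$a_c_n_ca, phis[j + 1])
    CA[j, ] <- place_atom(CA[j + 1, ], N[j + 1, ], C[j, ], g$b_ca_c, g$a_ca_c_n, 180)
    N[j, ] <- place_atom(N[j + 1, ], C[j, ], CA[j, ], g$b_n_ca, g$a_n_ca_c, psi[j])
    O[j, ] <- place_atom(N[j, ], CA[j, ], C[j, ], g$b_c_o, g$a_ca_c_o, psi[j] + 180)
  }
  structure(list(N = N, CA = CA, C = C, O = O), class = "backbone")
}

#' Build a perfect complementary capper for a binding site
#'
#' Constructs a scaffold whose graft strand backbone is an exact copy of
#' the virtual next layer restricted to the site window, guaranteeing a
#' graft rmsd of ~0, with an idealized clash-free body (helix, loops and
#' remaining strands of the requested topology class) grown off both ends
#' by internal-coordinate continuation. Body loop conformations are
#' resampled (seeded) until the body is free of hard clashes with the
#' fibril.
#'
#' @param site One row of [enumerate_sites()] output.
#' @param assembly The `fibril_assembly` the site lives on.
#' @param body_class Topology class of the capper (first strand element is
#'   the graft strand).
#' @param seed Seed for loop resampling.
#' @param max_tries Attempts before giving up.
#' @return A `scaffold` with sequence assigned.
#' @export
make_complementary_capper <- function(site, assembly, body_class = "EEH",
                                      seed = 1, max_tries = 200) {
  vl <- virtual_next_layer(assembly, site$protofilament, site$fib_end)
  vb <- chain_backbone(vl, "v")
  w <- site$end - site$start + 1
  stopifnot(w >= 4, site$end <= n_res(vb$bb))
  idx <- site$start:site$end
  graft_bb <- structure(list(N = vb$bb$N[idx, , drop = FALSE],
                             CA = vb$bb$CA[idx, , drop = FALSE],
                             C = vb$bb$C[idx, , drop = FALSE],
                             O = vb$bb$O[idx, , drop = FALSE]),
                        class = "backbone")
  elems <- strsplit(body_class, "")[[1]]
  if (sum(elems == "H") != 1 || !(sum(elems == "E") %in% c(2, 3))) {
    stop("invalid topology class: ", body_class)
  }
  first_e <- which(elems == "E")[1]
  # element lengths: graft strand = window; other strands 6; helix sized so
  # the total reaches the 35-residue floor; loops of 4
  kinds <- character(0); lens <- integer(0)
  for (i in seq_along(elems)) {
    if (i > 1) { kinds <- c(kinds, "L"); lens <- c(lens, 4L) }
    kinds <- c(kinds, elems[i])
    lens <- c(lens, if (elems[i] == "H") 12L else if (i == first_e) w else 6L)
  }
  total <- sum(lens)
  if (total < SCAFFOLD_MIN_LEN) {
    lens[kinds == "H"] <- lens[kinds == "H"] + (SCAFFOLD_MIN_LEN - total)
  }
  if (sum(lens) > SCAFFOLD_MAX_LEN) stop("capper body too long for the window")
  labels <- rep(kinds, lens)
  elem_tab <- data.frame(kind = kinds,
                         start = cumsum(lens) - lens + 1, end = cumsum(lens))
  graft_elem_row <- which(elem_tab$kind == "E")[1]
  g_start <- elem_tab$start[graft_elem_row]
  g_end <- elem_tab$end[graft_elem_row]
  after_lab <- labels[seq_along(labels) > g_end]
  before_lab <- labels[seq_along(labels) < g_start]

  elem_dih <- function(lab) {
    phi <- ifelse(lab == "H", IDEAL_DIHEDRALS$helix["phi"],
                  IDEAL_DIHEDRALS$strand["phi"])
    psi <- ifelse(lab == "H", IDEAL_DIHEDRALS$helix["psi"],
                  IDEAL_DIHEDRALS$strand["psi"])
    list(phi = phi, psi = psi)
  }
  fibril_atoms <- assembly$model
  for (t in seq_len(max_tries)) {
    bb <- with_seed(seed + (t - 1L) * 7919L, {
      fill <- function(lab) {
        d <- elem_dih(lab)
        loops <- lab == "L"
        if (any(loops)) {
          for (r in which(loops)) {
            d$phi[r] <- stats::runif(1, -150, -40)
            d$psi[r] <- stats::runif(1, -60, 170)
          }
        }
        d
      }
      out <- graft_bb
      if (length(after_lab) > 0) {
        d <- fill(after_lab)
        out <- extend_backbone_forward(out, d$phi, d$psi,
                                       psi_junction = stats::runif(1, 100, 170))
      }
      if (length(before_lab) > 0) {
        d <- fill(before_lab)
        out <- extend_backbone_backward(out, d$phi, d$psi,
                                        phi_junction = stats::runif(1, -150, -60))
      }
      out
    })
    if (backbone_self_clash(bb, 2.0)) next
    body_idx <- setdiff(seq_len(n_res(bb)), (g_start):(g_end))
    body_model <- model_from_backbone(
      structure(list(N = bb$N[body_idx, , drop = FALSE],
                     CA = bb$CA[body_idx, , drop = FALSE],
                     C = bb$C[body_idx, , drop = FALSE],
                     O = bb$O[body_idx, , drop = FALSE]), class = "backbone"),
      chain = "Z")
    cl <- clash_counts(body_model, fibril_atoms)
    if (cl[["hard"]] > 0) next
    sc <- structure(list(bb = bb, ss = labels, sequence = NULL, seed = seed,
                         try = t, class_id = body_class, elements = elem_tab,
                         id = sprintf("capper_%s_site%d", body_class, site$site_index)),
                    class = "scaffold")
    return(assign_initial_sequence(sc))
  }
  stop("could not place a clash-free capper body within ", max_tries, " tries")
}

#' Generate synthetic thioflavin-T aggregation traces
#'
#' Logistic traces `baseline + amplitude / (1 + exp(-rate (t - t50)))` with
#' seeded Gaussian noise; the ground-truth lag time (t50 - 2/rate) is
#' recorded.
#'
#' @param params List with `baseline`, `amplitude`, `t50` (h), `rate` (1/h).
#' @param noise_sd Gaussian noise SD (signal units).
#' @param n_replicates Number of replicate traces.
#' @param seed Seed.
#' @param times Sampling times (hours).
#' @return List with `traces` (list of data.frames: time, signal,
#'   replicate_id) and `truth` (params + lag_time).
#' @export
make_tht_dataset <- function(params = list(baseline = 0.1, amplitude = 1,
                                           t50 = 20, rate = 0.5),
                             noise_sd = 0.02, n_replicates = 3, seed = 1,
                             times = seq(0, 48, by = 0.5)) {
  stopifnot(params$amplitude >= 0, params$rate > 0)
  clean <- params$baseline + params$amplitude /
    (1 + exp(-params$rate * (times - params$t50)))
  traces <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      data.frame(time = times,
                 signal = clean + stats::rnorm(length(times), 0, noise_sd),
                 replicate_id = r)
    })
  })
  list(traces = traces,
       truth = c(params, list(lag_time = params$t50 - 2 / params$rate)))
}

#' Generate a synthetic saturation-binding curve
#'
#' One-site binding `signal = bmax * c / (half_saturation + c)` with seeded
#' Gaussian noise.
#'
#' @param bmax Saturating signal.
#' @param half_saturation Half-saturation concentration (nM).
#' @param conc Concentrations sampled (nM): a dilution series spanning the
#'   low-nanomolar to low-micromolar range, sampled more densely around the
#'   expected half-saturation where the curve is most informative.
#' @param n_replicates Independent measurements per concentration
#'   (plate-assay style, default 4).
#' @param noise_sd Gaussian noise SD.
#' @param seed Seed.
#' @return List with `data` (conc, signal; replicates stacked) and `truth`.
#' @export
make_binding_dataset <- function(bmax = 1.0, half_saturation = 150,
                                 conc = c(25, 50, 75, 100, 150, 200, 300,
                                          450, 800, 1600, 3200),
                                 n_replicates = 4, noise_sd = 0.03, seed = 1) {
  conc_all <- rep(conc, n_replicates)
  clean <- bmax * conc_all / (half_saturation + conc_all)
  sig <- with_seed(seed, clean + stats::rnorm(length(conc_all), 0, noise_sd))
  list(data = data.frame(conc = conc_all, signal = sig,
                         replicate_id = rep(seq_len(n_replicates), each = length(conc))),
       truth = list(bmax = bmax, half_saturation = half_saturation))
}
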