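# Miniprotein scaffold generation: topology classes (one helix, two or
# three strands), blueprint-driven idealized-dihedral backbone construction
# with stochastic loops, and burial-based initial sequence assignment
# (hydrophobic core, polar exterior, never cysteine).

SCAFFOLD_MIN_LEN <- 35
SCAFFOLD_MAX_LEN <- 50

HYDROPHOBIC_SET <- c("A", "V", "L", "I", "F", "M", "W")
POLAR_SET <- c("D", "E", "K", "R", "N", "Q", "S", "T")

## Canonical two-residue beta-turn dihedrals (types I, II, I', II') used to
## seed loop conformations, and the flank basins (extended, alpha, PPII)
## loops are padded with. Values in degrees.
TURN_TEMPLATES <- list(
  I   = list(c(-60, -30), c(-90, 0)),
  II  = list(c(-60, 120), c(80, 0)),
  Ip  = list(c(60, 30), c(90, 0)),
  IIp = list(c(60, -120), c(-80, 0))
)
LOOP_FLANKS <- list(ext = c(-120, 130), alpha = c(-60, -45), ppii = c(-75, 145))

## Run code with a private, reproducible RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Enumerate miniprotein topology classes
#'
#' All distinct orderings of helix (H) and strand (E) elements for every
#' combination of the given element counts, lexicographically sorted.
#' With one helix and two or three strands this yields the seven classes
#' EEEH, EEH, EEHE, EHE, EHEE, HEE, HEEE.
#'
#' @param n_helix Integer set of helix counts (default 1).
#' @param n_strand Integer set of strand counts (default c(2, 3)).
#' @return Character vector of topology class strings.
#' @export
enumerate_topology_classes <- function(n_helix = 1, n_strand = c(2, 3)) {
  stopifnot(length(n_helix) > 0, length(n_strand) > 0)
  out <- character(0)
  for (h in n_helix) {
    for (e in n_strand) {
      elems <- c(rep("H", h), rep("E", e))
      out <- c(out, unique(vapply(multiset_permutations(elems),
                                  paste, "", collapse = "")))
    }
  }
  sort(unique(out))
}

## All distinct permutations of a multiset (recursive enumeration).
multiset_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in multiset_permutations(rest)) out <- c(out, list(c(v, p)))
  }
  out
}

#' Construct a scaffold blueprint
#'
#' An ordered list of secondary-structure elements with lengths. The
#' element pattern (ignoring loops) must be a valid topology class (one
#' helix, two or three strands) and the total length must lie in
#' \[35, 50\] residues.
#'
#' @param kinds Character vector over \{"H", "E", "L"\}.
#' @param lengths Integer residue counts per element.
#' @return A `blueprint` object.
#' @export
blueprint <- function(kinds, lengths) {
  stopifnot(length(kinds) == length(lengths), all(kinds %in% c("H", "E", "L")),
            all(lengths >= 1))
  total <- sum(lengths)
  if (total < SCAFFOLD_MIN_LEN || total > SCAFFOLD_MAX_LEN) {
    stop(sprintf("blueprint total length %d outside [%d, %d]",
                 total, SCAFFOLD_MIN_LEN, SCAFFOLD_MAX_LEN))
  }
  core <- paste(kinds[kinds != "L"], collapse = "")
  n_h <- sum(kinds == "H"); n_e <- sum(kinds == "E")
  if (n_h != 1 || !(n_e %in% c(2, 3))) {
    stop("blueprint element pattern ", core,
         " is not a valid topology class (need one H and two or three E)")
  }
  structure(list(kinds = kinds, lengths = lengths, total_length = total,
                 class_id = core),
            class = "blueprint")
}

#' Default blueprint for a topology class
#'
#' Helix elements get 12 residues, strands 7, and connecting loops
#' alternate 4/5/4 residues; lengths can be overridden.
#'
#' @param class_id Topology class string (e.g. `"HEE"`).
#' @param helix_len,strand_len,loop_lens Element length defaults.
#' @export
default_blueprint <- function(class_id, helix_len = 12, strand_len = 7,
                              loop_lens = c(4, 5, 4)) {
  elems <- strsplit(class_id, "")[[1]]
  kinds <- character(0); lens <- integer(0)
  for (i in seq_along(elems)) {
    if (i > 1) {
      kinds <- c(kinds, "L")
      lens <- c(lens, loop_lens[(i - 2) %% length(loop_lens) + 1])
    }
    kinds <- c(kinds, elems[i])
    lens <- c(lens, if (elems[i] == "H") helix_len else strand_len)
  }
  blueprint(kinds, lens)
}

#' Read a blueprint from a text file
#'
#' One element per line: kind (H/E/L) and residue count, whitespace
#' separated. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @export
read_blueprint <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "[[:space:]]+")
  blueprint(vapply(parts, `[`, "", 1),
            as.integer(vapply(parts, `[`, "", 2)))
}

## Per-residue secondary-structure labels implied by a blueprint.
blueprint_labels <- function(bp) {
  rep(bp$kinds, bp$lengths)
}

## Element table: kind, start, end residue indices.
blueprint_elements <- function(bp) {
  ends <- cumsum(bp$lengths)
  data.frame(kind = bp$kinds, start = ends - bp$lengths + 1, end = ends)
}

## Initial conformation for a loop of k residues: a canonical beta-turn at
## a random position, padded with flank dihedrals, all jittered +/- 15 deg.
sample_loop_dihedrals <- function(k) {
  turn <- TURN_TEMPLATES[[sample(length(TURN_TEMPLATES), 1)]]
  pos <- sample(max(1, k - 1), 1)
  phi <- psi <- numeric(k)
  for (i in seq_len(k)) {
    if (i == pos && k - i >= 1) {
      phi[i] <- turn[[1]][1]; psi[i] <- turn[[1]][2]
    } else if (i == pos + 1) {
      phi[i] <- turn[[2]][1]; psi[i] <- turn[[2]][2]
    } else {
      f <- LOOP_FLANKS[[sample(length(LOOP_FLANKS), 1)]]
      phi[i] <- f[1]; psi[i] <- f[2]
    }
  }
  list(phi = phi + stats::runif(k, -15, 15), psi = psi + stats::runif(k, -15, 15))
}

blueprint_dihedrals <- function(bp) {
  # ideal dihedrals for H/E elements, NA at L positions (to be sampled)
  lab <- blueprint_labels(bp)
  phi <- psi <- rep(NA_real_, length(lab))
  phi[lab == "H"] <- IDEAL_DIHEDRALS$helix["phi"]
  psi[lab == "H"] <- IDEAL_DIHEDRALS$helix["psi"]
  phi[lab == "E"] <- IDEAL_DIHEDRALS$strand["phi"]
  psi[lab == "E"] <- IDEAL_DIHEDRALS$strand["psi"]
  list(phi = phi, psi = psi, labels = lab)
}

## Backbone self-clash test: any heavy-atom pair closer than `min_dist`
## between residues more than one apart.
backbone_self_clash <- function(bb, min_dist = 2.0) {
  xyz <- backbone_coords(bb)
  resi <- rep(seq_len(n_res(bb)), each = 4)
  pr <- neighbor_pairs(xyz, xyz, min_dist)
  bad <- abs(resi[pr$i] - resi[pr$j]) > 1 & pr$d < min_dist
  any(bad)
}

#' Build an idealized scaffold backbone from a blueprint
#'
#' Helix and strand elements use ideal dihedrals. Loop conformations are
#' seeded from canonical beta-turn templates and refined by a short
#' simulated-annealing compaction in loop torsion space, minimizing a
#' radius-of-gyration + steric-overlap objective. A candidate is accepted
#' when it is clash-free (no non-bonded backbone heavy-atom pair under
#' `clash_dist`) and compact (radius of gyration at most
#' `compactness * N^0.34` Angstrom). Deterministic given (blueprint, seed).
#'
#' @param bp A `blueprint`.
#' @param seed Integer seed recorded in the scaffold.
#' @param max_tries Annealing restarts before giving up.
#' @param compactness Radius-of-gyration prefactor.
#' @param clash_dist Hard-clash floor (Angstrom).
#' @param anneal_steps Annealing steps per restart.
#' @return A `scaffold` (backbone, blueprint labels, empty sequence).
#' @export
build_scaffold_backbone <- function(bp, seed = 1, max_tries = 25,
                                    compactness = 3.0, clash_dist = 2.0,
                                    anneal_steps = 600) {
  stopifnot(inherits(bp, "blueprint"))
  dih <- blueprint_dihedrals(bp)
  n <- length(dih$phi)
  rg_max <- compactness * n^0.34
  loop_idx <- which(dih$labels == "L")
  loop_runs <- ss_runs(dih$labels, "L")
  soft_floor <- 2.7  # annealing targets H-bond-like minimum separations
  for (t in seq_len(max_tries)) {
    res <- with_seed(seed + (t - 1L) * 10007L, {
      phi <- dih$phi; psi <- dih$psi
      for (r in seq_len(nrow(loop_runs))) {
        ld <- sample_loop_dihedrals(loop_runs$length[r])
        ix <- loop_runs$start[r]:loop_runs$end[r]
        phi[ix] <- ld$phi; psi[ix] <- ld$psi
      }
      objective <- function(phi, psi) {
        m <- cpp_build_backbone(phi, psi)
        s <- cpp_bb_score(m, n, soft_floor)
        list(f = 2 * max(0, s$rg - (rg_max - 0.3))^2 + s$pen, s = s)
      }
      cur <- objective(phi, psi)
      temps <- exp(seq(log(1.5), log(0.02), length.out = anneal_steps))
      for (step in seq_len(anneal_steps)) {
        if (cur$f == 0) break
        i <- if (length(loop_idx) == 1) loop_idx else sample(loop_idx, 1)
        nphi <- phi; npsi <- psi
        if (stats::runif(1) < 0.1) {
          nphi[i] <- stats::runif(1, -180, 180)
          npsi[i] <- stats::runif(1, -180, 180)
        } else {
          nphi[i] <- phi[i] + stats::rnorm(1, 0, 25)
          npsi[i] <- psi[i] + stats::rnorm(1, 0, 25)
        }
        cand <- objective(nphi, npsi)
        if (cand$f <= cur$f ||
            stats::runif(1) < exp((cur$f - cand$f) / temps[step])) {
          phi <- nphi; psi <- npsi; cur <- cand
        }
      }
      list(phi = phi, psi = psi, s = cur$s)
    })
    if (res$s$rg > rg_max) next
    if (res$s$min_nonbonded < clash_dist) next
    bb <- build_backbone(res$phi, res$psi)
    return(structure(list(bb = bb, ss = dih$labels, sequence = NULL,
                          seed = seed, try = t, class_id = bp$class_id,
                          elements = blueprint_elements(bp), blueprint = bp),
                     class = "scaffold"))
  }
  stop(sprintf("no clash-free compact backbone for class %s within %d tries (seed %d); reseed",
               bp$class_id, max_tries, seed))
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("scaffold: class %s, %d residues, seed %d%s\n",
              x$class_id, n_res(x$bb), x$seed,
              if (is.null(x$sequence)) "" else paste0("\n  seq: ", x$sequence)))
  invisible(x)
}

#' Residue burial by CA-neighbor counting
#'
#' Burial of residue i = number of CA atoms within `radius`, excluding
#' residues within `exclude` sequence positions.
#'
#' @param bb A `backbone`.
#' @param radius Count radius (Angstrom).
#' @param exclude Sequence-neighbor exclusion (+/- positions).
#' @return Integer vector of burial counts.
#' @export
residue_burial <- function(bb, radius = 10, exclude = 2) {
  ca <- bb$CA
  n <- nrow(ca)
  pr <- neighbor_pairs(ca, ca, radius)
  pr <- pr[abs(pr$i - pr$j) > exclude, , drop = FALSE]
  counts <- tabulate(pr$i, nbins = n)
  counts
}

#' Assign an initial burial-based sequence to a scaffold
#'
#' Buried positions (CA-neighbor count at or above `threshold`) draw from
#' the hydrophobic set \{A,V,L,I,F,M,W\}; exposed positions from the
#' polar/charged set \{D,E,K,R,N,Q,S,T\}. Loop positions with positive phi
#' get glycine. Cysteine is never assigned (capping designs carry no
#' disulfides). Deterministic given the scaffold's seed.
#'
#' @param scaffold A `scaffold`.
#' @param threshold Burial count at which a position counts as core.
#' @param radius Burial count radius (Angstrom).
#' @return The scaffold with `sequence` filled.
#' @export
assign_initial_sequence <- function(scaffold, threshold = 12, radius = 10) {
  bb <- scaffold$bb
  n <- n_res(bb)
  burial <- residue_burial(bb, radius = radius)
  d <- backbone_dihedrals(bb)
  aa <- with_seed(scaffold$seed * 2L + 101L, {
    out <- character(n)
    for (i in seq_len(n)) {
      out[i] <- if (burial[i] >= threshold) {
        sample(HYDROPHOBIC_SET, 1)
      } else {
        sample(POLAR_SET, 1)
      }
    }
    out
  })
  pos_phi <- !is.na(d$phi) & d$phi > 0 & scaffold$ss == "L"
  aa[pos_phi] <- "G"
  scaffold$sequence <- paste(aa, collapse = "")
  scaffold$burial <- burial
  scaffold
}

#' Build a complete scaffold (backbone + initial sequence)
#'
#' @inheritParams build_scaffold_backbone
#' @param ... Passed to [assign_initial_sequence()].
#' @export
build_scaffold <- function(bp, seed = 1, max_tries = 200, ...) {
  sc <- build_scaffold_backbone(bp, seed = seed, max_tries = max_tries)
  assign_initial_sequence(sc, ...)
}

#' Generate a scaffold library across topology classes
#'
#' @param classes Topology class strings (default: the seven standard
#'   classes from [enumerate_topology_classes()]).
#' @param n_per_class Scaffolds per class.
#' @param seed Base seed; scaffold k of class c gets its own derived seed.
#' @param max_tries Per-scaffold build attempts.
#' @return List with `scaffolds` (list) and `manifest` (data.frame: id,
#'   class, length, seed, sequence).
#' @export
scaffold_library <- function(classes = enumerate_topology_classes(),
                             n_per_class = 8, seed = 1, max_tries = 200) {
  scaffolds <- list()
  rows <- list()
  k <- 0
  for (ci in seq_along(classes)) {
    bp <- default_blueprint(classes[ci])
    made <- 0; s <- 0
    while (made < n_per_class && s < n_per_class * 50) {
      s <- s + 1
      sc_seed <- seed + ci * 100000L + s
      sc <- tryCatch(build_scaffold(bp, seed = sc_seed, max_tries = max_tries),
                     error = function(e) NULL)
      if (is.null(sc)) next
      made <- made + 1; k <- k + 1
      sc$id <- sprintf("%s_%03d", classes[ci], made)
      scaffolds[[k]] <- sc
      rows[[k]] <- data.frame(id = sc$id, class = sc$class_id,
                              length = n_res(sc$bb), seed = sc_seed,
                              sequence = sc$sequence)
    }
  }
  list(scaffolds = scaffolds, manifest = do.call(rbind, rows))
}

#' Convert a scaffold to a single-chain structure model
#'
#' @param scaffold A `scaffold` with sequence assigned.
#' @param chain Chain id (docked capping scaffolds conventionally use "Z").
#' @export
scaffold_to_model <- function(scaffold, chain = "Z") {
  model_from_backbone(scaffold$bb, chain = chain,
                      sequence = scaffold$sequence,
                      source = sprintf("scaffold %s seed %d",
                                       scaffold$class_id, scaffold$seed))
}
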