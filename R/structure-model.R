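# Hierarchical atomic structure model: chains -> residues -> atoms, stored
# as a flat atom table (bio3d idiom) with accessors that expose the
# hierarchy. Coordinates are Angstrom everywhere.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- structure(AA3, names = AA1)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure model
#'
#' A `structure_model` is an ordered hierarchy chain -> residue -> atom held
#' as a single atom table. Chains keep file order; residues within a chain
#' are ordered by (resno, icode); atoms keep their order within a residue.
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer author
#'   numbering), `icode` (insertion code, "" when absent), `resid` (3-letter
#'   residue name), `elety` (atom name), `elesy` (element symbol), `x`, `y`,
#'   `z` (Angstrom), and optionally `eleno` (serial).
#' @param source Provenance string (e.g. the file the model was read from).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "constructed") {
  req <- c("chain", "resno", "icode", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!nzchar(atoms$elety))) stop("empty atom names in atom table")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$chain <- as.character(atoms$chain)
  atoms$icode <- as.character(atoms$icode)
  atoms$resno <- as.integer(atoms$resno)
  # stable sort: chains in first-seen order, residues by (resno, icode)
  chain_order <- match(atoms$chain, unique(atoms$chain))
  ord <- order(chain_order, atoms$resno, atoms$icode)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- chain_ids(x)
  cat(sprintf("structure_model: %d chains, %d residues, %d atoms [%s]\n",
              length(ch),
              nrow(unique(x$atoms[, c("chain", "resno", "icode")])),
              nrow(x$atoms), x$source))
  invisible(x)
}

#' Chain identifiers in file order
#' @param model A `structure_model`.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Atom table of one chain
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @export
chain_atoms <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no such chain: ", chain)
  at
}

residue_keys <- function(atoms) paste(atoms$resno, atoms$icode, sep = "|")

#' One-letter sequence of a chain
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @export
chain_sequence <- function(model, chain) {
  at <- chain_atoms(model, chain)
  keys <- residue_keys(at)
  first <- !duplicated(keys)
  paste(AA1[at$resid[first]], collapse = "")
}

#' Backbone coordinates of a chain
#'
#' Extracts per-residue N/CA/C/O coordinates in residue order. Residues with
#' an incomplete backbone are dropped (with a warning) so downstream geometry
#' always sees complete frames.
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @return List with `bb` (a `backbone`), `resno`, `icode`, `resid` of the
#'   retained residues.
#' @export
chain_backbone <- function(model, chain) {
  at <- chain_atoms(model, chain)
  keys <- residue_keys(at)
  ukeys <- unique(keys)
  n <- length(ukeys)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  resno <- integer(n); icode <- character(n); resid <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    r <- at[keys == ukeys[i], , drop = FALSE]
    resno[i] <- r$resno[1]; icode[i] <- r$icode[1]; resid[i] <- r$resid[1]
    ok <- TRUE
    for (nm in BACKBONE_ATOMS) {
      j <- match(nm, r$elety)
      if (is.na(j)) { ok <- FALSE; break }
      xyz <- as.numeric(r[j, c("x", "y", "z")])
      switch(nm, N = { N[i, ] <- xyz }, CA = { CA[i, ] <- xyz },
             C = { C[i, ] <- xyz }, O = { O[i, ] <- xyz })
    }
    keep[i] <- ok
  }
  if (!all(keep)) {
    warning(sum(!keep), " residue(s) with incomplete backbone dropped in chain ", chain)
  }
  list(bb = structure(list(N = N[keep, , drop = FALSE], CA = CA[keep, , drop = FALSE],
                           C = C[keep, , drop = FALSE], O = O[keep, , drop = FALSE]),
                      class = "backbone"),
       resno = resno[keep], icode = icode[keep], resid = resid[keep])
}

#' Build a single-chain structure model from a backbone
#'
#' @param bb A `backbone` object.
#' @param chain Chain id for the new chain.
#' @param sequence One-letter sequence (length = residues); default poly-ALA.
#' @param resno Author residue numbers; default 1..n.
#' @param source Provenance string.
#' @export
model_from_backbone <- function(bb, chain = "A", sequence = NULL, resno = NULL,
                                source = "constructed") {
  n <- n_res(bb)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  if (is.null(resno)) resno <- seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- data.frame(
      chain = chain, resno = resno[i], icode = "",
      resid = unname(AA3_FROM_1[aa[i]]),
      elety = BACKBONE_ATOMS,
      elesy = c("N", "C", "C", "O"),
      x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
      y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
      z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
      stringsAsFactors = FALSE
    )
  }
  structure_model(do.call(rbind, rows), source = source)
}

#' Merge several structure models into one
#'
#' Chains must not collide; atom serials are renumbered.
#' @param ... `structure_model` objects.
#' @param source Provenance for the merged model.
#' @export
merge_models <- function(..., source = "merged") {
  models <- list(...)
  ats <- lapply(models, function(m) m$atoms)
  all_at <- do.call(rbind, ats)
  if (anyDuplicated(unique(unlist(lapply(models, chain_ids))))) {
    stop("duplicate chain ids across merged models")
  }
  all_at$eleno <- seq_len(nrow(all_at))
  structure_model(all_at, source = source)
}

#' Heavy-atom coordinates of a model
#' @param model A `structure_model`.
#' @return n x 3 matrix (hydrogens excluded).
#' @export
heavy_coords <- function(model) {
  at <- model$atoms[!(model$atoms$elesy %in% c("H", "D")), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Apply a rigid transform to a whole model
#' @param model A `structure_model`.
#' @param tf A `rigid_transform`.
#' @export
transform_model <- function(model, tf) {
  xyz <- apply_transform(as.matrix(model$atoms[, c("x", "y", "z")]), tf)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
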