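# Reading and writing atomic structures (PDB and mmCIF).
#
# Parsing of both formats is delegated to bio3d; mmCIF output is written
# directly as a minimal atom_site loop (no R package currently writes
# mmCIF). Only standard amino-acid atoms are kept: waters, ligands and
# hydrogens are skipped on input, and alternate locations are resolved to
# the highest-occupancy conformer (ties: first seen).

## single-character chain alphabet usable in the PDB dialect
PDB_CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

detect_format <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "pdb", "mmcif"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  stop("cannot detect structure format from extension: ", path)
}

#' Read an atomic structure
#'
#' Reads a PDB or mmCIF file into a [structure_model()]. All ATOM/HETATM
#' records with standard amino-acid residue names are kept; waters, other
#' heteroatoms and hydrogens are skipped; alternate locations are resolved
#' to the highest-occupancy copy; only the first model of a multi-model
#' file is used.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect from extension).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- detect_format(path, format)
  pdb <- if (fmt == "pdb") {
    bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, multi = FALSE,
                                     verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no standard protein atoms in ", path)
  elesy <- at$elesy
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", at$elety)), 1, 1))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess[is.na(elesy) | !nzchar(elesy)]
  at$elesy <- elesy
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no protein heavy atoms in ", path)
  # resolve altlocs: highest occupancy wins, ties broken by file order
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  icode <- ifelse(is.na(at$insert), "", as.character(at$insert))
  key <- paste(at$chain, at$resno, icode, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  icode <- icode[ord]
  keep <- !duplicated(key[ord])
  at <- at[keep, , drop = FALSE]
  icode <- icode[keep]
  structure_model(
    data.frame(chain = as.character(at$chain),
               resno = as.integer(at$resno),
               icode = icode,
               resid = as.character(at$resid),
               elety = as.character(at$elety),
               elesy = as.character(at$elesy),
               x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
               eleno = seq_len(nrow(at)),
               stringsAsFactors = FALSE),
    source = path
  )
}

#' Write an atomic structure
#'
#' Writes a [structure_model()] as PDB or mmCIF. Chain ids and author
#' residue numbering (including insertion codes) are preserved. The PDB
#' dialect is limited to 62 single-character chain ids; larger assemblies
#' must be written as mmCIF.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect from extension).
#' @export
write_structure <- function(model, path, format = "auto") {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$atoms) == 0) stop("empty model: nothing to write")
  fmt <- detect_format(path, format)
  at <- model$atoms
  if (fmt == "pdb") {
    ch <- chain_ids(model)
    if (length(ch) > 62 || any(nchar(ch) > 1)) {
      stop("model has >62 chains or multi-character chain ids; ",
           "the PDB dialect cannot represent this - write mmCIF instead")
    }
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(at)),
                     resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     chain = at$chain,
                     insert = ifelse(nzchar(at$icode), at$icode, ""),
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                     elesy = at$elesy)
  } else {
    write_mmcif_atoms(at, path)
  }
  invisible(path)
}

## Minimal mmCIF atom_site writer (one data block, one model).
write_mmcif_atoms <- function(at, path) {
  hdr <- c(
    "data_fibrilcap",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(at)), at$elesy, at$elety, at$resid, at$chain, at$resno,
    ifelse(nzchar(at$icode), at$icode, "?"),
    at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety
  )
  writeLines(c(hdr, rows, "#"), path)
}
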