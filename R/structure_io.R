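#' @include plafusion-package.R
NULL

# MDL bond-order codes; 4 marks an aromatic bond as in the V2000 spec.
BOND_ORDERS <- c(1L, 2L, 3L, 4L)
AROMATIC_BOND <- 4L

#' Construct a ligand record
#'
#' A ligand is a molecular graph with 3D coordinates: a table of atoms
#' (element symbol, x/y/z in Angstrom, formal charge) and a table of bonds
#' (1-based atom indices `i`, `j` and an MDL order code 1/2/3, or 4 for
#' aromatic).
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `charge`.
#' @param bonds data.frame with columns `i`, `j`, `order` (may have 0 rows).
#' @param name identifier string.
#' @param smiles optional SMILES string carried through from an SDF property
#'   block; never computed internally.
#' @return An object of class `pla_ligand`.
#' @export
new_ligand <- function(atoms, bonds, name = "ligand", smiles = NULL) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "x", "y", "z", "charge") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty molecule: ligand must have at least one atom")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("ligand coordinates must be finite")
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    bad <- bonds$i < 1L | bonds$j < 1L | bonds$i > nrow(atoms) |
      bonds$j > nrow(atoms) | bonds$i == bonds$j
    if (any(bad)) stop("bond endpoints must be distinct valid atom indices")
    if (!all(bonds$order %in% BOND_ORDERS))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(list(name = name, atoms = atoms, bonds = bonds, smiles = smiles),
            class = "pla_ligand")
}

#' @export
print.pla_ligand <- function(x, ...) {
  cat(sprintf("<pla_ligand> %s: %d atoms, %d bonds\n",
              x$name, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Construct a pocket record
#'
#' A binding pocket is an ordered list of residues (name, chain, residue
#' number) plus heavy-atom coordinates, each atom owned by one residue.
#' The one-letter sequence covers the retained standard residues only.
#'
#' @param residues data.frame with columns `resid` (3-letter name), `chain`,
#'   `resno`.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `res_index` (1-based index into `residues`).
#' @return An object of class `pla_pocket` with a `sequence` field.
#' @export
new_pocket <- function(residues, atoms) {
  residues <- as.data.frame(residues)
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("resid", "chain", "resno") %in% names(residues)),
            all(c("element", "x", "y", "z", "res_index") %in% names(atoms)))
  if (nrow(residues) == 0L) stop("empty pocket: no residues")
  if (nrow(atoms) == 0L) stop("empty pocket: no atoms")
  if (any(atoms$res_index < 1L | atoms$res_index > nrow(residues)))
    stop("atom res_index out of range")
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  structure(list(residues = residues, atoms = atoms,
                 sequence = residues_to_sequence(residues$resid)),
            class = "pla_pocket")
}

#' @export
print.pla_pocket <- function(x, ...) {
  cat(sprintf("<pla_pocket> %d residues, %d atoms, sequence %s\n",
              nrow(x$residues), nrow(x$atoms),
              if (nchar(x$sequence) > 24)
                paste0(substr(x$sequence, 1, 24), "...") else x$sequence))
  invisible(x)
}

#' Construct a complex sample
#'
#' One pocket + ligand pair with an optional binding-affinity label in pK
#' units; the atomic unit of training and prediction.
#'
#' @param ligand a `pla_ligand`.
#' @param pocket a `pla_pocket`.
#' @param label optional affinity in pK units (finite; typically 0-16).
#' @param id identifier string.
#' @return An object of class `pla_complex`.
#' @export
new_complex_sample <- function(ligand, pocket, label = NULL, id = "complex") {
  stopifnot(inherits(ligand, "pla_ligand"), inherits(pocket, "pla_pocket"))
  if (!is.null(label)) {
    label <- as.numeric(label)
    if (length(label) != 1L || !is.finite(label))
      stop("label must be a single finite pK value")
  }
  structure(list(id = id, ligand = ligand, pocket = pocket, label = label),
            class = "pla_complex")
}

#' @export
print.pla_complex <- function(x, ...) {
  cat(sprintf("<pla_complex> %s: ligand %d atoms, pocket %d residues, label %s\n",
              x$id, nrow(x$ligand$atoms), nrow(x$pocket$residues),
              if (is.null(x$label)) "NA" else sprintf("%.3f pK", x$label)))
  invisible(x)
}

# ---- SDF -------------------------------------------------------------------

# MDL atom-block charge codes -> formal charge (code 4 is a radical marker).
.mdl_charge_decode <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                        `5` = -1, `6` = -2, `7` = -3)
.mdl_charge_encode <- function(q) {
  code <- match(q, c(3, 2, 1, -1, -2, -3))
  ifelse(is.na(code), 0L, c(1L, 2L, 3L, 5L, 6L, 7L)[code])
}

# Split the lines of an SDF file into records at "$$$$".
.sdf_records <- function(lines) {
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0L) return(list(lines))
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

# Validate one V2000 record's counts line against its atom/bond blocks before
# handing the file to the ChemmineR parser, which mangles mismatches silently.
.validate_v2000_record <- function(rec, record_index) {
  where <- sprintf("SDF record %d", record_index)
  if (length(rec) < 4L) stop(sprintf("%s: truncated before counts line (line 4)", where))
  counts <- rec[4L]
  if (grepl("V3000", counts))
    stop(sprintf("%s: V3000 records are not supported; convert to V2000", where))
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("%s: malformed counts line (line 4): %s", where, counts))
  if (natoms == 0L) stop(sprintf("%s: empty molecule (0 atoms declared)", where))
  if (length(rec) < 4L + natoms + nbonds)
    stop(sprintf("%s: counts line declares %d atoms and %d bonds but the record has only %d block lines",
                 where, natoms, nbonds, length(rec) - 4L))
  for (k in seq_len(natoms)) {
    ln <- rec[4L + k]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                         substr(ln, 21, 30))))
    sym <- trimws(substr(ln, 32, 34))
    if (any(is.na(xyz)) || !nzchar(sym))
      stop(sprintf("%s: line %d is not a valid atom line (counts line declares %d atoms): %s",
                   where, 4L + k, natoms, ln))
  }
  for (k in seq_len(nbonds)) {
    ln <- rec[4L + natoms + k]
    ij <- suppressWarnings(as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6))))
    if (any(is.na(ij)))
      stop(sprintf("%s: line %d is not a valid bond line: %s",
                   where, 4L + natoms + k, ln))
  }
  list(natoms = natoms, nbonds = nbonds)
}

#' Read a ligand from an SDF file
#'
#' Parses an MDL V2000 SDF record into a [new_ligand()] record: elements, 3D
#' coordinates, formal charges (atom-block charge codes, overridden by any
#' `M  CHG` property lines as the format prescribes) and bonds with their
#' order codes. Multi-record files default to the first record.
#'
#' @param path path to an SDF file.
#' @param record 1-based record index within a multi-record file.
#' @return A `pla_ligand`.
#' @export
read_ligand_sdf <- function(path, record = 1L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  recs <- .sdf_records(lines)
  if (record < 1L || record > length(recs))
    stop(sprintf("record %d requested but file has %d record(s)", record, length(recs)))
  rec <- recs[[record]]
  counts <- .validate_v2000_record(rec, record)

  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  sdf <- sdfset[[record]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  # atom-block column 5 is MDL field 2, the charge code
  codes <- if (ncol(ab) >= 5) as.character(ab[, 5]) else rep("0", nrow(ab))
  charge <- unname(.mdl_charge_decode[codes])
  charge[is.na(charge)] <- 0
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines) > 0L) {
    charge <- rep(0, nrow(ab))  # M CHG supersedes all atom-block codes
    for (ln in chg_lines) {
      fields <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      n <- fields[1]
      for (p in seq_len(n)) charge[fields[2 * p]] <- fields[2 * p + 1]
    }
  }
  atoms <- data.frame(element = elements,
                      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
                      charge = charge)
  bonds <- if (counts$nbonds > 0L && !is.null(bb) && nrow(bb) > 0L) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(i = integer(), j = integer(), order = integer())
  db <- ChemmineR::datablock(sdf)
  smiles <- if ("SMILES" %in% names(db)) unname(db[["SMILES"]]) else NULL
  name <- trimws(rec[1L])
  if (!nzchar(name)) name <- basename(path)
  new_ligand(atoms, bonds, name = name, smiles = smiles)
}

#' Write a ligand to an SDF file
#'
#' Emits a fixed-width MDL V2000 record (coordinates at the format's 4-decimal
#' precision, charges as `M  CHG` lines) re-readable by [read_ligand_sdf()].
#'
#' @param ligand a `pla_ligand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(ligand, path) {
  stopifnot(inherits(ligand, "pla_ligand"))
  a <- ligand$atoms
  b <- ligand$bonds
  out <- c(ligand$name, "  plafusion", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element))
  if (nrow(b) > 0L)
    out <- c(out, sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
  charged <- which(a$charge != 0)
  if (length(charged) > 0L) {
    # M CHG lines carry at most 8 (atom, charge) pairs each
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      pairs <- paste(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")
      out <- c(out, sprintf("M  CHG%3d%s", length(grp), pairs))
    }
  }
  out <- c(out, "M  END")
  if (!is.null(ligand$smiles))
    out <- c(out, "> <SMILES>", ligand$smiles, "")
  out <- c(out, "$$$$")
  writeLines(out, path)
  invisible(path)
}

# ---- PDB -------------------------------------------------------------------

# 3-letter -> 1-letter residue codes: the 20 standard amino acids plus the
# mappable nonstandard residues (selenomethionine, selenocysteine).
RESIDUE_CODES <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C")

residues_to_sequence <- function(resids, warn_drops = TRUE) {
  codes <- RESIDUE_CODES[resids]
  dropped <- resids[is.na(codes)]
  if (warn_drops && length(dropped) > 0L)
    message(sprintf("dropping %d unmappable residue(s): %s",
                    length(dropped), paste(unique(dropped), collapse = ", ")))
  paste(codes[!is.na(codes)], collapse = "")
}

#' Read a binding pocket from a PDB file
#'
#' Keeps `ATOM` records only (`HETATM` entries, including waters, are
#' excluded), keeps the first alternate-location variant of each atom, orders
#' residues by (chain, residue number, insertion code), and derives the
#' one-letter pocket sequence. Residues whose 3-letter code cannot be mapped
#' to the 20-letter alphabet (after MSE to M and SEC to C) are dropped from
#' the sequence but their atoms are retained for the spatial graph.
#'
#' @param path path to a PDB file containing the pocket.
#' @param keep_hydrogens keep hydrogen atoms (default drop; PDB pockets
#'   rarely resolve them).
#' @return A `pla_pocket`.
#' @export
read_pocket_pdb <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty pocket: file has no ATOM records")
  if (!keep_hydrogens) at <- at[!(at$elesy %in% "H"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # keep the first altLoc occurrence of each atom
  at <- at[!duplicated(at[, c("chain", "resno", "insert", "elety")]), , drop = FALSE]
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_first <- !duplicated(key)
  residues <- data.frame(resid = at$resid[res_first], chain = at$chain[res_first],
                         resno = at$resno[res_first])
  res_index <- match(key, key[res_first])
  elem <- at$elesy
  # fall back to the first letter of the atom name when the element column
  # is absent (common in minimal files)
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  atoms <- data.frame(element = trimws(elem), x = at$x, y = at$y, z = at$z,
                      res_index = res_index)
  new_pocket(residues, atoms)
}

#' Write a pocket to a PDB file
#'
#' One `ATOM` record per pocket atom (atom names `CA`, `CB`, ... within each
#' residue), re-readable by [read_pocket_pdb()].
#'
#' @param pocket a `pla_pocket`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pocket, path) {
  stopifnot(inherits(pocket, "pla_pocket"))
  a <- pocket$atoms
  r <- pocket$residues
  # name atoms CA, CB, CC ... within each residue so altLoc dedup keys differ
  within_idx <- stats::ave(seq_len(nrow(a)), a$res_index, FUN = seq_along)
  elety <- paste0(a$element, LETTERS[pmin(within_idx, 26L)])
  elety[a$element == "C" & within_idx == 1L] <- "CA"
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = r$resno[a$res_index], resid = r$resid[a$res_index],
                   chain = r$chain[a$res_index], elety = elety,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Pocket one-letter sequence
#'
#' Maps the pocket's retained residues to one-letter codes (MSE to M, SEC to
#' C; unmappable residues dropped with a message).
#'
#' @param pocket a `pla_pocket`.
#' @return One-letter amino-acid string.
#' @export
pocket_sequence <- function(pocket) {
  stopifnot(inherits(pocket, "pla_pocket"))
  seq <- residues_to_sequence(pocket$residues$resid)
  if (!nzchar(seq))
    stop("empty sequence: no residue could be mapped to the 20-letter alphabet")
  seq
}

# ---- affinity index --------------------------------------------------------

#' Read a PDBbind-style affinity index
#'
#' Whitespace-delimited lines `id resolution year pK ...` with `#` comment
#' lines, as distributed with PDBbind index files.
#'
#' @param path path to the index file.
#' @return data.frame with columns `id` and `pk`.
#' @export
read_affinity_index <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.frame(id = character(), pk = numeric()))
  fields <- strsplit(lines, "\\s+")
  data.frame(id = vapply(fields, `[[`, "", 1L),
             pk = vapply(fields, function(f) as.numeric(f[4L]), 0))
}
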