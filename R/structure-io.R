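# Structure ingestion and annotated output.
#
# Conventions used throughout the package:
#   * author residue numbering (plus insertion codes) is the canonical key;
#     residues are never renumbered;
#   * altloc groups are resolved to a single conformer at read time;
#   * a chain break is flagged after residue i whenever C(i)-N(i+1) exceeds
#     a distance cutoff (default 2.5 Angstrom); torsions are never computed
#     across a flagged break.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a protein structure object from an atom table
#'
#' Low-level constructor used by [read_pdb()] and by the synthetic-structure
#' generators. The atom table must already be altloc-resolved (one row per
#' atom). Residues are ordered within each chain by (author number,
#' insertion code) and chain breaks are flagged from the C(i)-N(i+1)
#' distance.
#'
#' @param atoms data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`, `o`, `b`.
#' @param id free-text identifier.
#' @param break_cutoff C(i)-N(i+1) distance (Angstrom) beyond which a chain
#'   break is flagged after residue i.
#' @param metadata optional list (source path, model index, ...).
#' @return An object of class `pet_structure` with components `id`, `atoms`,
#'   `residues` (one row per residue, with `chain_break_after`), and
#'   `metadata`.
#' @export
new_structure <- function(atoms, id = "structure", break_cutoff = 2.5,
                          metadata = list()) {
  req <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z", "o", "b")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }

  chains <- unique(atoms$chain)
  ord <- order(match(atoms$chain, chains), atoms$resno, atoms$insert,
               match(atoms$elety, c(.BACKBONE_ATOMS,
                                    setdiff(unique(atoms$elety), .BACKBONE_ATOMS))))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL

  key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  dup <- duplicated(paste(key, atoms$elety))
  if (any(dup)) {
    stop("duplicate atom records after altloc resolution: ",
         paste(unique(key[dup]), collapse = ", "))
  }

  first <- !duplicated(key)
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    insert = atoms$insert[first], resid = atoms$resid[first],
    key = key[first], stringsAsFactors = FALSE
  )

  residues$chain_break_after <- FALSE
  for (ch in chains) {
    idx <- which(residues$chain == ch)
    if (length(idx) < 2L) next
    for (k in idx[-length(idx)]) {
      a_c <- .atom_xyz(atoms, residues$key[k], "C")
      a_n <- .atom_xyz(atoms, residues$key[k + 1L], "N")
      brk <- if (anyNA(a_c) || anyNA(a_n)) TRUE else vnorm(a_c - a_n) > break_cutoff
      residues$chain_break_after[k] <- brk
    }
  }

  structure(list(id = id, atoms = atoms, residues = residues,
                 metadata = metadata),
            class = "pet_structure")
}

.atom_xyz <- function(atoms, key, elety) {
  i <- which(residue_key(atoms$chain, atoms$resno, atoms$insert) == key &
               atoms$elety == elety)
  if (length(i) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  c(atoms$x[i[1L]], atoms$y[i[1L]], atoms$z[i[1L]])
}

#' @export
print.pet_structure <- function(x, ...) {
  cat(sprintf("<pet_structure '%s': %d chain(s), %d residue(s), %d atom(s)>\n",
              x$id, length(unique(x$residues$chain)), nrow(x$residues),
              nrow(x$atoms)))
  invisible(x)
}

#' Read a protein backbone from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the backbone atoms
#' (N, CA, C, O) of the twenty standard amino acids plus selenomethionine
#' (MSE), resolves alternate locations, and flags chain breaks.
#'
#' @param path PDB file.
#' @param model_index 1-based model to read from a multi-model file
#'   (default: first).
#' @param altloc_policy only `"highest_occupancy"` is implemented: within an
#'   altloc group the conformer with the highest occupancy wins, ties broken
#'   by altloc letter (alphabetical).
#' @param break_cutoff chain-break distance cutoff in Angstrom.
#' @return A [new_structure()] object.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' s0 <- make_ideal_structure(5, "helix")
#' write_annotated_pdb(s0, path = pdb)
#' s <- read_pdb(pdb)
#' extract_sequence(s, "A")
#' @export
read_pdb <- function(path, model_index = 1L,
                     altloc_policy = "highest_occupancy",
                     break_cutoff = 2.5) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  altloc_policy <- match.arg(altloc_policy, "highest_occupancy")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    stop("model ", model_index, " not present (file has ", n_models,
         " model(s))")
  }
  at <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else pdb$xyz
  at$x <- xyz[seq(1L, length(xyz), 3L)]
  at$y <- xyz[seq(2L, length(xyz), 3L)]
  at$z <- xyz[seq(3L, length(xyz), 3L)]

  keep <- (at$resid %in% names(.AA3) & at$type == "ATOM") | at$resid == "MSE"
  keep <- keep & at$elety %in% .BACKBONE_ATOMS
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard-residue backbone atoms in ", path)

  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: highest occupancy first, ties by altloc letter
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(grp, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(grp[ord]), , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      o = pmin(pmax(at$o, 0), 1), b = at$b,
                      stringsAsFactors = FALSE)
  atoms$b[is.na(atoms$b)] <- 0
  new_structure(atoms, id = basename(path), break_cutoff = break_cutoff,
                metadata = list(source = path, model_index = model_index,
                                n_models = n_models))
}

#' Extract a one-letter amino-acid sequence from a chain
#'
#' Residues without a standard one-letter code (including MSE) map to `"X"`.
#'
#' @param s a `pet_structure`.
#' @param chain_id chain identifier.
#' @return Character scalar, one letter per residue in chain order.
#' @export
extract_sequence <- function(s, chain_id) {
  stopifnot(inherits(s, "pet_structure"))
  if (!chain_id %in% s$residues$chain) stop("no such chain: '", chain_id, "'")
  res <- s$residues$resid[s$residues$chain == chain_id]
  letters1 <- unname(.AA3[res])
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' List chain identifiers of a structure
#' @param s a `pet_structure`.
#' @return Character vector of chain ids in order of appearance.
#' @export
structure_chains <- function(s) unique(s$residues$chain)

# CA coordinate matrix for one chain; rownames are residue keys, rows with
# missing CA are NA.
ca_coords <- function(s, chain_id) {
  res <- s$residues[s$residues$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0L) stop("no such chain: '", chain_id, "'")
  m <- t(vapply(res$key, function(k) .atom_xyz(s$atoms, k, "CA"), numeric(3L)))
  rownames(m) <- res$key
  m
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Emits standard PDB text with each atom's temperature-factor column
#' replaced by its residue's value (two decimals), the convention molecular
#' viewers read for putty-tube thickness/colour rendering of a per-residue
#' scalar. Residues without a value are written as 0.00.
#'
#' @param s a `pet_structure`.
#' @param values named numeric vector keyed by residue key
#'   (`"<chain>:<resno><icode>"`, see [residue_keys()]), or `NULL` for all
#'   zeros.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_pdb <- function(s, values = NULL, path) {
  stopifnot(inherits(s, "pet_structure"))
  b <- stats::setNames(rep(0, nrow(s$residues)), s$residues$key)
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    unknown <- setdiff(names(values), s$residues$key)
    if (length(unknown) > 0L) {
      stop("values supplied for unknown residues: ",
           paste(unknown, collapse = ", "))
    }
    bad <- names(values)[values > 999.99 | values < -99.99]
    if (length(bad) > 0L) {
      stop("value not representable in the PDB B-factor column (F6.2) for ",
           "residue(s): ", paste(bad, collapse = ", "))
    }
    b[names(values)] <- values
  }
  akey <- residue_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  xyz <- as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(s$atoms)),
                   resno = s$atoms$resno, resid = s$atoms$resid,
                   eleno = seq_len(nrow(s$atoms)), elety = s$atoms$elety,
                   chain = s$atoms$chain, insert = s$atoms$insert,
                   o = s$atoms$o, b = unname(b[akey]))
  invisible(path)
}

#' Residue keys of a structure
#' @param s a `pet_structure`.
#' @param chain_id optional chain filter.
#' @return Character vector `"<chain>:<resno><icode>"` in residue order.
#' @export
residue_keys <- function(s, chain_id = NULL) {
  res <- s$residues
  if (!is.null(chain_id)) res <- res[res$chain == chain_id, , drop = FALSE]
  res$key
}
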