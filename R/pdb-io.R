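#' Read a protein structure from a PDB file
#'
#' Parses a fixed-column PDB file (via bio3d) into a [structure_model()].
#' Coordinates are converted from Angstrom to nm.  Alternate locations
#' other than 'A' or blank are dropped with a warning, so the topology is
#' deterministic.  Hetero ions (MG, CL) and waters are retained as
#' single-atom residues; insertion codes are preserved in the numbering map.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = "pdb") {
  match.arg(format, "pdb")
  parsed <- .parse_pdb(path)
  .build_model(parsed, parsed$xyz[1, ])
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each MODEL/ENDMDL block becomes one frame; a single un-modeled PDB file
#' counts as one frame.  The topology is taken from the first model and all
#' models must list the same atoms in the same order.
#'
#' @inheritParams read_structure
#' @param frame_interval time between frames, ns.
#' @param replicate_id,system_id identifiers attached to the ensemble.
#' @return an [ensemble()].
#' @export
read_ensemble <- function(path, frame_interval = 1, format = "pdb",
                          replicate_id = "rep1", system_id = "system") {
  match.arg(format, "pdb")
  parsed <- .parse_pdb(path)
  topo <- .build_model(parsed, parsed$xyz[1, ])
  ensemble(topo, parsed$xyz, frame_interval = frame_interval,
           replicate_id = replicate_id, system_id = system_id)
}

# Pre-scan the raw records for the validation the parser contract requires
# (model bookkeeping, malformed coordinates), then parse with bio3d.
.parse_pdb <- function(path) {
  if (!file.exists(path)) .stopf("cannot read PDB file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) .stopf("empty structure: no ATOM/HETATM records in %s", path)

  n_model <- sum(startsWith(lines, "MODEL"))
  n_endmdl <- sum(startsWith(lines, "ENDMDL"))
  if (n_model != n_endmdl) {
    .stopf("parse error in %s: %d MODEL but %d ENDMDL records",
           path, n_model, n_endmdl)
  }
  if (n_model > 0) {
    model_id <- cumsum(startsWith(lines, "MODEL"))
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1) {
      ref <- as.integer(counts[1])
      bad <- names(counts)[as.integer(counts) != ref][1]
      .stopf("atom count mismatch in model %s of %s (%d atoms, expected %d)",
             bad, path, as.integer(counts[bad]), ref)
    }
  }
  coord_txt <- substr(lines[is_atom], 31, 54)
  xok <- grepl("^[-+ .0-9]+$", coord_txt) & grepl("[0-9]", coord_txt)
  if (!all(xok)) {
    .stopf("malformed coordinates in %s at ATOM record %d",
           path, which(!xok)[1])
  }

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) .stopf("cannot parse PDB file %s: %s",
                               path, conditionMessage(e))
  )
  atom <- pdb$atom
  keep <- is.na(atom$alt) | atom$alt %in% c("", "A")
  if (!all(keep)) {
    warning(sprintf("dropping %d alternate-location atoms (keeping altLoc 'A'/blank)",
                    sum(!keep)), call. = FALSE)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, .xyz_idx(which(keep)), drop = FALSE] * .NM_PER_ANGSTROM
  atom <- atom[keep, , drop = FALSE]

  insert <- ifelse(is.na(atom$insert), "", atom$insert)
  chain <- ifelse(is.na(atom$chain), "A", atom$chain)
  res_key <- paste(chain, atom$resno, insert, sep = "|")
  ordinal <- cumsum(!duplicated(res_key))[match(res_key, res_key)]
  # recompute as running index in file order
  ordinal <- cumsum(c(TRUE, res_key[-1] != res_key[-length(res_key)]))

  element <- atom$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- .element_from_name(atom$elety[blank])
  element <- trimws(element)

  list(
    atoms = data.frame(
      name = trimws(atom$elety),
      element = element,
      residue_ordinal = ordinal,
      residue_name = trimws(atom$resid),
      chain_id = chain,
      resno = atom$resno,
      insert = insert,
      stringsAsFactors = FALSE
    ),
    xyz = xyz
  )
}

.build_model <- function(parsed, coords_row) {
  atoms <- parsed$atoms
  first <- !duplicated(atoms$residue_ordinal)
  label <- paste0(atoms$resno[first], atoms$insert[first])
  if (anyDuplicated(label)) {
    label <- paste0(atoms$chain_id[first], ":", label)
  }
  coords <- matrix(coords_row, ncol = 3, byrow = TRUE)
  structure_model(atoms[, c("name", "element", "residue_ordinal",
                            "residue_name", "chain_id")],
                  coords, numbering_map = label)
}

#' Write a structure or ensemble as a (multi-model) PDB file
#'
#' Coordinates are converted from nm back to Angstrom.  Residue numbers and
#' insertion codes are recovered from the numbering map where its labels
#' look like PDB residue numbers (e.g. "52" or "52A"); otherwise residue
#' ordinals are written.
#'
#' @param x a `structure_model` or `ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) {
    topo <- x
    xyz <- matrix(as.numeric(t(x$coords)), nrow = 1)
  } else if (inherits(x, "ensemble")) {
    topo <- x$topology
    xyz <- x$xyz
  } else {
    .stopf("x must be a structure_model or ensemble")
  }
  lab <- topo$residues$label
  m <- regmatches(lab, regexec("^(?:[A-Za-z]:)?(-?[0-9]+)([A-Za-z]?)$", lab))
  ok <- lengths(m) == 3
  resno_res <- ifelse(ok, vapply(m, function(g) g[2], ""), NA)
  resno_res <- suppressWarnings(as.integer(resno_res))
  resno_res[is.na(resno_res)] <- topo$residues$ordinal[is.na(resno_res)]
  insert_res <- ifelse(ok, vapply(m, function(g) g[3], ""), "")
  idx <- match(topo$atoms$residue_ordinal, topo$residues$ordinal)

  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = xyz / .NM_PER_ANGSTROM,
    type = ifelse(topo$atoms$residue_name %in% .STD_AA, "ATOM", "HETATM"),
    resno = resno_res[idx],
    resid = topo$atoms$residue_name,
    insert = insert_res[idx],
    chain = topo$atoms$chain_id,
    eleno = seq_len(n_atoms(topo)),
    elety = topo$atoms$name,
    elesy = topo$atoms$element
  )
  invisible(path)
}
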