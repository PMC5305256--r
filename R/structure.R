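#' Structure and ensemble containers
#'
#' `structure_model()` builds the static-topology object used throughout the
#' package: an ordered atom table plus coordinates in nm and a residue-level
#' numbering map carrying the reference (PDB/author) residue labels.
#' `ensemble()` wraps a topology together with an ordered set of coordinate
#' frames (a conformational ensemble, e.g. one molecular-dynamics replicate),
#' and `replicate_set()` groups replicates of the same system.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_ordinal`
#'   (1-based serial index of the residue within the model), `residue_name`
#'   (3-letter code), `chain_id`.
#' @param coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @param numbering_map optional character vector, one label per residue
#'   ordinal, giving the user-facing (reference) residue numbering.
#'   Defaults to the ordinal as character.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, coords, numbering_map = NULL) {
  req <- c("name", "element", "residue_ordinal", "residue_name", "chain_id")
  .assert(all(req %in% names(atoms)), "atoms must have columns: %s",
          paste(req, collapse = ", "))
  coords <- as.matrix(coords)
  .assert(nrow(coords) == nrow(atoms) && ncol(coords) == 3,
          "coords must be an n_atoms x 3 matrix")
  .assert(all(is.finite(coords)), "coordinates must be finite")
  bad <- setdiff(unique(atoms$residue_name), c(.STD_AA, .HETERO_OK))
  .assert(length(bad) == 0,
          "unknown residue name(s): %s", paste(bad, collapse = ", "))

  atoms$name <- trimws(as.character(atoms$name))
  atoms$is_backbone <- atoms$name %in% .BACKBONE_NAMES &
    atoms$residue_name %in% .STD_AA
  atoms$is_hydrogen <- toupper(atoms$element) == "H"

  # duplicate atom names within a residue are topology errors
  key <- paste(atoms$residue_ordinal, atoms$name)
  if (anyDuplicated(key)) {
    d <- atoms[duplicated(key), , drop = FALSE][1, ]
    .stopf("duplicate atom '%s' in residue %s %s",
           d$name, d$residue_name, d$residue_ordinal)
  }

  ord <- !duplicated(atoms$residue_ordinal)
  residues <- data.frame(
    ordinal = atoms$residue_ordinal[ord],
    residue_name = atoms$residue_name[ord],
    chain_id = atoms$chain_id[ord],
    stringsAsFactors = FALSE
  )
  # ordinals must increase in atom order within each chain
  for (ch in unique(residues$chain_id)) {
    o <- residues$ordinal[residues$chain_id == ch]
    .assert(all(diff(o) > 0), "residue ordinals not strictly increasing in chain %s", ch)
  }
  if (is.null(numbering_map)) {
    numbering_map <- as.character(residues$ordinal)
  }
  .assert(length(numbering_map) == nrow(residues),
          "numbering_map must have one label per residue")
  .assert(!anyDuplicated(numbering_map), "numbering_map labels must be unique")
  residues$label <- as.character(numbering_map)

  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, residues = residues),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains: %s\n",
              n_atoms(x), nrow(x$residues),
              paste(unique(x$residues$chain_id), collapse = ",")))
  invisible(x)
}

#' @rdname structure_model
#' @param x a `structure_model` or `ensemble`.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.structure_model <- function(x) nrow(x$atoms)

#' @export
n_atoms.ensemble <- function(x) nrow(x$topology$atoms)

#' Residue labels of a structure via its numbering map
#' @param x a `structure_model`.
#' @return character vector of user-facing residue labels.
#' @export
residue_labels <- function(x) x$residues$label

#' @rdname structure_model
#' @param topology a `structure_model` giving the shared topology.
#' @param xyz frames as an `n_frames x 3*n_atoms` matrix in nm, coordinate
#'   order `x1,y1,z1,x2,...` (one conformation per row), or a list of
#'   `n_atoms x 3` matrices.
#' @param frame_interval time between stored frames, ns.
#' @param replicate_id,system_id identifiers carried into all outputs.
#' @export
ensemble <- function(topology, xyz, frame_interval = 1,
                     replicate_id = "rep1", system_id = "system") {
  .assert(inherits(topology, "structure_model"), "topology must be a structure_model")
  if (is.list(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(f) as.numeric(t(f))))
  }
  xyz <- as.matrix(xyz)
  .assert(ncol(xyz) == 3 * n_atoms(topology),
          "frames have %d coordinates but topology has %d atoms",
          ncol(xyz), n_atoms(topology))
  .assert(nrow(xyz) >= 1, "an ensemble needs at least one frame")
  .assert(is.numeric(frame_interval) && frame_interval > 0,
          "frame_interval must be > 0")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval = frame_interval,
                 replicate_id = replicate_id, system_id = system_id),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble '%s/%s': %d frames x %d atoms, dt = %g ns\n",
              x$system_id, x$replicate_id, n_frames(x), n_atoms(x),
              x$frame_interval))
  invisible(x)
}

#' @rdname structure_model
#' @export
n_frames <- function(x) {
  .assert(inherits(x, "ensemble"), "x must be an ensemble")
  nrow(x$xyz)
}

#' Extract one frame of an ensemble as an n_atoms x 3 matrix (nm)
#' @param ens an `ensemble`.
#' @param i frame index.
#' @export
frame_coords <- function(ens, i) {
  .assert(i >= 1 && i <= n_frames(ens), "frame index out of range")
  matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @rdname structure_model
#' @param ensembles list of `ensemble` objects sharing one topology.
#' @export
replicate_set <- function(ensembles, system_id = NULL) {
  .assert(length(ensembles) >= 1, "need at least one ensemble")
  .assert(all(vapply(ensembles, inherits, logical(1), "ensemble")),
          "all elements must be ensembles")
  na <- vapply(ensembles, n_atoms, integer(1))
  .assert(length(unique(na)) == 1, "ensembles differ in atom count")
  r1 <- ensembles[[1]]$topology$residues$residue_name
  for (e in ensembles[-1]) {
    .assert(identical(e$topology$residues$residue_name, r1),
            "ensembles differ in residue list")
  }
  ids <- vapply(ensembles, function(e) e$replicate_id, character(1))
  .assert(!anyDuplicated(ids), "replicate_ids must be unique")
  if (is.null(system_id)) system_id <- ensembles[[1]]$system_id
  structure(list(system_id = system_id, ensembles = ensembles),
            class = "replicate_set")
}

#' Select atom indices of a structure
#'
#' Selections are how every analysis names its atom subset: a keyword
#' (`"calpha"` for C-alpha atoms, `"mainchain"` for N/CA/C/O,
#' `"all-heavy"` for non-hydrogens, `"all"`), a logical or integer index
#' vector, or a predicate function over the atom table.
#'
#' @param topology a `structure_model`.
#' @param selection keyword, index vector, logical vector, or function
#'   taking the atom data.frame and returning a logical vector.
#' @return integer atom indices (possibly empty).
#' @export
select_atoms <- function(topology, selection = "calpha") {
  atoms <- topology$atoms
  if (is.function(selection)) return(which(selection(atoms)))
  if (is.logical(selection)) {
    .assert(length(selection) == nrow(atoms), "logical selection length mismatch")
    return(which(selection))
  }
  if (is.numeric(selection)) {
    .assert(all(selection >= 1 & selection <= nrow(atoms)),
            "atom indices out of range")
    return(as.integer(selection))
  }
  std <- atoms$residue_name %in% .STD_AA
  switch(match.arg(selection, c("calpha", "mainchain", "all-heavy", "all")),
         "calpha" = which(atoms$name == "CA" & std),
         "mainchain" = which(atoms$is_backbone),
         "all-heavy" = which(!atoms$is_hydrogen),
         "all" = seq_len(nrow(atoms)))
}

# xyz-index triplets for a set of atom indices
.xyz_idx <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}
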