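#' Least-squares (Kabsch) superposition of ensemble frames
#'
#' Rigid-body fits every frame onto a reference conformation, minimising
#' the RMSD over the selected atoms.  The rotation+translation is applied
#' to all atoms, so each frame's internal geometry is untouched.
#'
#' @param ens an [ensemble()].
#' @param reference reference coordinates: an `n_atoms x 3` matrix in nm, a
#'   `structure_model`, or `NULL` to use the first frame.
#' @param selection atoms used for the fit (see [select_atoms()]);
#'   default C-alpha.
#' @return the ensemble with fitted frames.
#' @export
superpose_frames <- function(ens, reference = NULL, selection = "calpha") {
  .assert(inherits(ens, "ensemble"), "ens must be an ensemble")
  ref <- .as_ref_xyz(reference, ens)
  sel <- select_atoms(ens$topology, selection)
  .assert(length(sel) >= 3, "degenerate fit: selection matches %d atoms (need >= 3)",
          length(sel))
  refsel <- matrix(ref[.xyz_idx(sel)], ncol = 3, byrow = TRUE)
  # collinearity check: centred selected reference points must span a plane
  sv <- svd(scale(refsel, scale = FALSE))$d
  .assert(sv[2] > 1e-9, "degenerate fit: selected reference atoms are collinear")

  fitted <- bio3d::fit.xyz(fixed = ref, mobile = ens$xyz,
                           fixed.inds = .xyz_idx(sel),
                           mobile.inds = .xyz_idx(sel))
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  ens$xyz <- unclass(fitted)
  ens
}

.as_ref_xyz <- function(reference, ens) {
  if (is.null(reference)) return(ens$xyz[1, ])
  if (inherits(reference, "structure_model")) {
    reference <- reference$coords
  }
  if (is.matrix(reference) && ncol(reference) == 3) {
    reference <- as.numeric(t(reference))
  }
  .assert(length(reference) == ncol(ens$xyz),
          "reference atom count does not match the ensemble")
  as.numeric(reference)
}

#' Pairwise fitted RMSD matrix between frames
#'
#' All-vs-all least-squares-fitted RMSD over the selected atoms, pooling
#' the frames of the supplied ensembles.  This is the distance matrix that
#' the clustering- and embedding-based ensemble-similarity methods consume.
#'
#' @param ensembles an `ensemble` or list of ensembles sharing a topology.
#' @param selection atoms compared, default C-alpha.
#' @return list with `rmsd` (symmetric matrix, nm), `origin` (integer
#'   ensemble index per pooled frame).
#' @export
pairwise_rmsd <- function(ensembles, selection = "calpha") {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  .assert(length(ensembles) >= 1, "need at least one ensemble")
  topo <- ensembles[[1]]$topology
  sel <- select_atoms(topo, selection)
  .assert(length(sel) >= 1, "empty selection")
  cols <- .xyz_idx(sel)
  xyz <- do.call(rbind, lapply(ensembles, function(e) e$xyz[, cols, drop = FALSE]))
  origin <- rep(seq_along(ensembles),
                vapply(ensembles, n_frames, integer(1)))
  list(rmsd = .pairwise_rmsd_cpp(xyz), origin = origin)
}
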