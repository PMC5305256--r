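# Toy peptides with planted noncovalent contacts at exact persistence.
# Built from idealized residue geometry (fixed bond lengths, no force
# field): only the geometric predicates of the structure-network stage
# matter.  The contact criterion is toggled per frame by displacing the
# partner group beyond its cutoff, so detected persistence is exact by
# construction, not statistical.

# Minimal idealized backbone, origin at N, roughly along +x (nm).
.BB_TEMPLATE <- rbind(
  N  = c(0.000, 0.000, 0.0),
  CA = c(0.146, 0.000, 0.0),
  C  = c(0.199, 0.139, 0.0),
  O  = c(0.131, 0.242, 0.0)
)

.peptide_residue <- function(res_name, origin, extra = NULL) {
  xyz <- sweep(.BB_TEMPLATE, 2, origin, `+`)
  nm <- rownames(.BB_TEMPLATE)
  el <- c("N", "C", "C", "O")
  if (!is.null(extra)) {
    xyz <- rbind(xyz, extra$xyz)
    nm <- c(nm, extra$name)
    el <- c(el, extra$element)
  }
  list(name = nm, element = el, residue_name = res_name, xyz = xyz)
}

# Place a group of atoms so its mass-weighted centre of mass lands exactly
# at `com`, keeping the group's internal shape.
.place_group <- function(local_xyz, element, com) {
  m <- .element_mass(element)
  cur <- colSums(local_xyz * m) / sum(m)
  sweep(local_xyz, 2, com - cur, `+`)
}

#' Generate a toy peptide ensemble with a planted interaction
#'
#' Builds a three-residue peptide in which residues 1 and 3 (sequence
#' separation 2, so not excluded as neighbours) carry one interaction of
#' the requested class.  The geometric criterion of that class
#' (hydrophobic side-chain centre-of-mass distance < 0.65 nm; hydrogen bond
#' donor-acceptor <= 0.35 nm with donor-H-acceptor angle > 120 degrees;
#' salt-bridge charged-group centre-of-mass distance < 0.45 nm) holds in
#' exactly `round(persistence_target * n_frames)` frames; in the remaining
#' frames the partner group is displaced beyond the cutoff.
#'
#' @param contact_type one of `"hbond"`, `"saltbridge"`, `"hydrophobic"`.
#' @param persistence_target fraction of frames in which the contact holds.
#' @param n_frames number of frames.
#' @param seed seed controlling which frames are contact frames.
#' @return an [ensemble()]; the planted on/off pattern is attached as
#'   attribute `"contact_frames"` (logical per frame).
#' @export
gen_contact_peptide <- function(contact_type, persistence_target,
                                n_frames = 100, seed = 1) {
  contact_type <- match.arg(contact_type,
                            c("hbond", "saltbridge", "hydrophobic"))
  .assert(persistence_target >= 0 && persistence_target <= 1,
          "persistence_target must be in [0, 1]")
  .assert(n_frames >= 1, "n_frames must be >= 1")

  origins <- rbind(c(0, 0, 0), c(0, 1.2, 0), c(1.0, 0, 0))
  on_gap <- switch(contact_type,    # group-group distance when in contact
                   hydrophobic = 0.60, hbond = 0.30, saltbridge = 0.40)
  off_gap <- switch(contact_type,   # safely beyond the class cutoff
                    hydrophobic = 0.80, hbond = 0.55, saltbridge = 0.60)

  build <- function(gap) {
    p1 <- c(0.25, -0.40, 0)          # partner-group centre on residue 1
    p2 <- p1 + c(gap, 0, 0)          # residue 3's group centre
    if (contact_type == "hydrophobic") {
      side <- rbind(c(0.05, 0, 0), c(-0.05, 0, 0), c(0, 0.05, 0), c(0, -0.05, 0))
      e1 <- list(name = c("CB", "CG", "CD1", "CD2"), element = rep("C", 4),
                 xyz = .place_group(side, rep("C", 4), p1))
      e2 <- list(name = c("CB", "CG", "CD1", "CD2"), element = rep("C", 4),
                 xyz = .place_group(side, rep("C", 4), p2))
      r1 <- .peptide_residue("LEU", origins[1, ], e1)
      r3 <- .peptide_residue("LEU", origins[3, ], e2)
    } else if (contact_type == "saltbridge") {
      e1 <- list(name = "NZ", element = "N",
                 xyz = matrix(p1, nrow = 1))
      carbox <- rbind(c(-0.065, 0, 0), c(0.06, 0.06, 0), c(0.06, -0.06, 0))
      e2 <- list(name = c("CD", "OE1", "OE2"), element = c("C", "O", "O"),
                 xyz = .place_group(carbox, c("C", "O", "O"), p2))
      r1 <- .peptide_residue("LYS", origins[1, ], e1)
      r3 <- .peptide_residue("GLU", origins[3, ], e2)
    } else { # hbond: SER hydroxyl donor -> GLU carboxylate oxygen acceptor
      u <- c(1, 0, 0)
      e1 <- list(name = c("OG", "HG"), element = c("O", "H"),
                 xyz = rbind(p1, p1 + 0.096 * u))
      e2 <- list(name = "OE1", element = "O",
                 xyz = matrix(p1 + gap * u, nrow = 1))
      r1 <- .peptide_residue("SER", origins[1, ], e1)
      r3 <- .peptide_residue("GLU", origins[3, ], e2)
    }
    r2 <- .peptide_residue("GLY", origins[2, ])
    res <- list(r1, r2, r3)
    atoms <- data.frame(
      name = unlist(lapply(res, `[[`, "name")),
      element = unlist(lapply(res, `[[`, "element")),
      residue_ordinal = rep(1:3, vapply(res, function(r) length(r$name), 1L)),
      residue_name = rep(vapply(res, `[[`, "", "residue_name"),
                         vapply(res, function(r) length(r$name), 1L)),
      chain_id = "A", stringsAsFactors = FALSE
    )
    structure_model(atoms, do.call(rbind, lapply(res, `[[`, "xyz")))
  }

  on_model <- build(on_gap)
  off_model <- build(off_gap)
  k <- round(persistence_target * n_frames)
  on_frames <- rep(FALSE, n_frames)
  if (k > 0) {
    on_frames[.with_seed(seed, sample.int(n_frames, k))] <- TRUE
  }
  xyz_on <- as.numeric(t(on_model$coords))
  xyz_off <- as.numeric(t(off_model$coords))
  xyz <- do.call(rbind, lapply(on_frames, function(on) if (on) xyz_on else xyz_off))
  ens <- ensemble(on_model, xyz, frame_interval = 1,
                  replicate_id = "toy", system_id = paste0("toy_", contact_type))
  attr(ens, "contact_frames") <- on_frames
  ens
}
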