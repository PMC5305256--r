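# Independent oracles and fixture builders used across the test files.

# Horn's quaternion method for the optimal rigid-body superposition RMSD.
# Deliberately a different formulation from the package's SVD-based
# Kabsch kernels so the two can cross-check each other.
horn_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  S <- t(A) %*% B
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Fixed-column PDB ATOM/HETATM line (coordinates in Angstrom).
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", icode = "", element = substr(name, 1, 1)) {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, resname, chain, resno, icode,
          x, y, z, 1, 0, element)
}

# Text of a 3-residue (ALA-GLY-ALA) backbone+CB toy structure, 14 atoms.
toy_pdb_lines <- function() {
  res <- list(list("ALA", c("N", "CA", "C", "O", "CB")),
              list("GLY", c("N", "CA", "C", "O")),
              list("ALA", c("N", "CA", "C", "O", "CB")))
  lines <- character(0)
  serial <- 0
  for (i in seq_along(res)) {
    for (j in seq_along(res[[i]][[2]])) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, res[[i]][[2]][j], res[[i]][[1]],
                                 "A", i, 4 * i + 0.3 * j, 1.5 * j, 0.2 * i))
    }
  }
  c(lines, "TER", "END")
}

# Two-residue structure_model with atoms placed at exact coordinates (nm);
# used for the worked distance/angle criterion examples.
two_residue_model <- function(res1, atoms1, xyz1, res2, atoms2, xyz2,
                              spacer = TRUE) {
  bb <- function(origin) {
    list(names = c("N", "CA", "C", "O"), el = c("N", "C", "C", "O"),
         xyz = sweep(rbind(c(0, 0, 0), c(0.146, 0, 0), c(0.199, 0.139, 0),
                           c(0.131, 0.242, 0)), 2, origin, `+`))
  }
  b1 <- bb(c(0, 3, 0)); b2 <- bb(c(1, 3, 0)); bs <- bb(c(0.5, 6, 0))
  els <- function(nms) vapply(nms, function(n) substr(gsub("^[0-9]+", "", n), 1, 1), "")
  name <- c(b1$names, atoms1, bs$names, b2$names, atoms2)
  element <- c(b1$el, els(atoms1), bs$el, b2$el, els(atoms2))
  ords <- c(rep(1, 4 + length(atoms1)), rep(2, 4),
            rep(3, 4 + length(atoms2)))
  resn <- c(rep(res1, 4 + length(atoms1)), rep("GLY", 4),
            rep(res2, 4 + length(atoms2)))
  coords <- rbind(b1$xyz, xyz1, bs$xyz, b2$xyz, xyz2)
  structure_model(data.frame(name = name, element = element,
                             residue_ordinal = ords, residue_name = resn,
                             chain_id = "A", stringsAsFactors = FALSE),
                  coords)
}

one_frame_ensemble <- function(model) {
  ensemble(model, matrix(as.numeric(t(model$coords)), nrow = 1))
}

# Brute-force connected components by transitive reachability, independent
# of igraph.
reach_components <- function(nodes, edges) {
  comp <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$residue_a[k]; b <- edges$residue_b[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp %in% c(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  touched <- unique(c(edges$residue_a, edges$residue_b))
  split(names(comp[touched]), comp[touched])
}

make_psn_graph <- function(nodes, edges_df, edge_class = "hydrophobic",
                           threshold = 0.2) {
  edges_df$edge_class <- rep(edge_class, nrow(edges_df))
  if (is.null(edges_df$persistence)) edges_df$persistence <- rep(1, nrow(edges_df))
  edges_df$subtype <- rep(NA_character_, nrow(edges_df))
  structure(list(nodes = nodes, edges = edges_df,
                 persistence_threshold = threshold,
                 edge_class = edge_class, system_id = "toy"),
            class = "psn_graph")
}
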