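# Persistence-weighted protein structure networks: residues are nodes,
# noncovalent interactions are edges, and the edge weight is the fraction
# of ensemble frames in which the interaction's geometric criterion holds.
# Interaction classes are analysed separately (hydrophobic, hydrogen bond,
# salt bridge), each with its own distance/angle criterion.

# Side chains whose heavy-atom centre of mass enters hydrophobic contacts.
.HYDROPHOBIC_SET <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

# Charged side-chain groups for salt bridges.  Histidine is excluded by
# default (protonation state unknown); termini are not treated specially.
.CHARGED_GROUPS <- list(
  ASP = list(atoms = c("CG", "OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("CD", "OE1", "OE2"), sign = -1),
  LYS = list(atoms = "NZ", sign = +1),
  ARG = list(atoms = c("CZ", "NH1", "NH2", "NE"), sign = +1)
)

# Hydrogen-bond donor heavy atoms (with the hydrogen names expected on
# them) and acceptor heavy atoms, by residue.  "*" applies to all standard
# residues (backbone).
.HB_DONORS <- list(
  "*"   = list(N = c("H", "HN")),
  ARG  = list(NE = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
  ASN  = list(ND2 = c("HD21", "HD22")),
  GLN  = list(NE2 = c("HE21", "HE22")),
  HIS  = list(ND1 = "HD1", NE2 = "HE2"),
  LYS  = list(NZ = c("HZ1", "HZ2", "HZ3")),
  SER  = list(OG = "HG"),
  THR  = list(OG1 = "HG1"),
  TRP  = list(NE1 = "HE1"),
  TYR  = list(OH = "HH")
)
.HB_ACCEPTORS <- list(
  "*"  = "O",
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD", SER = "OG", THR = "OG1", TYR = "OH"
)

.DEFAULT_CUTOFFS <- list(hydrophobic = 0.65, saltbridge = 0.45,
                         hbond_dist = 0.35, hbond_angle = 120,
                         seq_exclusion = 2)

#' Detect noncovalent interactions in a single frame
#'
#' Applies the geometric criterion of one interaction class to one
#' conformation:
#' \describe{
#'   \item{hydrophobic}{side-chain heavy-atom centre-of-mass distance
#'     below 0.65 nm between residues of the hydrophobic set;}
#'   \item{hbond}{donor-acceptor distance at most 0.35 nm and
#'     donor-hydrogen-acceptor angle greater than 120 degrees;}
#'   \item{saltbridge}{centre-of-mass distance between oppositely charged
#'     side-chain groups below 0.45 nm.}
#' }
#' Residue pairs adjacent in sequence (`|i - j| < 2`) are excluded.
#'
#' @param frame `n_atoms x 3` coordinate matrix, nm (see
#'   [frame_coords()]).
#' @param topology the matching `structure_model`.
#' @param edge_class `"hydrophobic"`, `"hbond"` or `"saltbridge"`.
#' @param cutoffs named list overriding the defaults
#'   (`hydrophobic`, `saltbridge`, `hbond_dist` nm; `hbond_angle` degrees;
#'   `seq_exclusion` residues).
#' @param infer_hydrogens place missing donor hydrogens geometrically
#'   (flagged in the result); without this, hbond detection on a
#'   hydrogen-free topology is an error.
#' @param hydrophobic_set residue names eligible for hydrophobic edges.
#' @return data.frame of interacting residue ordinal pairs (`a` < `b`)
#'   with a `subtype` column for hydrogen bonds
#'   (mainchain-mainchain/mainchain-sidechain/sidechain-sidechain).
#' @export
detect_frame_interactions <- function(frame, topology, edge_class,
                                      cutoffs = list(),
                                      infer_hydrogens = FALSE,
                                      hydrophobic_set = .HYDROPHOBIC_SET) {
  edge_class <- match.arg(edge_class, c("hydrophobic", "hbond", "saltbridge"))
  co <- utils::modifyList(.DEFAULT_CUTOFFS, cutoffs)
  .assert(nrow(frame) == n_atoms(topology), "frame does not match topology")
  atoms <- topology$atoms
  switch(edge_class,
         hydrophobic = .detect_com_pairs(frame, atoms,
                                         subset = atoms$residue_name %in% hydrophobic_set &
                                           !atoms$is_backbone & !atoms$is_hydrogen,
                                         cutoff = co$hydrophobic,
                                         seq_excl = co$seq_exclusion,
                                         signed = FALSE),
         saltbridge = .detect_saltbridges(frame, atoms, co),
         hbond = .detect_hbonds(frame, atoms, co, infer_hydrogens))
}

.residue_coms <- function(frame, atoms, keep) {
  # mass-weighted centre of mass of the kept atoms, per residue
  idx <- which(keep)
  if (length(idx) == 0) return(NULL)
  m <- .element_mass(atoms$element[idx])
  ords <- atoms$residue_ordinal[idx]
  xs <- rowsum(frame[idx, , drop = FALSE] * m, ords)
  ms <- rowsum(m, ords)
  list(com = xs / as.numeric(ms), ordinal = as.integer(rownames(xs)))
}

.pairs_within <- function(com, ordinal, cutoff, seq_excl) {
  n <- length(ordinal)
  if (n < 2) return(data.frame(a = integer(0), b = integer(0)))
  D <- as.matrix(dist(com))
  hit <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  a <- ordinal[hit[, 1]]
  b <- ordinal[hit[, 2]]
  keep <- abs(a - b) >= seq_excl
  data.frame(a = pmin(a, b)[keep], b = pmax(a, b)[keep])
}

.detect_com_pairs <- function(frame, atoms, subset, cutoff, seq_excl, signed) {
  # whole side-chain centre of mass per eligible residue
  g <- .residue_coms(frame, atoms, subset)
  if (is.null(g)) return(data.frame(a = integer(0), b = integer(0)))
  .pairs_within(g$com, g$ordinal, cutoff, seq_excl)
}

.detect_saltbridges <- function(frame, atoms, co) {
  out <- data.frame(a = integer(0), b = integer(0))
  groups <- list()
  for (ord in unique(atoms$residue_ordinal)) {
    rn <- atoms$residue_name[atoms$residue_ordinal == ord][1]
    spec <- .CHARGED_GROUPS[[rn]]
    if (is.null(spec)) next
    keep <- atoms$residue_ordinal == ord & atoms$name %in% spec$atoms
    if (!any(keep)) next
    m <- .element_mass(atoms$element[keep])
    com <- colSums(frame[keep, , drop = FALSE] * m) / sum(m)
    groups[[length(groups) + 1]] <- list(ordinal = ord, sign = spec$sign,
                                         com = com)
  }
  if (length(groups) < 2) return(out)
  for (i in seq_len(length(groups) - 1)) {
    for (j in (i + 1):length(groups)) {
      gi <- groups[[i]]; gj <- groups[[j]]
      if (gi$sign * gj$sign >= 0) next   # only opposite charges
      if (abs(gi$ordinal - gj$ordinal) < co$seq_exclusion) next
      if (sqrt(sum((gi$com - gj$com)^2)) < co$saltbridge) {
        out <- rbind(out, data.frame(a = min(gi$ordinal, gj$ordinal),
                                     b = max(gi$ordinal, gj$ordinal)))
      }
    }
  }
  out
}

.hb_sites <- function(atoms) {
  # enumerate donor (heavy atom + expected hydrogens) and acceptor sites
  don <- list(); acc <- list()
  for (ord in unique(atoms$residue_ordinal)) {
    sel <- atoms$residue_ordinal == ord
    rn <- atoms$residue_name[sel][1]
    if (!rn %in% .STD_AA) next
    dn <- c(.HB_DONORS[["*"]], .HB_DONORS[[rn]])
    for (heavy in names(dn)) {
      i <- which(sel & atoms$name == heavy)
      if (length(i) != 1) next
      hyd <- which(sel & atoms$name %in% dn[[heavy]])
      don[[length(don) + 1]] <- list(ordinal = ord, heavy = i, hydrogens = hyd,
                                     mainchain = heavy == "N")
    }
    an <- unique(c(.HB_ACCEPTORS[["*"]], .HB_ACCEPTORS[[rn]]))
    for (nm in an) {
      i <- which(sel & atoms$name == nm)
      if (length(i) == 1) {
        acc[[length(acc) + 1]] <- list(ordinal = ord, atom = i,
                                       mainchain = nm == "O")
      }
    }
  }
  list(donors = don, acceptors = acc)
}

.detect_hbonds <- function(frame, atoms, co, infer_hydrogens) {
  sites <- .hb_sites(atoms)
  has_h <- any(vapply(sites$donors, function(d) length(d$hydrogens) > 0, TRUE))
  if (!has_h && !infer_hydrogens && length(sites$donors) > 0) {
    .stopf(paste("hydrogen-bond detection needs hydrogens: none found in the",
                 "topology; re-run with infer_hydrogens = TRUE to place",
                 "donor hydrogens geometrically"))
  }
  out <- data.frame(a = integer(0), b = integer(0), subtype = character(0))
  for (d in sites$donors) {
    dpos <- frame[d$heavy, ]
    for (a in sites$acceptors) {
      if (a$atom == d$heavy) next
      if (abs(a$ordinal - d$ordinal) < co$seq_exclusion) next
      apos <- frame[a$atom, ]
      dist <- sqrt(sum((dpos - apos)^2))
      if (dist > co$hbond_dist) next
      if (length(d$hydrogens) > 0) {
        hpos <- frame[d$hydrogens, , drop = FALSE]
      } else if (infer_hydrogens) {
        # place the hydrogen 0.1 nm from the donor toward the acceptor;
        # a coarse stand-in for rotatable donors, flagged in the result
        u <- (apos - dpos) / dist
        hpos <- matrix(dpos + 0.1 * u, nrow = 1)
      } else {
        next
      }
      ang <- apply(hpos, 1, function(h) {
        v1 <- dpos - h; v2 <- apos - h
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(min(max(cosang, -1), 1)) * 180 / pi
      })
      if (any(ang > co$hbond_angle)) {
        subtype <- if (d$mainchain && a$mainchain) "mainchain-mainchain"
        else if (!d$mainchain && !a$mainchain) "sidechain-sidechain"
        else "mainchain-sidechain"
        out <- rbind(out, data.frame(a = min(d$ordinal, a$ordinal),
                                     b = max(d$ordinal, a$ordinal),
                                     subtype = subtype))
      }
    }
  }
  if (!has_h && infer_hydrogens) attr(out, "hydrogens_inferred") <- TRUE
  unique(out)
}

#' Build a persistence-weighted protein structure network
#'
#' Runs [detect_frame_interactions()] on every frame; the persistence of a
#' residue pair is the fraction of frames in which it interacts.  Edges at
#' or above `persistence_threshold` are retained, weighted by persistence.
#'
#' @param ens an [ensemble()].
#' @param edge_class interaction class (see
#'   [detect_frame_interactions()]).
#' @param persistence_threshold minimum retained persistence, in `[0, 1]`
#'   (default 0.2).
#' @param ... passed to [detect_frame_interactions()].
#' @return a `psn_graph`: list with `nodes` (residue labels), `edges`
#'   (data.frame `residue_a`, `residue_b`, `edge_class`, `persistence`,
#'   `subtype`), `persistence_threshold`, `system_id`.
#' @export
build_psn <- function(ens, edge_class, persistence_threshold = 0.2, ...) {
  .assert(persistence_threshold >= 0 && persistence_threshold <= 1,
          "persistence_threshold must lie in [0, 1]")
  nf <- n_frames(ens)
  counts <- list()
  subtypes <- list()
  for (k in seq_len(nf)) {
    hits <- detect_frame_interactions(frame_coords(ens, k), ens$topology,
                                      edge_class, ...)
    if (nrow(hits) == 0) next
    key <- paste(hits$a, hits$b, sep = "-")
    for (i in seq_along(key)) {
      counts[[key[i]]] <- (counts[[key[i]]] %||% 0) + 1
      if (!is.null(hits$subtype)) subtypes[[key[i]]] <- hits$subtype[i]
    }
  }
  labels <- residue_labels(ens$topology)
  ord2lab <- setNames(labels, ens$topology$residues$ordinal)
  if (length(counts) > 0) {
    ab <- do.call(rbind, strsplit(names(counts), "-", fixed = TRUE))
    edges <- data.frame(
      residue_a = unname(ord2lab[ab[, 1]]),
      residue_b = unname(ord2lab[ab[, 2]]),
      edge_class = edge_class,
      persistence = unlist(counts) / nf,
      subtype = if (edge_class == "hbond")
        vapply(names(counts), function(k) subtypes[[k]] %||% NA_character_, "")
      else NA_character_,
      row.names = NULL, stringsAsFactors = FALSE
    )
    edges <- edges[edges$persistence >= persistence_threshold, , drop = FALSE]
  } else {
    edges <- data.frame(residue_a = character(0), residue_b = character(0),
                        edge_class = character(0), persistence = numeric(0),
                        subtype = character(0))
  }
  structure(list(nodes = labels, edges = edges,
                 persistence_threshold = persistence_threshold,
                 edge_class = edge_class, system_id = ens$system_id),
            class = "psn_graph")
}

#' @export
print.psn_graph <- function(x, ...) {
  cat(sprintf("psn_graph (%s) '%s': %d nodes, %d edges at persistence >= %.2f\n",
              x$edge_class, x$system_id, length(x$nodes), nrow(x$edges),
              x$persistence_threshold))
  invisible(x)
}

.psn_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("residue_a", "residue_b", "persistence")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
}

#' Hub residues of a structure network
#'
#' Residues connected by more than four edges (degree >= `min_degree`,
#' default 5), the topological feature associated with structural
#' stability and signal propagation.
#'
#' @param graph a `psn_graph`.
#' @param min_degree minimum degree to report.
#' @return data.frame (`residue`, `degree`), sorted by degree descending
#'   then residue label.
#' @export
find_hubs <- function(graph, min_degree = 5) {
  g <- .psn_igraph(graph)
  deg <- igraph::degree(g)
  hubs <- deg[deg >= min_degree]
  out <- data.frame(residue = names(hubs), degree = as.integer(hubs),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$residue), , drop = FALSE]
}

#' Connected interaction clusters of a structure network
#'
#' Connected components of the persistence-filtered graph (isolated nodes
#' are not reported), ordered by size descending.
#'
#' @param graph a `psn_graph`.
#' @return list of character vectors of residue labels, each sorted.
#' @export
find_clusters <- function(graph) {
  if (nrow(graph$edges) == 0) return(list())
  g <- .psn_igraph(graph)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) {
    sort(names(comp$membership)[comp$membership == k])
  })
  out[order(-vapply(out, length, 1L))]
}

#' Differential edges between two structure networks
#'
#' Maps residues of system A onto system B and partitions the union of
#' mapped edges into `only_in_a`, `only_in_b` and `shared` (with both
#' persistences).  Edges touching unmapped residues are reported in an
#' `unmapped` bucket, never silently dropped.  Hydrogen-bond networks can
#' exclude the mainchain-mainchain subtype before comparison.
#'
#' @param graph_a,graph_b `psn_graph`s of the same edge class.
#' @param residue_map data.frame (`label_a`, `label_b`) aligning residue
#'   labels; default identity on shared labels.
#' @param exclude_mainchain drop mainchain-mainchain hydrogen bonds before
#'   counting.
#' @return a `network_diff`: list with `only_in_a`, `only_in_b`, `shared`,
#'   `unmapped`, and a `counts` summary.
#' @export
diff_networks <- function(graph_a, graph_b, residue_map = NULL,
                          exclude_mainchain = FALSE) {
  .assert(graph_a$edge_class == graph_b$edge_class,
          "cannot diff networks of different edge class (%s vs %s)",
          graph_a$edge_class, graph_b$edge_class)
  ea <- graph_a$edges
  eb <- graph_b$edges
  if (exclude_mainchain && graph_a$edge_class == "hbond") {
    ea <- ea[is.na(ea$subtype) | ea$subtype != "mainchain-mainchain", ]
    eb <- eb[is.na(eb$subtype) | eb$subtype != "mainchain-mainchain", ]
  }
  if (is.null(residue_map)) {
    shared_lab <- intersect(graph_a$nodes, graph_b$nodes)
    residue_map <- data.frame(label_a = shared_lab, label_b = shared_lab,
                              stringsAsFactors = FALSE)
  }
  a2b <- setNames(residue_map$label_b, residue_map$label_a)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "~")

  amap <- ea$residue_a %in% names(a2b) & ea$residue_b %in% names(a2b)
  bmap <- eb$residue_a %in% residue_map$label_b &
    eb$residue_b %in% residue_map$label_b
  unmapped <- rbind(
    if (any(!amap)) cbind(ea[!amap, , drop = FALSE], system = "a"),
    if (any(!bmap)) cbind(eb[!bmap, , drop = FALSE], system = "b")
  )
  ea_m <- ea[amap, , drop = FALSE]
  eb_m <- eb[bmap, , drop = FALSE]
  ka <- key(unname(a2b[ea_m$residue_a]), unname(a2b[ea_m$residue_b]))
  kb <- key(eb_m$residue_a, eb_m$residue_b)
  shared_keys <- intersect(ka, kb)
  shared <- if (length(shared_keys)) {
    data.frame(edge = shared_keys,
               persistence_a = ea_m$persistence[match(shared_keys, ka)],
               persistence_b = eb_m$persistence[match(shared_keys, kb)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(edge = character(0), persistence_a = numeric(0),
               persistence_b = numeric(0))
  }
  structure(list(
    only_in_a = ea_m[!(ka %in% kb), , drop = FALSE],
    only_in_b = eb_m[!(kb %in% ka), , drop = FALSE],
    shared = shared,
    unmapped = unmapped,
    counts = c(n_a = nrow(ea_m), n_b = nrow(eb_m),
               only_a = sum(!(ka %in% kb)), only_b = sum(!(kb %in% ka)),
               shared = length(shared_keys),
               unmapped = if (is.null(unmapped)) 0L else nrow(unmapped))
  ), class = "network_diff")
}

#' Write a structure network as GraphML and TSV edge list
#'
#' @param graph a `psn_graph`.
#' @param path output GraphML path; the TSV edge list replaces the
#'   extension.
#' @export
write_psn_graphml <- function(graph, path) {
  g <- .psn_igraph(graph)
  igraph::E(g)$edge_class <- graph$edges$edge_class
  igraph::E(g)$subtype <- ifelse(is.na(graph$edges$subtype), "",
                                 graph$edges$subtype)
  igraph::write_graph(g, path, format = "graphml")
  tsv <- sub("\\.[A-Za-z]+$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  write.table(graph$edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
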