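test_that("hydrophobic contact criterion is strict at 0.65 nm on side-chain centres", {
  hit <- detect_frame_interactions(leu_pair(0.60)$coords, leu_pair(0.60),
                                   "hydrophobic")
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$a, hit$b), c(1, 3))
  miss <- detect_frame_interactions(leu_pair(0.70)$coords, leu_pair(0.70),
                                    "hydrophobic")
  expect_equal(nrow(miss), 0)
})

test_that("hydrogen-bond criterion applies 0.35 nm and the 120-degree angle jointly", {
  ok <- hbond_model(0.34, 150)
  hit <- detect_frame_interactions(ok$coords, ok, "hbond")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$subtype, "sidechain-sidechain")

  bad_angle <- hbond_model(0.34, 119)
  expect_equal(nrow(detect_frame_interactions(bad_angle$coords, bad_angle,
                                              "hbond")), 0)
  too_far <- hbond_model(0.36, 150)
  expect_equal(nrow(detect_frame_interactions(too_far$coords, too_far,
                                              "hbond")), 0)
})

test_that("salt-bridge criterion is strict at 0.45 nm between charged-group centres", {
  hit <- detect_frame_interactions(salt_model(0.40)$coords, salt_model(0.40),
                                   "saltbridge")
  expect_equal(nrow(hit), 1)
  miss <- detect_frame_interactions(salt_model(0.50)$coords, salt_model(0.50),
                                    "saltbridge")
  expect_equal(nrow(miss), 0)
})

test_that("hbond detection without hydrogens demands the inference flag", {
  m <- salt_model(0.40)   # no hydrogens anywhere in this topology
  expect_error(detect_frame_interactions(m$coords, m, "hbond"),
               "infer_hydrogens")
  expect_silent(detect_frame_interactions(m$coords, m, "hbond",
                                          infer_hydrogens = TRUE))
})

test_that("persistence equals an independent per-frame recount and respects thresholds", {
  ens <- gen_contact_peptide("saltbridge", 0.35, n_frames = 100, seed = 2)
  g <- build_psn(ens, "saltbridge", persistence_threshold = 0.2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$persistence, 0.35)

  # brute-force recount straight from the geometry
  recount <- mean(vapply(seq_len(n_frames(ens)), function(k) {
    nrow(detect_frame_interactions(frame_coords(ens, k), ens$topology,
                                   "saltbridge")) > 0
  }, TRUE))
  expect_equal(g$edges$persistence, recount)

  g2 <- build_psn(ens, "saltbridge", persistence_threshold = 0.5)
  expect_equal(nrow(g2$edges), 0)
  expect_error(build_psn(ens, "saltbridge", persistence_threshold = 1.5),
               "persistence_threshold")

  # raising the threshold never adds edges
  th <- c(0, 0.1, 0.34, 0.36, 0.9)
  counts <- vapply(th, function(t) nrow(build_psn(ens, "saltbridge", t)$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("structure networks are invariant under global rigid-body motion", {
  ens <- gen_contact_peptide("hydrophobic", 0.6, n_frames = 20, seed = 4)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  rot <- ens
  rot$xyz <- t(apply(ens$xyz, 1, function(row) {
    as.numeric(t(matrix(row, ncol = 3, byrow = TRUE) %*% t(R) + 2))
  }))
  ga <- build_psn(ens, "hydrophobic", 0.2)
  gb <- build_psn(rot, "hydrophobic", 0.2)
  expect_equal(ga$edges$persistence, gb$edges$persistence)
  expect_equal(ga$edges$residue_a, gb$edges$residue_a)
})

test_that("hub detection includes degree-5 and excludes degree-4 nodes", {
  star5 <- make_psn_graph(as.character(1:7),
                          data.frame(residue_a = "1",
                                     residue_b = as.character(2:6)))
  h <- find_hubs(star5)
  expect_equal(h$residue, "1")
  expect_equal(h$degree, 5L)

  star4 <- make_psn_graph(as.character(1:5),
                          data.frame(residue_a = "1",
                                     residue_b = as.character(2:5)))
  expect_equal(nrow(find_hubs(star4)), 0)
  expect_equal(nrow(find_hubs(make_psn_graph("1", data.frame(
    residue_a = character(0), residue_b = character(0))))), 0)

  # min_degree = 1 returns every non-isolated node
  h1 <- find_hubs(star4, min_degree = 1)
  expect_setequal(h1$residue, as.character(1:5))
})

test_that("interaction clusters are the connected components, checked by brute force", {
  tri2 <- make_psn_graph(as.character(1:6),
                         data.frame(residue_a = c("1", "2", "1", "4", "5", "4"),
                                    residue_b = c("2", "3", "3", "5", "6", "6")))
  cl <- find_clusters(tri2)
  expect_equal(length(cl), 2)
  expect_equal(vapply(cl, length, 0L), c(3L, 3L))

  expect_equal(find_clusters(make_psn_graph("1", data.frame(
    residue_a = character(0), residue_b = character(0)))), list())

  edges7 <- data.frame(residue_a = c("a", "b", "c", "e"),
                       residue_b = c("b", "c", "d", "f"))
  g7 <- make_psn_graph(c("a", "b", "c", "d", "e", "f", "g"), edges7)
  cl7 <- find_clusters(g7)
  oracle <- reach_components(g7$nodes, edges7)
  oracle <- lapply(oracle, sort)
  oracle <- oracle[order(-vapply(oracle, length, 0L))]
  expect_equal(vapply(cl7, length, 0L), c(4L, 2L))
  expect_equal(unname(cl7), unname(oracle))
})

test_that("network diffs partition edges and never drop unmapped residues", {
  ga <- make_psn_graph(as.character(1:4),
                       data.frame(residue_a = c("1", "2"),
                                  residue_b = c("2", "3"),
                                  persistence = c(0.5, 0.6)))
  gb <- make_psn_graph(as.character(1:4),
                       data.frame(residue_a = c("2", "3"),
                                  residue_b = c("3", "4"),
                                  persistence = c(0.7, 0.8)))
  d0 <- diff_networks(ga, ga)
  expect_equal(nrow(d0$only_in_a), 0)
  expect_equal(nrow(d0$only_in_b), 0)
  expect_equal(nrow(d0$shared), 2)

  d <- diff_networks(ga, gb)
  expect_equal(paste(d$only_in_a$residue_a, d$only_in_a$residue_b), "1 2")
  expect_equal(paste(d$only_in_b$residue_a, d$only_in_b$residue_b), "3 4")
  expect_equal(d$shared$edge, "2~3")
  expect_equal(d$counts[["shared"]], 1)

  # residue 4 unmapped: its edge lands in the unmapped bucket
  map <- data.frame(label_a = as.character(1:3), label_b = as.character(1:3))
  d2 <- diff_networks(ga, gb, residue_map = map)
  expect_equal(nrow(d2$unmapped), 1)
  expect_equal(d2$unmapped$residue_b, "4")

  gc <- make_psn_graph(as.character(1:4),
                       data.frame(residue_a = "1", residue_b = "3"),
                       edge_class = "hbond")
  expect_error(diff_networks(ga, gc), "edge class")
})
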