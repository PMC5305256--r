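mk_aln <- function(seqs, labels, target_a = names(seqs)[1],
                   target_b = NULL) {
  if (is.null(target_b)) target_b <- names(seqs)[which(labels == "mesophilic")[1]]
  labeled_alignment(seqs, labels, target_a, target_b)
}

test_that("composition deltas count residues exactly and conserve totals", {
  aln <- mk_aln(c(a = "AAKK", b = "AAKA"),
                c("psychrophilic", "mesophilic"))
  cd <- composition_delta(aln)
  expect_equal(cd$counts$delta[cd$counts$residue == "K"], 1)
  expect_equal(cd$counts$delta[cd$counts$residue == "A"], -1)
  expect_true(all(cd$counts$delta[!cd$counts$residue %in% c("A", "K")] == 0))
  expect_equal(sum(cd$counts$count_a), 4)
  expect_equal(sum(cd$counts$count_b), 4)

  same <- mk_aln(c(a = "MKV-A", b = "MKV-A"),
                 c("psychrophilic", "mesophilic"))
  cd2 <- composition_delta(same)
  expect_true(all(cd2$counts$delta == 0))
  expect_equal(cd2$length_a, 4)  # the gap is not a residue
})

test_that("substitution sites enumerate differing columns and indels", {
  same <- mk_aln(c(a = "MKVA", b = "MKVA"),
                 c("psychrophilic", "mesophilic"))
  expect_equal(nrow(substitution_sites(same)), 0)

  aln <- gen_labeled_alignment(4, 4, 50,
                               planted_candidate_columns = c(2, 11, 30),
                               planted_drift_columns = c(5, 17, 28, 44),
                               seed = 9)
  recs <- substitution_sites(aln)
  expect_equal(sort(recs$column), sort(c(2, 11, 30, 5, 17, 28, 44)))
  expect_true(all(recs$type == "substitution"))

  gap <- mk_aln(c(a = "MKVA", b = "MK-A"),
                c("psychrophilic", "mesophilic"))
  r <- substitution_sites(gap)
  expect_equal(nrow(r), 1)
  expect_equal(r$type, "insertion_a")
})

test_that("planted candidates are recovered with precision and recall 1", {
  cand <- c(4, 19, 37)
  drift <- c(8, 23, 41, 55)
  aln <- gen_labeled_alignment(6, 6, 60,
                               planted_candidate_columns = cand,
                               planted_drift_columns = drift, seed = 12)
  recs <- classify_substitutions(substitution_sites(aln), aln)
  called <- recs$column[recs$verdict == "candidate"]
  expect_setequal(called, cand)                       # recall and precision 1
  expect_setequal(recs$column[recs$verdict == "drift"], drift)
})

test_that("shared modal residues and target-only groups are not candidates", {
  # both groups share the modal residue at column 2: drift
  seqs <- c(p1 = "AKA", p2 = "AKA", m1 = "AKC", m2 = "AKA")
  aln <- mk_aln(seqs, c("psychrophilic", "psychrotolerant",
                        "mesophilic", "mesophilic"),
                target_a = "p1", target_b = "m1")
  recs <- classify_substitutions(substitution_sites(aln), aln)
  expect_equal(recs$column, 3)
  expect_equal(recs$verdict, "drift")

  # groups consisting only of the targets: indeterminate
  two <- mk_aln(c(p = "AVA", m = "ATA"), c("psychrophilic", "mesophilic"))
  r2 <- classify_substitutions(substitution_sites(two), two)
  expect_true(all(r2$verdict == "indeterminate"))
})

test_that("verdicts are stable under reordering and monotone in the cutoff", {
  aln <- gen_labeled_alignment(5, 6, 40,
                               planted_candidate_columns = c(6, 21),
                               planted_drift_columns = c(13, 33), seed = 3)
  recs <- classify_substitutions(substitution_sites(aln), aln)

  perm <- rev(seq_along(aln$sequences))
  aln2 <- labeled_alignment(aln$sequences[perm], aln$labels[perm],
                            aln$target_a, aln$target_b)
  recs2 <- classify_substitutions(substitution_sites(aln2), aln2)
  expect_equal(recs2$verdict, recs$verdict)

  # raising the cutoff never converts drift to candidate
  for (cut in c(0.6, 0.8, 0.95, 1)) {
    r <- classify_substitutions(substitution_sites(aln), aln,
                                conservation_cutoff = cut)
    drift_cols <- recs$column[recs$verdict == "drift"]
    expect_false(any(r$verdict[r$column %in% drift_cols] == "candidate"))
  }
})

test_that("grouped mode treats similar residues as one conserved pattern", {
  # cold group split V/I (exact mode: heterogeneous; grouped: conserved)
  seqs <- c(p1 = "VA", p2 = "IA", p3 = "VA",
            m1 = "TA", m2 = "TA", m3 = "TA")
  aln <- mk_aln(seqs, c(rep("psychrophilic", 3), rep("mesophilic", 3)),
                target_a = "p1", target_b = "m1")
  exact <- classify_substitutions(substitution_sites(aln), aln, mode = "exact")
  grouped <- classify_substitutions(substitution_sites(aln), aln,
                                    mode = "grouped")
  expect_equal(exact$verdict, "indeterminate")
  expect_equal(grouped$verdict, "candidate")
})

test_that("pairwise identity follows its worked values and error path", {
  expect_equal(pairwise_identity("MKVA", "MKVA"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_equal(pairwise_identity("AA--", "AAT-"), 100 * 2 / 3)
  expect_equal(pairwise_identity("AA--", "AAT-", denominator = "both"), 100)
  expect_error(pairwise_identity("--", "--"), "no comparable")
})

test_that("alignment files round-trip through the FASTA reader", {
  skip_if_not_installed("Biostrings")
  aln <- gen_labeled_alignment(3, 3, 25, planted_candidate_columns = 7,
                               seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_fasta(aln, fa, tsv)
  back <- read_labeled_alignment(fa, tsv, aln$target_a, aln$target_b)
  expect_equal(back$sequences, aln$sequences)
  expect_equal(back$labels, aln$labels)
})
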