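#' Temperature-labeled multiple sequence alignment
#'
#' Container for an aligned set of homolog sequences, each labeled by the
#' thermal class of its source organism, plus the two target homologs
#' being compared (one cold-adapted, one mesophilic).
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; 20-letter amino-acid alphabet plus `-` for gaps).
#' @param labels character vector (same order/names) with values
#'   `"psychrophilic"`, `"psychrotolerant"` or `"mesophilic"`.
#' @param target_a id of the cold-adapted (psychrophilic) target sequence.
#' @param target_b id of the mesophilic target sequence.
#' @return an object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(sequences, labels, target_a, target_b) {
  .assert(length(sequences) >= 2, "need at least two sequences")
  .assert(!is.null(names(sequences)) && !anyDuplicated(names(sequences)),
          "sequences must be uniquely named")
  lens <- nchar(sequences)
  .assert(length(unique(lens)) == 1,
          "aligned sequences must have equal length")
  .assert(length(labels) == length(sequences), "one label per sequence")
  ok_lab <- c("psychrophilic", "psychrotolerant", "mesophilic")
  .assert(all(labels %in% ok_lab),
          "labels must be one of: %s", paste(ok_lab, collapse = ", "))
  names(labels) <- names(sequences)
  .assert(target_a %in% names(sequences), "target_a '%s' not found", target_a)
  .assert(target_b %in% names(sequences), "target_b '%s' not found", target_b)
  .assert(labels[[target_a]] == "psychrophilic",
          "target_a must be labeled psychrophilic")
  .assert(labels[[target_b]] == "mesophilic",
          "target_b must be labeled mesophilic")
  letters_seen <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(letters_seen, c(.AA1, "-", "X"))
  .assert(length(bad) == 0, "non-standard letters in alignment: %s",
          paste(bad, collapse = ", "))
  structure(list(sequences = sequences, labels = labels,
                 target_a = target_a, target_b = target_b),
            class = "labeled_alignment")
}

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("labeled_alignment: %d sequences x %d columns; targets %s (cold) vs %s (meso)\n",
              length(x$sequences), nchar(x$sequences[[1]]),
              x$target_a, x$target_b))
  cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a labeled alignment from files
#'
#' Reads an alignment in FASTA (via Biostrings) or Clustal (via seqinr)
#' format together with a tab-separated label table (columns `id`,
#' `label`).
#'
#' @param alignment_path path to the alignment file.
#' @param labels_path path to a TSV with columns `id` and `label`.
#' @param target_a,target_b ids of the two compared homologs.
#' @param format `"fasta"` or `"clustal"`; default guesses from the
#'   file contents.
#' @return a [labeled_alignment()].
#' @export
read_labeled_alignment <- function(alignment_path, labels_path,
                                   target_a, target_b, format = NULL) {
  .assert(file.exists(alignment_path), "alignment file not found: %s",
          alignment_path)
  if (is.null(format)) {
    first <- readLines(alignment_path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  format <- match.arg(format, c("fasta", "clustal"))
  if (format == "fasta") {
    .assert(requireNamespace("Biostrings", quietly = TRUE),
            "reading FASTA alignments requires the Biostrings package")
    aa <- Biostrings::readAAStringSet(alignment_path)
    seqs <- setNames(as.character(aa), names(aa))
  } else {
    .assert(requireNamespace("seqinr", quietly = TRUE),
            "reading Clustal alignments requires the seqinr package")
    aln <- seqinr::read.alignment(alignment_path, format = "clustal")
    seqs <- setNames(toupper(unlist(aln$seq)), aln$nam)
  }
  labs <- read.table(labels_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  .assert(all(c("id", "label") %in% names(labs)),
          "labels TSV must have columns 'id' and 'label'")
  .assert(all(names(seqs) %in% labs$id),
          "missing labels for: %s",
          paste(setdiff(names(seqs), labs$id), collapse = ", "))
  labels <- labs$label[match(names(seqs), labs$id)]
  labeled_alignment(seqs, labels, target_a, target_b)
}

#' Write an alignment as FASTA
#' @param alignment a `labeled_alignment`.
#' @param path output FASTA path.
#' @param labels_path optional path for the matching labels TSV.
#' @export
write_alignment_fasta <- function(alignment, path, labels_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(alignment$sequences)) {
    writeLines(c(paste0(">", id), alignment$sequences[[id]]), con)
  }
  if (!is.null(labels_path)) {
    write.table(data.frame(id = names(alignment$sequences),
                           label = unname(alignment$labels)),
                labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Generate a labeled alignment with planted adaptation signal
#'
#' Builds a synthetic alignment of cold-group (psychrophilic +
#' psychrotolerant) and mesophilic sequences in which designated columns
#' carry a planted signal:
#' \describe{
#'   \item{candidate columns}{one residue fixed across the whole cold
#'     group and a different residue fixed across the whole mesophilic
#'     group — the conserved-divergence pattern expected of a true
#'     cold-adaptation substitution;}
#'   \item{drift columns}{the two targets differ but the mesophilic group
#'     is internally heterogeneous, the signature of genetic drift;}
#'   \item{all other columns}{identical across every sequence.}
#' }
#' The first cold and first mesophilic sequences are the designated
#' targets.  The generator is a pure function of its arguments and seed.
#'
#' @param n_psychro number of cold-group sequences (>= 1; alternating
#'   psychrophilic / psychrotolerant labels, the first one psychrophilic).
#' @param n_meso number of mesophilic sequences (>= 2 so drift columns can
#'   be heterogeneous).
#' @param length alignment length in columns.
#' @param planted_candidate_columns,planted_drift_columns disjoint column
#'   index sets (1-based).
#' @param seed RNG seed.
#' @return a [labeled_alignment()]; planted truth is attached as
#'   attributes `"candidate_columns"` and `"drift_columns"`.
#' @export
gen_labeled_alignment <- function(n_psychro = 6, n_meso = 6, length = 60,
                                  planted_candidate_columns = integer(0),
                                  planted_drift_columns = integer(0),
                                  seed = 1) {
  .assert(n_psychro >= 1 && n_meso >= 2,
          "need n_psychro >= 1 and n_meso >= 2")
  cand <- as.integer(planted_candidate_columns)
  drift <- as.integer(planted_drift_columns)
  .assert(length(intersect(cand, drift)) == 0,
          "planted candidate and drift column sets overlap")
  .assert(all(c(cand, drift) >= 1) && all(c(cand, drift) <= length),
          "planted column indices must lie in 1..length")

  n <- n_psychro + n_meso
  .with_seed(seed, {
    base <- sample(.AA1, length, replace = TRUE)
    M <- matrix(rep(base, each = n), nrow = n)
    for (j in cand) {
      pair <- sample(setdiff(.AA1, base[j]), 2)
      M[seq_len(n_psychro), j] <- pair[1]
      M[n_psychro + seq_len(n_meso), j] <- pair[2]
    }
    for (j in drift) {
      trio <- sample(setdiff(.AA1, base[j]), 3)
      M[seq_len(n_psychro), j] <- trio[1]
      # heterogeneous mesophilic group: alternate two residues
      M[n_psychro + seq_len(n_meso), j] <- rep(trio[2:3],
                                               length.out = n_meso)
    }
    ids <- c(paste0("cold_", seq_len(n_psychro)),
             paste0("meso_", seq_len(n_meso)))
    labels <- c("psychrophilic",
                rep(c("psychrotolerant", "psychrophilic"),
                    length.out = max(n_psychro - 1, 0)),
                rep("mesophilic", n_meso))
    seqs <- setNames(apply(M, 1, paste, collapse = ""), ids)
    aln <- labeled_alignment(seqs, labels,
                             target_a = ids[1], target_b = ids[n_psychro + 1])
    attr(aln, "candidate_columns") <- cand
    attr(aln, "drift_columns") <- drift
    aln
  })
}
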