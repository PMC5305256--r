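# Sequence-level comparison of the two target homologs: amino-acid
# composition differences, substitution-site extraction, and
# classification of sites into cold-adaptation candidates vs genetic
# drift using the temperature-labeled homolog groups of the alignment.

# Documented physicochemical class table used for grouped composition
# summaries.  Classes overlap deliberately (e.g. aromatics are also
# counted among hydrophobics where conventional).
.AA_CLASSES <- list(
  charged_positive = c("K", "R", "H"),
  charged_negative = c("D", "E"),
  polar = c("S", "T", "N", "Q", "C", "Y", "W", "H"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "P"),
  aromatic = c("F", "Y", "W"),
  glycine = "G",
  proline = "P"
)

# Residue-similarity groups for the optional grouped classification mode
# (treats e.g. a V/I/L exchange as one conserved hydrophobic pattern).
.SIMILARITY_GROUPS <- list(
  c("V", "I", "L", "M"), c("S", "T"), c("D", "E"), c("K", "R"),
  c("F", "Y", "W"), c("N", "Q")
)

.seq_chars <- function(s) strsplit(s, "")[[1]]

#' Amino-acid composition difference between the two targets
#'
#' Per-residue-type counts over the ungapped target sequences and their
#' signed difference (cold target minus mesophilic target), plus grouped
#' summaries over a documented physicochemical class table.
#'
#' @param alignment a [labeled_alignment()].
#' @return a `composition_delta`: list with `counts` (data.frame
#'   `residue`, `count_a`, `count_b`, `delta`), `classes` (grouped
#'   version) and the target ids.
#' @export
composition_delta <- function(alignment) {
  .assert(inherits(alignment, "labeled_alignment"), "need a labeled_alignment")
  a <- .seq_chars(alignment$sequences[[alignment$target_a]])
  b <- .seq_chars(alignment$sequences[[alignment$target_b]])
  a <- a[a != "-"]
  b <- b[b != "-"]
  bad <- setdiff(unique(c(a, b)), .AA1)
  .assert(length(bad) == 0, "non-standard letters in targets: %s",
          paste(bad, collapse = ", "))
  ca <- table(factor(a, levels = .AA1))
  cb <- table(factor(b, levels = .AA1))
  counts <- data.frame(residue = .AA1,
                       count_a = as.integer(ca), count_b = as.integer(cb),
                       delta = as.integer(ca) - as.integer(cb),
                       stringsAsFactors = FALSE)
  classes <- do.call(rbind, lapply(names(.AA_CLASSES), function(cl) {
    keep <- counts$residue %in% .AA_CLASSES[[cl]]
    data.frame(class = cl,
               count_a = sum(counts$count_a[keep]),
               count_b = sum(counts$count_b[keep]),
               delta = sum(counts$delta[keep]),
               stringsAsFactors = FALSE)
  }))
  structure(list(counts = counts, classes = classes,
                 target_a = alignment$target_a, target_b = alignment$target_b,
                 length_a = length(a), length_b = length(b)),
            class = "composition_delta")
}

#' @export
print.composition_delta <- function(x, ...) {
  cat(sprintf("composition_delta: %s (%d aa) vs %s (%d aa)\n",
              x$target_a, x$length_a, x$target_b, x$length_b))
  nz <- x$counts[x$counts$delta != 0, ]
  if (nrow(nz)) {
    cat("  non-zero deltas:",
        paste(sprintf("%s%+d", nz$residue, nz$delta), collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract substitution and indel sites between the two targets
#'
#' Every alignment column where the targets differ becomes a record:
#' substitutions where both targets have residues, insertion/deletion
#' records where exactly one is gapped.  Verdicts are left unset; see
#' [classify_substitutions()].
#'
#' @param alignment a [labeled_alignment()].
#' @param numbering_map optional character vector of reference labels per
#'   ungapped position of the cold target (e.g. the numbering of a
#'   reference crystal structure); default the ungapped position itself.
#' @return data.frame with `column`, `label_a`, `label_b`,
#'   `reference_position`, `type` (substitution/insertion_a/deletion_a)
#'   and `verdict = NA`.
#' @export
substitution_sites <- function(alignment, numbering_map = NULL) {
  .assert(inherits(alignment, "labeled_alignment"), "need a labeled_alignment")
  a <- .seq_chars(alignment$sequences[[alignment$target_a]])
  b <- .seq_chars(alignment$sequences[[alignment$target_b]])
  pos_a <- cumsum(a != "-")
  if (is.null(numbering_map)) {
    refpos <- as.character(pos_a)
  } else {
    .assert(length(numbering_map) >= max(pos_a),
            "numbering_map shorter than the ungapped target")
    refpos <- numbering_map[pmax(pos_a, 1)]
  }
  differ <- which(a != b)
  if (length(differ) == 0) {
    return(data.frame(column = integer(0), label_a = character(0),
                      label_b = character(0), reference_position = character(0),
                      type = character(0), verdict = character(0)))
  }
  type <- ifelse(a[differ] == "-", "deletion_a",
                 ifelse(b[differ] == "-", "insertion_a", "substitution"))
  data.frame(column = differ,
             label_a = a[differ], label_b = b[differ],
             reference_position = refpos[differ],
             type = type, verdict = NA_character_,
             stringsAsFactors = FALSE)
}

.mode_freq <- function(letters, groups = NULL) {
  # modal residue (or similarity-group) and its frequency among non-gaps
  letters <- letters[letters != "-"]
  if (length(letters) == 0) return(list(mode = NA, freq = 0, n = 0))
  cls <- letters
  if (!is.null(groups)) {
    for (g in groups) cls[cls %in% g] <- g[1]
  }
  tab <- sort(table(cls), decreasing = TRUE)
  list(mode = names(tab)[1], freq = as.numeric(tab[1]) / length(cls),
       n = length(cls))
}

#' Classify substitution sites into adaptation candidates vs drift
#'
#' For each substitution record, compares the cold group (psychrophilic +
#' psychrotolerant sequences pooled, optionally kept separate) against
#' the mesophilic group at that alignment column.  Verdicts:
#' \describe{
#'   \item{candidate}{both groups conserved (modal frequency >=
#'     `conservation_cutoff`) on *different* residues, and each target
#'     matches its own group's modal residue — the pattern expected of a
#'     substitution maintained by thermal adaptation;}
#'   \item{drift}{the groups share the modal residue, or the mesophilic
#'     group is heterogeneous (modal frequency below the cutoff) — the
#'     difference is not systematically associated with temperature;}
#'   \item{indeterminate}{anything else (e.g. a conserved mesophilic group
#'     but a heterogeneous cold group, or no group evidence beyond the
#'     targets themselves).}
#' }
#' In `mode = "grouped"`, residues within a similarity class (V/I/L/M,
#' S/T, D/E, K/R, F/Y/W, N/Q) count as one conserved pattern;
#' `mode = "exact"` (default) requires identical residues.
#'
#' @param records output of [substitution_sites()].
#' @param alignment the [labeled_alignment()] the records came from.
#' @param conservation_cutoff within-group modal frequency required to
#'   call a group conserved (default 0.8).
#' @param mode `"exact"` or `"grouped"` residue equivalence.
#' @param pool_cold pool psychrophilic and psychrotolerant sequences into
#'   one cold group (default TRUE).
#' @return the records with `verdict` filled and evidence columns
#'   (`cold_mode`, `cold_freq`, `meso_mode`, `meso_freq`) added.
#' @export
classify_substitutions <- function(records, alignment,
                                   conservation_cutoff = 0.8,
                                   mode = "exact", pool_cold = TRUE) {
  mode <- match.arg(mode, c("exact", "grouped"))
  groups <- if (mode == "grouped") .SIMILARITY_GROUPS else NULL
  labs <- alignment$labels
  cold_ids <- names(labs)[labs %in%
                            (if (pool_cold) c("psychrophilic", "psychrotolerant")
                             else "psychrophilic")]
  meso_ids <- names(labs)[labs == "mesophilic"]
  .assert(length(cold_ids) >= 1 && length(meso_ids) >= 1,
          "both temperature groups must be non-empty")
  seqs <- lapply(alignment$sequences, .seq_chars)

  records$cold_mode <- NA_character_
  records$cold_freq <- NA_real_
  records$meso_mode <- NA_character_
  records$meso_freq <- NA_real_
  eq <- function(x, y) {
    if (is.na(x) || is.na(y)) return(FALSE)
    if (is.null(groups)) return(x == y)
    for (g in groups) if (x %in% g && y %in% g) return(TRUE)
    x == y
  }
  for (i in seq_len(nrow(records))) {
    j <- records$column[i]
    cold <- vapply(seqs[cold_ids], `[`, "", j)
    meso <- vapply(seqs[meso_ids], `[`, "", j)
    mc <- .mode_freq(cold, groups)
    mm <- .mode_freq(meso, groups)
    records$cold_mode[i] <- mc$mode
    records$cold_freq[i] <- mc$freq
    records$meso_mode[i] <- mm$mode
    records$meso_freq[i] <- mm$freq
    if (records$type[i] != "substitution") {
      records$verdict[i] <- "indeterminate"
      next
    }
    # groups consisting only of the targets give no independent evidence
    only_targets <- identical(sort(cold_ids), sort(alignment$target_a)) &&
      identical(sort(meso_ids), sort(alignment$target_b))
    cold_cons <- mc$freq >= conservation_cutoff
    meso_cons <- mm$freq >= conservation_cutoff
    same_mode <- eq(mc$mode, mm$mode)
    a_matches <- eq(records$label_a[i], mc$mode)
    b_matches <- eq(records$label_b[i], mm$mode)
    records$verdict[i] <-
      if (only_targets) "indeterminate"
      else if (same_mode || !meso_cons) "drift"
      else if (cold_cons && meso_cons && a_matches && b_matches) "candidate"
      else "indeterminate"
  }
  records
}

#' Percent pairwise sequence identity on an alignment
#'
#' Identical non-gap positions divided by the aligned positions carrying
#' at least one non-gap residue (i.e. only gap-gap columns are excluded;
#' an indel counts as a mismatch), times 100.
#'
#' @param seq_a,seq_b aligned sequences of equal length.
#' @param denominator `"union"` (default, as above) or `"both"` (only
#'   columns where both sequences have residues).
#' @return percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, denominator = "union") {
  denominator <- match.arg(denominator, c("union", "both"))
  a <- .seq_chars(seq_a)
  b <- .seq_chars(seq_b)
  .assert(length(a) == length(b), "sequences must have equal aligned length")
  comparable <- if (denominator == "union") a != "-" | b != "-"
  else a != "-" & b != "-"
  .assert(any(comparable), "no comparable (non-gap) positions")
  100 * sum(a == b & a != "-" & comparable) / sum(comparable)
}

#' Write substitution records or composition tables as TSV
#' @param x a data.frame of records or a `composition_delta`.
#' @param path output path.
#' @export
write_sequence_tsv <- function(x, path) {
  if (inherits(x, "composition_delta")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# amino-acid counts: %s (a) vs %s (b)",
                       x$target_a, x$target_b), con)
    write.table(x$counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
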