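#' Percent identity of the best local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with BLOSUM62 scores, gap open 11 and
#' gap extend 1 (the BL2SEQ protein defaults). Identity is the number of
#' identical aligned residues divided by the number of alignment columns
#' (gap columns included), times 100. If no positive-scoring local
#' alignment exists the identity is reported as 0 over 0 columns.
#'
#' @param seq_a,seq_b Protein sequences (character strings, non-empty).
#' @return List with `percent_identity` (0-100) and `aligned_length`
#'   (number of alignment columns).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  len <- nchar(as.character(Biostrings::pattern(aln)))
  if (len == 0) {
    return(list(percent_identity = 0, aligned_length = 0L))
  }
  # PID1: matches / (aligned positions + internal gaps) = alignment columns
  list(percent_identity = Biostrings::pid(aln, type = "PID1"),
       aligned_length = len)
}

#' Remove homologous redundancy from a fragment set
#'
#' For every pair of proteins whose full sequences exceed the identity
#' threshold in a local alignment, fragment pairs with 100% identical
#' windows (the glycosylated site in the same relative position) are
#' collapsed to a single representative; all other fragments are kept.
#' The fragment from the lexicographically smaller protein id is
#' retained. Positive and negative sets are intended to be reduced
#' separately; this function treats its input as one set.
#'
#' @param fragments data.frame of fragments sharing one window size.
#' @param sequences Named character vector of full protein sequences for
#'   every protein referenced by `fragments`.
#' @param protein_identity_threshold Percent identity above which two
#'   proteins count as homologous (default 30).
#' @return List with `kept` (the reduced fragment data.frame) and
#'   `report` (data.frame of drops: `kept_id`, `kept_position`,
#'   `dropped_id`, `dropped_position`, `reason`).
#' @export
dedup_fragments <- function(fragments, sequences,
                            protein_identity_threshold = 30) {
  if (nrow(fragments) == 0) {
    return(list(kept = fragments,
                report = data.frame(kept_id = character(0),
                                    kept_position = integer(0),
                                    dropped_id = character(0),
                                    dropped_position = integer(0),
                                    reason = character(0))))
  }
  if (length(unique(nchar(fragments$window))) != 1) {
    stop("fragments have mixed window sizes")
  }
  missing <- setdiff(unique(fragments$protein_id), names(sequences))
  if (length(missing) > 0) {
    stop(sprintf("no full sequence supplied for protein '%s'", missing[1]))
  }

  # Protein identity is only consulted for proteins that actually share an
  # identical window string, so alignments are computed lazily and cached.
  id_cache <- new.env(parent = emptyenv())
  homologous <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    v <- id_cache[[key]]
    if (is.null(v)) {
      v <- pairwise_identity(sequences[[a]], sequences[[b]])$percent_identity >
        protein_identity_threshold
      id_cache[[key]] <- v
    }
    v
  }

  ord <- order(fragments$protein_id, fragments$position)
  frag <- fragments[ord, , drop = FALSE]
  drop <- logical(nrow(frag))
  report <- list()
  groups <- split(seq_len(nrow(frag)), frag$window)
  for (idx in groups) {
    if (length(idx) < 2) next
    kept_idx <- integer(0)
    for (i in idx) {
      dropped <- FALSE
      for (j in kept_idx) {
        if (frag$protein_id[i] != frag$protein_id[j] &&
            homologous(frag$protein_id[i], frag$protein_id[j])) {
          drop[i] <- TRUE
          report[[length(report) + 1]] <- data.frame(
            kept_id = frag$protein_id[j], kept_position = frag$position[j],
            dropped_id = frag$protein_id[i],
            dropped_position = frag$position[i],
            reason = "identical_window_homologous_protein",
            stringsAsFactors = FALSE)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) kept_idx <- c(kept_idx, i)
    }
  }
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(kept_id = character(0), kept_position = integer(0),
               dropped_id = character(0), dropped_position = integer(0),
               reason = character(0))
  kept <- frag[!drop, , drop = FALSE]
  # restore the caller's row order among kept fragments
  kept <- kept[order(match(paste(kept$protein_id, kept$position),
                           paste(fragments$protein_id, fragments$position))), ,
               drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Write a deduplication report to TSV
#' @param report Report data.frame from [dedup_fragments()].
#' @param path Output path.
#' @export
write_dedup_report <- function(report, path) {
  write_tsv(report, path,
            header = "# kept_id\tkept_position\tdropped_id\tdropped_position\treason")
}
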