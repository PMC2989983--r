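#' Select the anchor position for amino acid pair discovery
#'
#' The anchor is the relative window position with the highest positional
#' F-score (maximum over residue indicators at that position). Ties are
#' broken toward the smaller absolute position, then the negative side.
#' The anchor residues are the residues observed at that position in the
#' positive class, ranked by positive-class frequency and truncated to the
#' `k_anchor` most frequent.
#'
#' @param fragments Labeled fragment data.frame (both classes present).
#' @param k_anchor Number of most-frequent anchor residues to keep
#'   (default 3).
#' @return List with `position` (relative), `residues` (ranked character
#'   vector), `fscore` (the position's score) and `tie` (TRUE if the
#'   maximum was tied).
#' @export
select_anchor <- function(fragments, k_anchor = 3) {
  pf <- positional_residue_fscores(fragments)
  per_pos <- pf$per_position
  pos_ids <- as.integer(names(per_pos))
  best <- max(per_pos)
  cand <- pos_ids[per_pos == best]
  tie <- length(cand) > 1
  ord <- order(abs(cand), cand)  # smaller |pos| first, then negative side
  anchor_pos <- cand[ord][1]
  if (tie) {
    message(sprintf("anchor F-score tied at positions %s; using %+d",
                    paste(sprintf("%+d", sort(cand)), collapse = ", "),
                    anchor_pos))
  }
  w <- nchar(fragments$window[1])
  n <- (w - 1L) %/% 2L
  col <- rel_to_col(anchor_pos, n)
  pos_res <- substr(fragments$window[fragments$label == "positive"], col, col)
  freq <- sort(table(pos_res), decreasing = TRUE)
  residues <- utils::head(names(freq), k_anchor)
  list(position = anchor_pos, residues = residues, fscore = best, tie = tie)
}

#' Enumerate candidate significant amino acid pairs for an anchor
#'
#' For every anchor residue, every other relative position, and every
#' partner residue whose positive-class frequency at that position is at
#' least `f_min`, a singleton-partner pair is scored by the F-score of
#' its binary indicator. At each partner position, the best two-residue
#' partner merge is additionally kept when it scores strictly higher than
#' both of its singletons (producing "or" partner sets).
#'
#' @param fragments Labeled fragment data.frame.
#' @param anchor Anchor as returned by [select_anchor()].
#' @param f_min Minimum positive-class partner frequency (default 0.10).
#' @return SAAP data.frame with columns `anchor_pos`, `anchor_res`,
#'   `partner_pos`, `partner_set` (comma-joined), `fscore`, sorted by
#'   descending F-score.
#' @export
enumerate_pairs <- function(fragments, anchor, f_min = 0.10) {
  is_pos <- fragment_mask(fragments)
  w <- nchar(fragments$window[1])
  n <- (w - 1L) %/% 2L
  chars <- matrix(unlist(strsplit(fragments$window, "", fixed = TRUE)),
                  nrow = nrow(fragments), byrow = TRUE)
  rows <- list()
  for (a_res in anchor$residues) {
    anchor_hit <- chars[, rel_to_col(anchor$position, n)] == a_res
    for (p in setdiff(setdiff(-n:n, 0L), anchor$position)) {
      col <- chars[, rel_to_col(p, n)]
      freq <- table(col[is_pos]) / sum(is_pos)
      partners <- names(freq)[freq >= f_min]
      partners <- intersect(partners, AA20)
      if (length(partners) == 0) next
      ind <- vapply(partners,
                    function(r) as.numeric(anchor_hit & col == r),
                    numeric(length(col)))
      ind <- matrix(ind, ncol = length(partners),
                    dimnames = list(NULL, partners))
      fs <- col_fscores(ind, is_pos)
      for (r in partners) {
        rows[[length(rows) + 1]] <- data.frame(
          anchor_pos = anchor$position, anchor_res = a_res,
          partner_pos = p, partner_set = r, fscore = unname(fs[r]),
          stringsAsFactors = FALSE)
      }
      if (length(partners) >= 2) {
        combos <- utils::combn(partners, 2, simplify = FALSE)
        merged <- vapply(combos, function(pr) {
          fscore(as.numeric(anchor_hit & col %in% pr)[is_pos],
                 as.numeric(anchor_hit & col %in% pr)[!is_pos])
        }, numeric(1))
        bi <- which.max(merged)
        pr <- combos[[bi]]
        if (merged[bi] > fs[pr[1]] && merged[bi] > fs[pr[2]]) {
          rows[[length(rows) + 1]] <- data.frame(
            anchor_pos = anchor$position, anchor_res = a_res,
            partner_pos = p, partner_set = paste(pr, collapse = ","),
            fscore = merged[bi], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(anchor_pos = integer(0), anchor_res = character(0),
               partner_pos = integer(0), partner_set = character(0),
               fscore = numeric(0))
  out <- out[order(-out$fscore, abs(out$partner_pos), out$partner_pos,
                   out$anchor_res, out$partner_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-select ranked amino acid pairs by cross-validated performance
#'
#' Candidates are sorted by descending F-score and appended to the
#' feature vector one at a time; after each addition the cross-validated
#' balanced accuracy is recorded. The prefix achieving the maximum
#' balanced accuracy is returned (ties resolved toward the shorter
#' prefix, so uninformative candidates can yield an empty selection).
#'
#' @param candidate_saaps Scored SAAP data.frame.
#' @param fragments Labeled fragment data.frame.
#' @param model_trainer Callback `function(fragments, saaps)` returning
#'   the cross-validated balanced accuracy of a model using the given
#'   SAAP features (see [cv_bacc_trainer()]).
#' @param max_pairs Maximum prefix length to explore (>= 1).
#' @return List with `saaps` (the selected prefix), `curve` (data.frame
#'   `n_pairs`, `bacc` for prefix lengths 0..max) and `best_bacc`.
#' @export
rank_and_select <- function(candidate_saaps, fragments, model_trainer,
                            max_pairs = 10) {
  if (max_pairs < 1) stop("max_pairs must be >= 1")
  ranked <- candidate_saaps[order(-candidate_saaps$fscore), , drop = FALSE]
  kmax <- min(max_pairs, nrow(ranked))
  baccs <- numeric(kmax + 1)
  for (k in 0:kmax) {
    prefix <- ranked[seq_len(k), , drop = FALSE]
    baccs[k + 1] <- model_trainer(fragments, prefix)
  }
  best_k <- which.max(baccs) - 1L  # which.max takes the first maximum: ties
  selected <- ranked[seq_len(best_k), , drop = FALSE]  # go to shorter prefix
  rownames(selected) <- NULL
  list(saaps = selected,
       curve = data.frame(n_pairs = 0:kmax, bacc = baccs),
       best_bacc = max(baccs))
}

#' Cross-validation trainer callback for forward selection
#'
#' Builds the `model_trainer` used by [rank_and_select()]: a closure that
#' runs sequence-level k-fold cross-validation with the given SAAP
#' features and returns the pooled balanced accuracy.
#'
#' @param sequences Named character vector of full protein sequences.
#' @param config Run configuration (see [run_config()]).
#' @return `function(fragments, saaps) -> balanced accuracy`.
#' @export
cv_bacc_trainer <- function(sequences, config) {
  function(fragments, saaps) {
    cfg <- config
    cfg$saaps <- saaps
    run_cv(fragments, sequences, cfg)$pooled$bacc
  }
}

#' Write a SAAP table to TSV
#'
#' Columns: center_residue, protein_class, anchor_pos, anchor_res,
#' partner_pos, partner_set, fscore.
#'
#' @param saaps SAAP data.frame; columns `center_residue` and
#'   `protein_class` are added from the arguments if absent.
#' @param path Output path.
#' @param center_residue "S" or "T" stratum tag.
#' @param protein_class "TM" or "nonTM" stratum tag.
#' @export
write_saaps <- function(saaps, path, center_residue = NA_character_,
                        protein_class = NA_character_) {
  tab <- data.frame(center_residue = rep(center_residue, nrow(saaps)),
                    protein_class = rep(protein_class, nrow(saaps)),
                    saaps[, c("anchor_pos", "anchor_res", "partner_pos",
                              "partner_set", "fscore")],
                    stringsAsFactors = FALSE)
  write_tsv(tab, path, header = paste0(
    "# center_residue\tprotein_class\tanchor_pos\tanchor_res\t",
    "partner_pos\tpartner_set\tfscore"))
}

#' Read a SAAP table written by [write_saaps()]
#' @param path Path to the SAAP TSV.
#' @return SAAP data.frame.
#' @export
read_saaps <- function(path) {
  tab <- read_tsv4(path, c("center_residue", "protein_class", "anchor_pos",
                           "anchor_res", "partner_pos", "partner_set",
                           "fscore"))
  tab$anchor_pos <- as.integer(tab$anchor_pos)
  tab$partner_pos <- as.integer(tab$partner_pos)
  tab$fscore <- as.numeric(tab$fscore)
  tab
}
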