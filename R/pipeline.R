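#' Confusion counts and derived performance statistics
#'
#' Precision = TP/(TP+FP), Sensitivity = TP/(TP+FN), Specificity =
#' TN/(TN+FP), Accuracy = (TP+TN)/total, Balanced Accuracy = (Sn+Sp)/2,
#' and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FN \cdot FP}
#' {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.}
#' A zero MCC denominator yields MCC = 0; other statistics with a zero
#' denominator are NaN.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return List with the four counts and `pr`, `sn`, `sp`, `acc`, `bacc`,
#'   `mcc`.
#' @examples
#' m <- compute_metrics(132, 462, 1988, 70)
#' round(100 * m$bacc, 1)  # 73.2
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  # double precision: the MCC denominator overflows integer arithmetic
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  den2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else (tp * tn - fn * fp) / sqrt(den2)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       pr = tp / (tp + fp), sn = sn, sp = sp,
       acc = (tp + tn) / sum(counts),
       bacc = (sn + sp) / 2, mcc = mcc)
}

#' Format a metrics list the way performance tables are reported
#'
#' Percentages to one decimal place, MCC to two.
#'
#' @param m Metrics list from [compute_metrics()].
#' @return Named character vector.
#' @export
format_metrics <- function(m) {
  c(TP = as.character(m$tp), FP = as.character(m$fp),
    TN = as.character(m$tn), FN = as.character(m$fn),
    Sensitivity = sprintf("%.1f%%", 100 * m$sn),
    Specificity = sprintf("%.1f%%", 100 * m$sp),
    Accuracy = sprintf("%.1f%%", 100 * m$acc),
    `Balanced Accuracy` = sprintf("%.1f%%", 100 * m$bacc),
    MCC = sprintf("%.2f", m$mcc))
}

#' Assign proteins to cross-validation folds
#'
#' A uniformly random partition at the sequence level: all fragments of
#' one protein share its fold. Fold sizes differ by at most one.
#'
#' @param protein_ids Character vector of unique protein ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed making the assignment reproducible.
#' @return Named integer vector protein id -> fold in 1..k.
#' @export
split_folds <- function(protein_ids, k = 5, seed = 1) {
  protein_ids <- unique(protein_ids)
  if (length(protein_ids) < k) stop("fewer proteins than folds")
  perm <- with_seed(seed, sample(protein_ids))
  folds <- rep_len(seq_len(k), length(perm))
  stats::setNames(folds[order(match(protein_ids, perm))], protein_ids)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Default run configuration
#'
#' @param window_n Flank width; windows are 2n+1 long (default 14, the
#'   29-mer used by the deployed models).
#' @param sigma RBF kernel bandwidth (default 5).
#' @param ridge_lambda Ridge regularizer for the weight solve (default 0).
#' @param k_anchor Anchor residues kept in pair discovery (default 3).
#' @param f_min Minimum positive-class partner frequency (default 0.10).
#' @param max_pairs Forward-selection cap (default 10).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment and simulation (default 1).
#' @param threshold Decision threshold on the score margin (default 0).
#' @param homology Homology reduction mode: "fold" (reduce each training
#'   fold against its own proteins; default), "global" (reduce once up
#'   front) or "none".
#' @param use_topology Veto positive predictions inside TM segments
#'   (default TRUE).
#' @param saaps SAAP feature table or NULL for BLOSUM62-only features.
#' @return A named list.
#' @export
run_config <- function(window_n = 14, sigma = 5, ridge_lambda = 0,
                       k_anchor = 3, f_min = 0.10, max_pairs = 10,
                       folds = 5, seed = 1, threshold = 0,
                       homology = c("fold", "global", "none"),
                       use_topology = TRUE, saaps = NULL) {
  stopifnot(window_n >= 1, folds >= 2, sigma > 0, ridge_lambda >= 0,
            k_anchor >= 1, f_min >= 0, f_min <= 1, max_pairs >= 1)
  list(window_n = window_n, sigma = sigma, ridge_lambda = ridge_lambda,
       k_anchor = k_anchor, f_min = f_min, max_pairs = max_pairs,
       folds = folds, seed = seed, threshold = threshold,
       homology = match.arg(homology), use_topology = use_topology,
       saaps = saaps)
}

# BLOSUM62 block plus optional SAAP block for a fragment table.
build_feature_matrix <- function(fragments, saaps = NULL) {
  X <- encode_windows(fragments$window)
  if (!is.null(saaps) && nrow(saaps) > 0) {
    X <- cbind(X, encode_saaps(fragments, saaps))
  }
  X
}

#' Sequence-level k-fold cross-validation of the RBF network
#'
#' Proteins are split into folds; in each round the classifier is trained
#' on the other folds' fragments (after homology reduction, by default
#' against that round's training proteins only) and the held-out
#' fragments are predicted. Confusion counts are pooled across folds
#' (micro-averaged) to give the headline metrics.
#'
#' @param fragments Labeled fragment data.frame for one stratum.
#' @param sequences Named character vector of full protein sequences
#'   (needed for homology reduction).
#' @param config Run configuration from [run_config()].
#' @return List with `pooled` (metrics list), `per_fold` (list of
#'   metrics), `folds` (the fold assignment) and `predictions`
#'   (data.frame with scores and decisions for every fragment).
#' @export
run_cv <- function(fragments, sequences, config = run_config()) {
  is_pos <- fragment_mask(fragments)
  folds <- split_folds(unique(fragments$protein_id), k = config$folds,
                       seed = config$seed)
  if (config$homology == "global") {
    fragments <- dedup_stratum(fragments, sequences)
    is_pos <- fragments$label == "positive"
  }
  frag_fold <- folds[fragments$protein_id]
  per_fold <- vector("list", config$folds)
  preds <- list()
  for (f in seq_len(config$folds)) {
    train <- fragments[frag_fold != f, , drop = FALSE]
    test <- fragments[frag_fold == f, , drop = FALSE]
    if (nrow(test) == 0) next
    if (config$homology == "fold") train <- dedup_stratum(train, sequences)
    if (!any(train$label == "positive") || !any(train$label == "negative")) {
      warning(sprintf("fold %d: training data lacks a class; fold skipped", f))
      next
    }
    if (!any(test$label == "positive")) {
      warning(sprintf("fold %d: no positive fragments in the test fold", f))
    }
    model <- rbfn_fit(build_feature_matrix(train, config$saaps), train$label,
                      sigma = config$sigma,
                      ridge_lambda = config$ridge_lambda)
    s <- predict_scores(model, build_feature_matrix(test, config$saaps))
    decision <- ifelse(s[, "positive"] - s[, "negative"] > config$threshold,
                       "positive", "negative")
    per_fold[[f]] <- confusion_from(test$label, decision)
    preds[[f]] <- data.frame(test[, c("protein_id", "position", "center",
                                      "label")],
                             fold = f, score_pos = s[, "positive"],
                             score_neg = s[, "negative"], decision = decision,
                             stringsAsFactors = FALSE)
  }
  counts <- Reduce(`+`, lapply(per_fold[!vapply(per_fold, is.null, TRUE)],
                               function(m) c(m$tp, m$fp, m$tn, m$fn)))
  pooled <- compute_metrics(counts[1], counts[2], counts[3], counts[4])
  list(pooled = pooled,
       per_fold = lapply(per_fold, function(m) if (is.null(m)) NULL else m),
       folds = folds,
       predictions = do.call(rbind, preds))
}

confusion_from <- function(truth, decision) {
  compute_metrics(sum(truth == "positive" & decision == "positive"),
                  sum(truth == "negative" & decision == "positive"),
                  sum(truth == "negative" & decision == "negative"),
                  sum(truth == "positive" & decision == "negative"))
}

# Homology-reduce positives and negatives separately, then recombine.
dedup_stratum <- function(fragments, sequences, threshold = 30) {
  pos <- fragments[fragments$label == "positive", , drop = FALSE]
  neg <- fragments[fragments$label == "negative", , drop = FALSE]
  rbind(dedup_fragments(pos, sequences, threshold)$kept,
        dedup_fragments(neg, sequences, threshold)$kept)
}

#' Veto positive predictions inside transmembrane segments
#'
#' O-linked glycosylation requires enzymatic access, so no true site lies
#' inside a membrane-spanning segment; any positively predicted site
#' whose position falls inside a TM segment is forced negative. All other
#' predictions (including everything on proteins without topology) are
#' unchanged, and no prediction is ever flipped negative to positive.
#'
#' @param predictions data.frame with columns `protein_id`, `position`,
#'   `decision`.
#' @param topology Named list mapping protein id to a segment data.frame.
#' @return The predictions with filtered decisions and an added
#'   `topology_label` column (segment label at each site, "Unknown" if
#'   uncovered).
#' @export
topology_filter <- function(predictions, topology) {
  labels <- site_topology_labels(predictions, topology)
  predictions$topology_label <- labels
  flip <- predictions$decision == "positive" & labels == "TM"
  predictions$decision[flip] <- "negative"
  predictions
}

site_topology_labels <- function(sites, topology) {
  vapply(seq_len(nrow(sites)), function(i) {
    seg <- topology[[sites$protein_id[i]]]
    if (is.null(seg) || nrow(seg) == 0) return("Unknown")
    hit <- seg$start <= sites$position[i] & sites$position[i] <= seg$end
    if (any(hit)) seg$label[which(hit)[1]] else "Unknown"
  }, character(1))
}

#' Tally sites by membrane topology label
#'
#' Each site is assigned the label of its containing segment, or
#' "Unknown" when no segment covers it.
#'
#' @param sites data.frame with columns `protein_id`, `position`.
#' @param topology Named list of segment data.frames.
#' @return Named integer vector over L, N, E, C, TM, S, Unknown, summing
#'   to the number of sites.
#' @export
tally_topology <- function(sites, topology) {
  labels <- site_topology_labels(sites, topology)
  counts <- stats::setNames(integer(length(TOPOLOGY_LABELS)), TOPOLOGY_LABELS)
  tab <- table(labels)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Predict O-linked glycosylation sites for one protein
#'
#' Every S/T position is scored with the model matching its residue and
#' the protein's class (TM if the protein has a TM segment, non-TM
#' otherwise). When `use_topology` is TRUE and the protein is TM,
#' positive calls inside TM segments are vetoed.
#'
#' @param record A protein record.
#' @param models Named list of `rbfn_model`s keyed "S_TM", "T_TM",
#'   "S_nonTM", "T_nonTM"; each must carry a feature schema.
#' @param use_topology Apply the transmembrane veto (default TRUE).
#' @param threshold Decision threshold on the score margin (default 0).
#' @return data.frame with one row per candidate site: `protein_id`,
#'   `position`, `residue`, `protein_class`, `score_pos`, `score_neg`,
#'   `decision`, `topology_label`, `matched_saaps`.
#' @export
predict_protein <- function(record, models, use_topology = TRUE,
                            threshold = 0) {
  sites <- candidate_sites(record)
  cls <- if (record$is_tm) "TM" else "nonTM"
  empty <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), protein_class = character(0),
                      score_pos = numeric(0), score_neg = numeric(0),
                      decision = character(0), topology_label = character(0),
                      matched_saaps = character(0))
  if (nrow(sites) == 0) return(empty)
  out <- list()
  for (res in intersect(c("S", "T"), unique(sites$residue))) {
    key <- paste0(res, "_", cls)
    model <- models[[key]]
    if (is.null(model)) stop(sprintf("no model loaded for stratum '%s'", key))
    if (is.null(model$schema)) stop(sprintf("model '%s' lacks a schema", key))
    sub <- sites[sites$residue == res, , drop = FALSE]
    frs <- do.call(rbind, lapply(sub$position, function(p)
      extract_window(record, p, model$schema$n)))
    saaps <- model$schema$saaps
    s <- predict_scores(model, build_feature_matrix(frs, saaps))
    matched <- if (is.null(saaps) || nrow(saaps) == 0) {
      rep("", nrow(frs))
    } else {
      bits <- encode_saaps(frs, saaps)
      nm <- saap_names(saaps)
      apply(bits, 1, function(b) paste(nm[b == 1], collapse = ";"))
    }
    out[[res]] <- data.frame(
      protein_id = sub$protein_id, position = sub$position,
      residue = sub$residue, protein_class = cls,
      score_pos = s[, "positive"], score_neg = s[, "negative"],
      decision = ifelse(s[, "positive"] - s[, "negative"] > threshold,
                        "positive", "negative"),
      matched_saaps = matched, stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, out)
  pred <- pred[order(pred$position), , drop = FALSE]
  topo <- stats::setNames(list(record$topology), record$id)
  if (use_topology && record$is_tm) {
    pred <- topology_filter(pred, topo)
  } else {
    pred$topology_label <- site_topology_labels(pred, topo)
  }
  rownames(pred) <- NULL
  pred[, c("protein_id", "position", "residue", "protein_class",
           "score_pos", "score_neg", "decision", "topology_label",
           "matched_saaps")]
}
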