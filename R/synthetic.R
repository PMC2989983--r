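#' Configuration for the synthetic glycoprotein generator
#'
#' The generator emulates a glycoprotein site-annotation study: random
#' protein sequences with enriched serine/threonine content, a chosen
#' fraction of transmembrane proteins with labeled topology segments,
#' positive glycosylation sites placed outside TM segments, and flanking
#' residues rewritten to implant amino-acid-pair motifs with a chosen
#' penetrance.
#'
#' @param n_proteins Number of proteins (default 60).
#' @param length_range Sequence length range, inclusive (default 150-400).
#' @param fraction_tm Fraction of proteins given TM topology (default
#'   0.17, matching the roughly one-in-six TM share of curated
#'   glycoprotein sets).
#' @param positive_rate Probability that an eligible S/T becomes a
#'   positive site (default 0.05); ignored when `n_positives` is given.
#' @param n_positives,n_negatives Optional exact annotation counts;
#'   negatives beyond `n_negatives` are subsampled away.
#' @param implanted_saaps data.frame with columns `anchor_pos`,
#'   `anchor_res`, `partner_pos`, `partner_set` (comma-joined),
#'   `penetrance`; each row is implanted independently into each positive
#'   window with its penetrance. NULL implants nothing.
#' @param background_frequencies Named residue probabilities over the 20
#'   amino acids, summing to 1. Default: uniform with S and T enriched to
#'   0.10 each so candidate sites are plentiful.
#' @param tm_segment_length_range TM segment length range (default 15-25,
#'   a typical membrane-spanning helix).
#' @param window_margin Positives are kept at least this far from the
#'   sequence ends and from each other so implanted windows never collide
#'   (default 14, one full flank).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 60, length_range = c(150, 400),
                       fraction_tm = 0.17, positive_rate = 0.05,
                       n_positives = NULL, n_negatives = NULL,
                       implanted_saaps = default_implants(),
                       background_frequencies = default_background(),
                       tm_segment_length_range = c(15, 25),
                       window_margin = 14, seed = 1) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] >= 2 * window_margin + 1,
            fraction_tm >= 0, fraction_tm <= 1,
            positive_rate >= 0, positive_rate <= 1)
  if (!setequal(names(background_frequencies), AA20) ||
      abs(sum(background_frequencies) - 1) > 1e-8) {
    stop("background_frequencies must cover the 20 amino acids and sum to 1")
  }
  if (!is.null(implanted_saaps)) {
    stopifnot(all(c("anchor_pos", "anchor_res", "partner_pos", "partner_set",
                    "penetrance") %in% names(implanted_saaps)),
              all(implanted_saaps$penetrance >= 0),
              all(implanted_saaps$penetrance <= 1),
              all(abs(implanted_saaps$anchor_pos) <= window_margin),
              all(abs(implanted_saaps$partner_pos) <= window_margin),
              all(implanted_saaps$anchor_pos != 0),
              all(implanted_saaps$partner_pos != 0))
  }
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 fraction_tm = fraction_tm, positive_rate = positive_rate,
                 n_positives = n_positives, n_negatives = n_negatives,
                 implanted_saaps = implanted_saaps,
                 background_frequencies = background_frequencies[AA20],
                 tm_segment_length_range = tm_segment_length_range,
                 window_margin = window_margin, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_background <- function() {
  p <- stats::setNames(rep((1 - 0.20) / 18, 20), AA20)
  p["S"] <- 0.10
  p["T"] <- 0.10
  p
}

#' @rdname sim_config
#' @export
default_implants <- function() {
  data.frame(anchor_pos = 3L, anchor_res = "T", partner_pos = 9L,
             partner_set = "E,T", penetrance = 0.25,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic glycoprotein dataset
#'
#' @param config A [sim_config()].
#' @return List with `records` (named list of protein records), `sites`
#'   (annotation data.frame: every S/T of every protein, labeled),
#'   `topology` (named list of segment data.frames for TM proteins) and
#'   `config`.
#' @export
generate_glycodata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  ids <- sprintf("SYN%04d", seq_len(cfg$n_proteins))
  n_tm <- round(cfg$fraction_tm * cfg$n_proteins)
  tm_ids <- if (n_tm > 0) sample(ids, n_tm) else character(0)

  chars_list <- list()
  topo_list <- list()
  eligible <- list()
  m <- cfg$window_margin
  for (id in ids) {
    len <- sample(seq(cfg$length_range[1], cfg$length_range[2]), 1)
    chars <- sample(AA20, len, replace = TRUE,
                    prob = cfg$background_frequencies)
    seg <- NULL
    if (id %in% tm_ids) {
      seg <- draw_topology(len, cfg$tm_segment_length_range)
      topo_list[[id]] <- seg
    }
    chars_list[[id]] <- chars
    pos <- which(chars %in% c("S", "T"))
    pos <- pos[pos > m & pos <= len - m]
    if (!is.null(seg)) {
      tm <- seg[seg$label == "TM", , drop = FALSE]
      in_tm <- vapply(pos, function(p) any(tm$start <= p & p <= tm$end),
                      logical(1))
      pos <- pos[!in_tm]
    }
    eligible[[id]] <- pos
  }

  # choose positive sites, enforcing a minimum spacing of 2*margin + 1
  # within each protein so implanted flanks never collide
  chosen <- lapply(ids, function(id) integer(0))
  names(chosen) <- ids
  if (!is.null(cfg$n_positives)) {
    pool <- data.frame(
      id = rep(ids, lengths(eligible)),
      pos = unlist(eligible, use.names = FALSE), stringsAsFactors = FALSE)
    pool <- pool[sample(nrow(pool)), , drop = FALSE]
    taken <- 0
    for (i in seq_len(nrow(pool))) {
      if (taken == cfg$n_positives) break
      id <- pool$id[i]
      p <- pool$pos[i]
      if (all(abs(chosen[[id]] - p) > 2 * m)) {
        chosen[[id]] <- c(chosen[[id]], p)
        taken <- taken + 1
      }
    }
    if (taken < cfg$n_positives) {
      stop(sprintf("could not place %d positives (only %d eligible sites)",
                   cfg$n_positives, taken))
    }
  } else {
    for (id in ids) {
      hits <- eligible[[id]][stats::runif(length(eligible[[id]])) <
                               cfg$positive_rate]
      keep <- integer(0)
      for (p in hits) if (all(abs(keep - p) > 2 * m)) keep <- c(keep, p)
      chosen[[id]] <- keep
    }
  }

  # implant the configured amino acid pairs into each positive window
  imp <- cfg$implanted_saaps
  for (id in ids) {
    for (p in chosen[[id]]) {
      if (is.null(imp)) next
      for (j in seq_len(nrow(imp))) {
        if (stats::runif(1) < imp$penetrance[j]) {
          partners <- strsplit(imp$partner_set[j], ",", fixed = TRUE)[[1]]
          chars_list[[id]][p + imp$anchor_pos[j]] <- imp$anchor_res[j]
          chars_list[[id]][p + imp$partner_pos[j]] <-
            partners[sample.int(length(partners), 1)]
        }
      }
    }
  }

  records <- lapply(ids, function(id) {
    protein_record(id, paste(chars_list[[id]], collapse = ""),
                   topology = topo_list[[id]])
  })
  names(records) <- ids

  sites <- do.call(rbind, lapply(ids, function(id)
    candidate_sites(records[[id]], positives = chosen[[id]])))
  if (!is.null(cfg$n_negatives)) {
    neg_idx <- which(sites$label == "negative")
    if (length(neg_idx) < cfg$n_negatives) {
      stop(sprintf("only %d negatives available, %d requested",
                   length(neg_idx), cfg$n_negatives))
    }
    drop <- sample(neg_idx, length(neg_idx) - cfg$n_negatives)
    if (length(drop) > 0) sites <- sites[-drop, , drop = FALSE]
  }
  rownames(sites) <- NULL
  list(records = records, sites = sites, topology = topo_list,
       config = cfg)
}

# Non-overlapping TM segments with the remainder labeled alternately
# E and C (extracellular first, as for a type-I membrane protein).
draw_topology <- function(len, tm_len_range) {
  n_seg <- sample(1:3, 1)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n_seg)) {
    for (try in 1:50) {
      l <- sample(seq(tm_len_range[1], tm_len_range[2]), 1)
      s <- sample(seq_len(max(1, len - l)), 1)
      e <- s + l - 1
      if (e <= len && all(e < starts - 1 | s > ends + 1)) {
        starts <- c(starts, s)
        ends <- c(ends, e)
        break
      }
    }
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  seg <- data.frame(start = starts, end = ends,
                    label = rep("TM", length(starts)),
                    stringsAsFactors = FALSE)
  gaps <- data.frame(start = c(1, ends + 1), end = c(starts - 1, len))
  gaps <- gaps[gaps$start <= gaps$end, , drop = FALSE]
  if (nrow(gaps) > 0) {
    gaps$label <- rep(c("E", "C"), length.out = nrow(gaps))
    seg <- rbind(seg, gaps)
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Deterministic fixture reproducing a published topology-filter scenario
#'
#' A set of 2652 candidate sites on one synthetic TM protein with ground
#' truth and model decisions arranged so the pre-filter confusion is
#' (TP 132, FP 462, TN 1988, FN 70), with exactly 145 of the false
#' positives lying inside TM segments and every true site outside them.
#' Applying [topology_filter()] therefore yields (132, 317, 2133, 70) and
#' removes no true positives.
#'
#' @return List with `predictions` (data.frame: `protein_id`, `position`,
#'   `residue`, `truth`, `decision`) and `topology`.
#' @export
topology_veto_fixture <- function() {
  id <- "SYNFIX_TM"
  n_fp_tm <- 145L
  pos <- seq_len(2652L)
  truth <- rep("negative", 2652L)
  decision <- rep("negative", 2652L)
  decision[1:462] <- "positive"             # false positives
  truth[463:594] <- "positive"              # 132 true positives
  decision[463:594] <- "positive"
  truth[595:664] <- "positive"              # 70 false negatives
  # remaining 1988 sites are true negatives
  topology <- stats::setNames(list(data.frame(
    start = c(1L, n_fp_tm + 1L), end = c(n_fp_tm, 2700L),
    label = c("TM", "E"), stringsAsFactors = FALSE)), id)
  predictions <- data.frame(
    protein_id = id, position = pos,
    residue = rep(c("S", "T"), length.out = 2652L),
    truth = truth, decision = decision, stringsAsFactors = FALSE)
  list(predictions = predictions, topology = topology)
}
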