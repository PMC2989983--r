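STRATA <- c("S_TM", "T_TM", "S_nonTM", "T_nonTM")

# Split fragments into the four (center residue x protein class) strata.
stratify_fragments <- function(fragments, records) {
  tm <- vapply(records, `[[`, logical(1), "is_tm")
  frag_tm <- tm[fragments$protein_id]
  key <- paste0(fragments$center, "_", ifelse(frag_tm, "TM", "nonTM"))
  split(fragments, factor(key, levels = STRATA))
}

#' Write a reproducible run manifest
#'
#' Records the command, configuration, seed, input file checksums and
#' package version alongside a command's outputs, so a deterministic run
#' can be reproduced bit for bit.
#'
#' @param path Output path for the manifest JSON.
#' @param command Command name.
#' @param config Configuration list.
#' @param inputs Named character vector of input file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(0)) {
  manifest <- list(
    tool = "glycorbf",
    version = as.character(utils::packageVersion("glycorbf")),
    command = command,
    config = config[!vapply(config, is.null, logical(1))],
    inputs = as.list(if (length(inputs) > 0)
      vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
      else character(0)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}

#' Discover significant amino acid pairs per stratum
#'
#' Runs anchor selection, pair enumeration, and cross-validated forward
#' selection independently for each of the four (residue x TM class)
#' strata, and writes one SAAP TSV per non-empty stratum plus a
#' discovery log and run manifest.
#'
#' @param fasta Path to the protein FASTA.
#' @param sites Path to the site annotation TSV.
#' @param topology Optional path to the topology TSV (required when TM
#'   strata are requested and any protein should count as TM).
#' @param out_dir Output directory.
#' @param config Run configuration from [run_config()].
#' @param strata Which strata to process (default all four).
#' @return Named list of selection results per stratum, invisibly.
#' @export
cmd_discover <- function(fasta, sites, topology = NULL, out_dir,
                         config = run_config(), strata = STRATA) {
  bad <- setdiff(strata, STRATA)
  if (length(bad) > 0) {
    stop(sprintf("unknown stratum '%s' (allowed: %s)", bad[1],
                 paste(STRATA, collapse = ", ")))
  }
  if (is.null(topology) && any(grepl("_TM$", strata))) {
    stop("TM strata requested but no --topology file given")
  }
  topo <- if (!is.null(topology)) read_topology(topology)
  records <- read_fasta(fasta, topology = topo)
  site_tab <- read_sites(sites)
  fragments <- extract_fragments(records, site_tab, config$window_n)
  sequences <- vapply(records, `[[`, character(1), "sequence")
  by_stratum <- stratify_fragments(fragments, records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trainer <- cv_bacc_trainer(sequences, config)
  results <- list()
  for (st in strata) {
    frs <- by_stratum[[st]]
    if (is.null(frs) || !any(frs$label == "positive") ||
        !any(frs$label == "negative")) {
      warning(sprintf("stratum %s has no usable data; skipped", st))
      next
    }
    anchor <- select_anchor(frs, k_anchor = config$k_anchor)
    cands <- enumerate_pairs(frs, anchor, f_min = config$f_min)
    sel <- tryCatch(
      rank_and_select(cands, frs, trainer, max_pairs = config$max_pairs),
      error = function(e) {
        warning(sprintf("stratum %s: selection failed (%s); skipped", st,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(sel)) next
    parts <- strsplit(st, "_", fixed = TRUE)[[1]]
    write_saaps(sel$saaps, file.path(out_dir, paste0("saaps_", st, ".tsv")),
                center_residue = parts[1], protein_class = parts[2])
    log_lines <- c(
      sprintf("stratum %s: anchor %+d (residues %s), F-score %.6g", st,
              anchor$position, paste(anchor$residues, collapse = ","),
              anchor$fscore),
      sprintf("stratum %s: %d candidate pairs, %d selected", st,
              nrow(cands), nrow(sel$saaps)),
      sprintf("stratum %s: selection curve %s", st,
              paste(sprintf("%d:%.4f", sel$curve$n_pairs, sel$curve$bacc),
                    collapse = " ")))
    cat(log_lines, file = file.path(out_dir, "discovery.log"), sep = "\n",
        append = TRUE)
    results[[st]] <- c(sel, list(anchor = anchor, candidates = cands))
  }
  write_manifest(file.path(out_dir, "manifest.json"), "discover", config,
                 inputs = c(fasta = fasta, sites = sites,
                            topology = topology))
  invisible(results)
}

#' Train per-stratum RBF network models
#'
#' @inheritParams cmd_discover
#' @param saap_dir Optional directory of `saaps_<stratum>.tsv` files from
#'   [cmd_discover()]; absent files mean BLOSUM62-only features.
#' @return Named list of trained models, invisibly; one
#'   `model_<stratum>.json` per stratum is written to `out_dir`.
#' @export
cmd_train <- function(fasta, sites, topology = NULL, saap_dir = NULL,
                      out_dir, config = run_config(), strata = STRATA) {
  topo <- if (!is.null(topology)) read_topology(topology)
  records <- read_fasta(fasta, topology = topo)
  site_tab <- read_sites(sites)
  fragments <- extract_fragments(records, site_tab, config$window_n)
  sequences <- vapply(records, `[[`, character(1), "sequence")
  by_stratum <- stratify_fragments(fragments, records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- list()
  for (st in strata) {
    frs <- by_stratum[[st]]
    if (is.null(frs) || !any(frs$label == "positive") ||
        !any(frs$label == "negative")) {
      warning(sprintf("stratum %s has no usable data; skipped", st))
      next
    }
    saaps <- NULL
    if (!is.null(saap_dir)) {
      f <- file.path(saap_dir, paste0("saaps_", st, ".tsv"))
      if (file.exists(f)) saaps <- read_saaps(f)
    }
    if (config$homology != "none") frs <- dedup_stratum(frs, sequences)
    model <- rbfn_fit(build_feature_matrix(frs, saaps), frs$label,
                      sigma = config$sigma,
                      ridge_lambda = config$ridge_lambda,
                      schema = list(n = config$window_n, saaps = saaps))
    write_rbfn(model, file.path(out_dir, paste0("model_", st, ".json")))
    models[[st]] <- model
  }
  write_manifest(file.path(out_dir, "manifest.json"), "train", config,
                 inputs = c(fasta = fasta, sites = sites,
                            topology = topology))
  invisible(models)
}

#' Predict O-linked glycosylation sites for a FASTA of proteins
#'
#' @inheritParams cmd_discover
#' @param model_dir Directory of `model_<stratum>.json` archives.
#' @param out Output predictions TSV.
#' @param use_topology Apply the transmembrane veto on TM proteins.
#' @param threshold Decision threshold on the score margin.
#' @return The predictions data.frame, invisibly.
#' @export
cmd_predict <- function(fasta, topology = NULL, model_dir, out,
                        use_topology = TRUE, threshold = 0) {
  topo <- if (!is.null(topology)) read_topology(topology)
  records <- read_fasta(fasta, topology = topo)
  models <- list()
  for (st in STRATA) {
    f <- file.path(model_dir, paste0("model_", st, ".json"))
    if (file.exists(f)) models[[st]] <- read_rbfn(f)
  }
  preds <- do.call(rbind, lapply(records, predict_protein, models = models,
                                 use_topology = use_topology,
                                 threshold = threshold))
  rownames(preds) <- NULL
  write_tsv(preds, out, header = paste0(
    "# protein_id\tposition\tresidue\tprotein_class\tscore_pos\t",
    "score_neg\tdecision\ttopology_label\tmatched_saaps"))
  write_manifest(paste0(out, ".manifest.json"), "predict",
                 list(use_topology = use_topology, threshold = threshold),
                 inputs = c(fasta = fasta, topology = topology))
  invisible(preds)
}

#' Cross-validated evaluation with a performance report
#'
#' Runs sequence-level cross-validation per stratum and writes a metrics
#' TSV (one row per stratum plus the pooled decisions after the optional
#' topology veto on TM strata).
#'
#' @inheritParams cmd_discover
#' @param saap_dir Optional directory of per-stratum SAAP TSVs.
#' @param out Output metrics TSV.
#' @return Named list of `run_cv()` results per stratum, invisibly.
#' @export
cmd_evaluate <- function(fasta, sites, topology = NULL, saap_dir = NULL,
                         out, config = run_config(), strata = STRATA) {
  topo <- if (!is.null(topology)) read_topology(topology)
  records <- read_fasta(fasta, topology = topo)
  site_tab <- read_sites(sites)
  fragments <- extract_fragments(records, site_tab, config$window_n)
  sequences <- vapply(records, `[[`, character(1), "sequence")
  by_stratum <- stratify_fragments(fragments, records)
  rows <- list()
  results <- list()
  for (st in strata) {
    frs <- by_stratum[[st]]
    if (is.null(frs) || !any(frs$label == "positive") ||
        !any(frs$label == "negative")) next
    cfg <- config
    if (!is.null(saap_dir)) {
      f <- file.path(saap_dir, paste0("saaps_", st, ".tsv"))
      if (file.exists(f)) cfg$saaps <- read_saaps(f)
    }
    res <- tryCatch(run_cv(frs, sequences, cfg), error = function(e) {
      warning(sprintf("stratum %s: cross-validation failed (%s); skipped",
                      st, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    m <- res$pooled
    if (config$use_topology && grepl("_TM$", st) && !is.null(topo)) {
      filtered <- topology_filter(res$predictions, topo)
      m <- confusion_from(filtered$label, filtered$decision)
      res$pooled_filtered <- m
    }
    rows[[st]] <- data.frame(stratum = st, t(format_metrics(m)),
                             check.names = FALSE)
    results[[st]] <- res
  }
  write_tsv(do.call(rbind, rows), out, header = paste0(
    "# stratum\tTP\tFP\tTN\tFN\tSn\tSp\tAcc\tBAcc\tMCC"))
  write_manifest(paste0(out, ".manifest.json"), "evaluate", config,
                 inputs = c(fasta = fasta, sites = sites,
                            topology = topology))
  invisible(results)
}

#' Generate and write a synthetic dataset
#'
#' @param out_dir Output directory; writes `proteins.fasta`, `sites.tsv`
#'   and `topology.tsv` in the dialects consumed by the readers.
#' @param config A [sim_config()].
#' @return The generated dataset, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = sim_config()) {
  data <- generate_glycodata(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data$records, file.path(out_dir, "proteins.fasta"))
  write_sites(data$sites, file.path(out_dir, "sites.tsv"))
  write_topology(data$topology, file.path(out_dir, "topology.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), "simulate",
                 unclass(config))
  invisible(data)
}
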