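#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; non-standard residue codes (B, Z, U, O, J, X)
#' are mapped to the terminal symbol with a warning. Record ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param topology Optional topology map (as returned by [read_topology()])
#'   whose segments are attached to matching records.
#' @return A named list of protein records; each record is a list with
#'   elements `id`, `sequence`, `topology` (data.frame with columns
#'   `start`, `end`, `label`) and `is_tm` (TRUE if at least one TM
#'   segment is present).
#' @export
read_fasta <- function(path, topology = NULL) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf(
                    "failed to parse FASTA '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(set) == 0) stop(sprintf("FASTA '%s' contains no records", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(ids == "")) stop(sprintf("FASTA '%s': empty header", path))
  if (anyDuplicated(ids)) {
    stop(sprintf("FASTA '%s': duplicate record id '%s'",
                 path, ids[duplicated(ids)][1]))
  }
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop(sprintf("FASTA '%s': record '%s' has an empty sequence",
                 path, ids[nchar(seqs) == 0][1]))
  }
  records <- lapply(seq_along(ids), function(i) {
    protein_record(ids[i], seqs[i],
                   topology = if (!is.null(topology)) topology[[ids[i]]])
  })
  names(records) <- ids
  records
}

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param sequence Amino acid sequence (uppercased and validated).
#' @param topology Optional data.frame of topology segments with columns
#'   `start`, `end`, `label`.
#' @return A protein record list (see [read_fasta()]).
#' @export
protein_record <- function(id, sequence, topology = NULL) {
  sequence <- normalize_sequence(sequence, id)
  if (is.null(topology)) {
    topology <- data.frame(start = integer(0), end = integer(0),
                           label = character(0))
  } else {
    validate_segments(topology, nchar(sequence), id)
  }
  list(id = id, sequence = sequence, topology = topology,
       is_tm = any(topology$label == "TM"))
}

#' Write protein records to FASTA
#' @param records Named list of protein records.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$sequence)))
  writeLines(lines, path)
  invisible(path)
}

TOPOLOGY_LABELS <- c("L", "N", "E", "C", "TM", "S", "Unknown")

validate_segments <- function(seg, seq_len = NULL, id = "<protein>") {
  stopifnot(all(c("start", "end", "label") %in% names(seg)))
  if (nrow(seg) == 0) return(invisible(seg))
  bad <- !(seg$label %in% TOPOLOGY_LABELS)
  if (any(bad)) {
    stop(sprintf("protein '%s': unknown topology label '%s' (allowed: %s)",
                 id, seg$label[bad][1], paste(TOPOLOGY_LABELS, collapse = ", ")))
  }
  if (any(seg$start < 1) || any(seg$start > seg$end)) {
    stop(sprintf("protein '%s': segment with start > end or start < 1", id))
  }
  if (!is.null(seq_len) && any(seg$end > seq_len)) {
    stop(sprintf("protein '%s': segment end exceeds sequence length %d",
                 id, seq_len))
  }
  o <- order(seg$start)
  if (any(seg$start[o][-1] <= seg$end[o][-nrow(seg)])) {
    stop(sprintf("protein '%s': overlapping topology segments", id))
  }
  invisible(seg[o, , drop = FALSE])
}

#' Read membrane topology segments from a TSV file
#'
#' Expected columns: protein id, start, end, label (tab-separated,
#' 1-based inclusive coordinates, optional single '#'-prefixed header
#' line). Labels: L (lumenal), N (nucleoplasmic), E (extracellular),
#' C (cytoplasmic), TM (transmembrane), S (signal peptide), Unknown.
#'
#' @param path Path to the topology TSV.
#' @return Named list mapping protein id to a data.frame of segments
#'   (`start`, `end`, `label`), sorted by start.
#' @export
read_topology <- function(path) {
  tab <- read_tsv4(path, c("protein_id", "start", "end", "label"))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (anyNA(tab$start) || anyNA(tab$end)) {
    stop(sprintf("topology '%s': non-integer coordinates", path))
  }
  out <- lapply(split(tab, tab$protein_id), function(d) {
    seg <- data.frame(start = d$start, end = d$end, label = d$label)
    seg <- tryCatch(validate_segments(seg, id = d$protein_id[1]),
                    error = function(e) stop(sprintf(
                      "topology '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    seg[order(seg$start), , drop = FALSE]
  })
  out
}

#' Write a topology map to TSV
#' @param topology Named list of segment data.frames.
#' @param path Output path.
#' @export
write_topology <- function(topology, path) {
  rows <- lapply(names(topology), function(id) {
    seg <- topology[[id]]
    if (nrow(seg) == 0) return(NULL)
    data.frame(protein_id = id, start = seg$start, end = seg$end,
               label = seg$label)
  })
  tab <- do.call(rbind, rows)
  write_tsv(tab, path, header = "# protein_id\tstart\tend\tlabel")
}

#' Read site annotations from a TSV file
#'
#' Expected columns: protein id, 1-based position, residue (S or T),
#' label (positive or negative).
#'
#' @param path Path to the sites TSV.
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `label`.
#' @export
read_sites <- function(path) {
  tab <- read_tsv4(path, c("protein_id", "position", "residue", "label"))
  tab$position <- as.integer(tab$position)
  if (anyNA(tab$position)) stop(sprintf("sites '%s': non-integer position", path))
  if (!all(tab$residue %in% c("S", "T"))) {
    stop(sprintf("sites '%s': residue must be S or T", path))
  }
  if (!all(tab$label %in% c("positive", "negative"))) {
    stop(sprintf("sites '%s': label must be positive or negative", path))
  }
  tab
}

#' Write site annotations to TSV
#' @param sites data.frame with columns `protein_id`, `position`,
#'   `residue`, `label`.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  write_tsv(sites[, c("protein_id", "position", "residue", "label")], path,
            header = "# protein_id\tposition\tresidue\tlabel")
}

read_tsv4 <- function(path, cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && startsWith(lines[1], "#")) lines <- lines[-1]
  if (length(lines) == 0) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(tab)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    stop(sprintf("'%s' line %d: expected %d tab-separated fields, got %d",
                 path, which(nf != length(cols))[1], length(cols),
                 nf[nf != length(cols)][1]))
  }
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- cols
  tab
}

write_tsv <- function(tab, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (!is.null(tab) && nrow(tab) > 0) {
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Enumerate every candidate S/T site of a protein
#'
#' Every serine and threonine position is returned; positions present in
#' `positives` are labeled positive, all others negative.
#'
#' @param record A protein record.
#' @param positives Integer vector of 1-based positions annotated as
#'   glycosylated.
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `label`.
#' @export
candidate_sites <- function(record, positives = integer(0)) {
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars %in% c("S", "T"))
  if (length(positives) > 0) {
    missing <- setdiff(positives, pos)
    if (length(missing) > 0) {
      stop(sprintf("protein '%s': annotated position %d is not S/T",
                   record$id, missing[1]))
    }
  }
  data.frame(protein_id = rep(record$id, length(pos)),
             position = pos,
             residue = chars[pos],
             label = ifelse(pos %in% positives, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Extract the fixed-length window around a candidate site
#'
#' The window has length 2n+1 and is centered on the site; positions
#' falling outside the sequence are filled with the terminal symbol.
#'
#' @param record A protein record.
#' @param position 1-based position of an S or T residue.
#' @param n Number of flanking residues on each side (window length 2n+1).
#' @param label Optional class label carried along.
#' @return A one-row data.frame fragment with columns `protein_id`,
#'   `position`, `center`, `window`, `label`.
#' @export
extract_window <- function(record, position, n, label = NA_character_) {
  stopifnot(n >= 1)
  len <- nchar(record$sequence)
  if (position < 1 || position > len) {
    stop(sprintf("protein '%s': position %d outside sequence (length %d)",
                 record$id, position, len))
  }
  center <- substr(record$sequence, position, position)
  if (!(center %in% c("S", "T"))) {
    stop(sprintf("protein '%s': residue at position %d is '%s', not S/T",
                 record$id, position, center))
  }
  lo <- position - n
  hi <- position + n
  core <- substr(record$sequence, max(1, lo), min(len, hi))
  window <- paste0(strrep(TERMINAL, max(0, 1 - lo)), core,
                   strrep(TERMINAL, max(0, hi - len)))
  data.frame(protein_id = record$id, position = position, center = center,
             window = window, label = label, stringsAsFactors = FALSE)
}

#' Extract windows for a whole annotation table
#'
#' @param records Named list of protein records.
#' @param sites data.frame of site annotations (see [read_sites()]).
#' @param n Flank width; windows have length 2n+1.
#' @return data.frame of fragments, one row per site.
#' @export
extract_fragments <- function(records, sites, n) {
  frs <- lapply(seq_len(nrow(sites)), function(i) {
    rec <- records[[sites$protein_id[i]]]
    if (is.null(rec)) {
      stop(sprintf("sites refer to unknown protein '%s'", sites$protein_id[i]))
    }
    extract_window(rec, sites$position[i], n, label = sites$label[i])
  })
  do.call(rbind, frs)
}

# Relative window position (-n..+n) -> column index in the window string.
rel_to_col <- function(rel, n) {
  stopifnot(all(abs(rel) <= n))
  rel + n + 1L
}
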