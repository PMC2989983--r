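#' F-score of one feature between two classes
#'
#' The ratio of between-class to within-class scatter for a single
#' feature: \deqn{F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar
#' x)^2}{s^2_{+} + s^2_{-}}} where \eqn{\bar x} is the grand mean over
#' both classes and \eqn{s^2_{\pm}} are the unbiased (n-1 denominator)
#' within-class variances. Symmetric in the two classes and invariant
#' under affine rescaling of the feature. This is the feature-selection
#' F-score, not the F1 classification measure.
#'
#' When both within-class variances are zero the convention is: 0 if the
#' class means are equal (the feature is constant), `Inf` otherwise (the
#' feature separates the classes perfectly).
#'
#' @param values_pos,values_neg Numeric vectors of the feature in the
#'   positive and negative class; each needs at least 2 values.
#' @return A nonnegative number (possibly `Inf`).
#' @examples
#' fscore(c(0, 2), c(-1, 1))  # 0.125
#' @export
fscore <- function(values_pos, values_neg) {
  if (length(values_pos) < 2 || length(values_neg) < 2) {
    stop("each class needs at least 2 values for the F-score")
  }
  mp <- mean(values_pos)
  mn <- mean(values_neg)
  m <- mean(c(values_pos, values_neg))
  num <- (mp - m)^2 + (mn - m)^2
  den <- stats::var(values_pos) + stats::var(values_neg)
  if (den == 0) {
    if (mp == mn) return(0)
    return(Inf)
  }
  num / den
}

# Column-wise F-scores of a feature matrix against a logical positive mask.
# Same statistic as fscore(), vectorized over columns.
col_fscores <- function(X, is_pos) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  stopifnot(np >= 2, nn >= 2)
  Xp <- X[is_pos, , drop = FALSE]
  Xn <- X[!is_pos, , drop = FALSE]
  mp <- colMeans(Xp)
  mn <- colMeans(Xn)
  m <- colMeans(X)
  num <- (mp - m)^2 + (mn - m)^2
  vp <- (colSums(Xp^2) - np * mp^2) / (np - 1)
  vn <- (colSums(Xn^2) - nn * mn^2) / (nn - 1)
  den <- pmax(vp, 0) + pmax(vn, 0)
  out <- ifelse(den == 0, ifelse(mp == mn, 0, Inf), num / den)
  names(out) <- colnames(X)
  out
}

#' Encode a fragment window with normalized BLOSUM62 rows
#'
#' Every position of the 2n+1 window contributes 21 numbers: the
#' residue's min-max normalized BLOSUM62 row with 0 in the 21st slot, or,
#' for the terminal symbol, zeros with 1 in the 21st slot.
#'
#' @param fragment A one-row fragment data.frame (or anything with a
#'   `window` element).
#' @return Numeric vector of length (2n+1) * 21.
#' @export
encode_blosum62 <- function(fragment) {
  as.numeric(encode_windows(fragment$window[1]))
}

#' Encode many windows into a feature matrix
#'
#' @param windows Character vector of equal-length windows over the
#'   21-symbol alphabet.
#' @return Numeric matrix, one row per window, (window length) * 21
#'   columns ordered position-major.
#' @export
encode_windows <- function(windows) {
  stopifnot(length(windows) > 0)
  w <- unique(nchar(windows))
  if (length(w) != 1) stop("windows have mixed lengths")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE)),
                  nrow = length(windows), byrow = TRUE)
  idx <- matrix(match(chars, ALPHABET21), nrow = nrow(chars))
  if (anyNA(idx)) {
    stop(sprintf("window symbol outside the 21-letter alphabet: '%s'",
                 chars[is.na(idx)][1]))
  }
  enc <- blosum62_encoding()
  out <- matrix(0, nrow = length(windows), ncol = w * 21L)
  for (p in seq_len(w)) {
    out[, ((p - 1L) * 21L + 1L):(p * 21L)] <- enc[idx[, p], , drop = FALSE]
  }
  out
}

#' Positional residue F-scores around the candidate site
#'
#' For every relative window position p != 0 and every residue a, the
#' F-score of the binary indicator "window carries a at p" computed over
#' positive versus negative fragments. The per-position summary score is
#' the maximum over residues at that position.
#'
#' @param fragments Labeled fragment data.frame (both classes present).
#' @return List with `table` (data.frame `pos`, `residue`, `fscore`) and
#'   `per_position` (named numeric vector of per-position maxima, names
#'   are the relative positions).
#' @export
positional_residue_fscores <- function(fragments) {
  is_pos <- fragment_mask(fragments)
  w <- nchar(fragments$window[1])
  n <- (w - 1L) %/% 2L
  chars <- matrix(unlist(strsplit(fragments$window, "", fixed = TRUE)),
                  nrow = nrow(fragments), byrow = TRUE)
  rows <- list()
  for (rel in setdiff(-n:n, 0L)) {
    col <- chars[, rel_to_col(rel, n)]
    present <- intersect(ALPHABET21, unique(col))
    ind <- matrix(0, nrow = length(col), ncol = length(present),
                  dimnames = list(NULL, present))
    ind[cbind(seq_along(col), match(col, present))] <- 1
    fs <- col_fscores(ind, is_pos)
    rows[[length(rows) + 1]] <- data.frame(
      pos = rel, residue = present, fscore = unname(fs),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  per_pos <- tapply(tab$fscore, tab$pos, max)
  list(table = tab,
       per_position = stats::setNames(as.numeric(per_pos),
                                      names(per_pos)))
}

fragment_mask <- function(fragments) {
  if (!all(fragments$label %in% c("positive", "negative"))) {
    stop("fragments must be labeled positive/negative")
  }
  is_pos <- fragments$label == "positive"
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  is_pos
}

#' Binary SAAP indicator features for fragments
#'
#' Bit j is 1 iff the window carries the anchor residue at the anchor
#' position and any member of the partner set at the partner position.
#'
#' @param fragments Fragment data.frame (windows of one size 2n+1).
#' @param saaps SAAP table: data.frame with columns `anchor_pos`,
#'   `anchor_res`, `partner_pos`, `partner_set` (comma-joined residues).
#' @return 0/1 matrix, one row per fragment, one column per SAAP.
#' @export
encode_saaps <- function(fragments, saaps) {
  w <- nchar(fragments$window[1])
  n <- (w - 1L) %/% 2L
  out <- matrix(0L, nrow = nrow(fragments), ncol = nrow(saaps))
  if (nrow(saaps) == 0) return(out)
  if (any(saaps$anchor_pos == 0L) || any(saaps$partner_pos == 0L) ||
      any(abs(saaps$anchor_pos) > n) || any(abs(saaps$partner_pos) > n)) {
    stop("SAAP references position 0 or outside the window")
  }
  for (j in seq_len(nrow(saaps))) {
    ac <- rel_to_col(saaps$anchor_pos[j], n)
    pc <- rel_to_col(saaps$partner_pos[j], n)
    partners <- strsplit(saaps$partner_set[j], ",", fixed = TRUE)[[1]]
    hit <- substr(fragments$window, ac, ac) == saaps$anchor_res[j] &
      substr(fragments$window, pc, pc) %in% partners
    out[, j] <- as.integer(hit)
  }
  colnames(out) <- saap_names(saaps)
  out
}

#' Human-readable SAAP names like "(+3T, +9E or +9T)"
#' @param saaps SAAP table.
#' @return Character vector.
#' @export
saap_names <- function(saaps) {
  if (nrow(saaps) == 0) return(character(0))
  vapply(seq_len(nrow(saaps)), function(j) {
    partners <- strsplit(saaps$partner_set[j], ",", fixed = TRUE)[[1]]
    pp <- sprintf("%+d%s", saaps$partner_pos[j], partners)
    sprintf("(%+d%s, %s)", saaps$anchor_pos[j], saaps$anchor_res[j],
            paste(pp, collapse = " or "))
  }, character(1))
}

#' Positional F-scores of a physicochemical property
#'
#' Replaces every residue of the window with a per-residue property value
#' (terminal symbol = 0) and computes the class F-score of that value at
#' each relative position.
#'
#' @param fragments Labeled fragment data.frame.
#' @param property_table Named numeric vector mapping each of the 20
#'   amino acids to one value.
#' @return Named numeric vector: relative position -> F-score.
#' @export
property_fscore <- function(fragments, property_table) {
  missing <- setdiff(AA20, names(property_table))
  if (length(missing) > 0) {
    stop(sprintf("property table lacks residues: %s",
                 paste(missing, collapse = ", ")))
  }
  vals <- c(property_table[AA20], 0)
  names(vals) <- ALPHABET21
  is_pos <- fragment_mask(fragments)
  w <- nchar(fragments$window[1])
  n <- (w - 1L) %/% 2L
  chars <- matrix(unlist(strsplit(fragments$window, "", fixed = TRUE)),
                  nrow = nrow(fragments), byrow = TRUE)
  X <- matrix(vals[chars], nrow = nrow(fragments))
  fs <- col_fscores(X, is_pos)
  stats::setNames(fs, as.character(seq_len(w) - n - 1L))
}

#' Parse an AAindex1 flat file of physicochemical properties
#'
#' Reads accessions (H lines) and the two I-block rows of 10 values in
#' the standard A/R/N/D/C/Q/E/G/H/I and L/K/M/F/P/S/T/W/Y/V order.
#' Entries with missing ("NA") values are dropped.
#'
#' @param path Path to an AAindex1-format file.
#' @return Named list of property tables (named numeric vectors over the
#'   20 amino acids), keyed by accession.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path)
  out <- list()
  acc <- NULL
  i <- 1
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  while (i <= length(lines)) {
    line <- lines[i]
    if (startsWith(line, "H ")) {
      acc <- trimws(sub("^H ", "", line))
    } else if (startsWith(line, "I ")) {
      if (is.null(acc)) stop(sprintf("'%s' line %d: I block before H line", path, i))
      if (i + 2 > length(lines)) stop(sprintf("'%s': truncated I block", path))
      v1 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]]))
      v2 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2]), "\\s+")[[1]]))
      if (length(v1) == 10 && length(v2) == 10 && !anyNA(c(v1, v2))) {
        out[[acc]] <- stats::setNames(c(v1, v2), c(row1, row2))
      }
      i <- i + 2
    }
    i <- i + 1
  }
  out
}

#' Read a plain two-column residue/value property table
#' @param path TSV with columns residue, value (optional '#' header).
#' @return Named numeric vector over the 20 amino acids.
#' @export
read_property_tsv <- function(path) {
  tab <- read_tsv4(path, c("residue", "value"))
  v <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(v)) stop(sprintf("'%s': non-numeric property value", path))
  stats::setNames(v, tab$residue)
}
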