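#' @keywords internal
"_PACKAGE"

# 20 standard amino acids in the conventional BLOSUM row order, plus a 21st
# terminal symbol used to pad windows that run past a sequence end. The
# terminal symbol is rendered as "X" in all text output; non-standard
# residue codes (B, Z, U, O, J, X) are mapped onto it on input.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
TERMINAL <- "X"
ALPHABET21 <- c(AA20, TERMINAL)
NONSTANDARD <- c("B", "Z", "U", "O", "J", "X")

#' Per-symbol encoding matrix from the normalized BLOSUM62 matrix
#'
#' Each of the 20 amino acids is encoded by its 20-entry BLOSUM62 row,
#' min-max normalized to \[0,1\] over the whole 20x20 matrix, followed by a
#' 0 in the 21st (terminal) slot. The terminal symbol encodes as all zeros
#' with a 1 in the 21st slot. BLOSUM62 scores range over \[-4, 11\], so the
#' normalization is (s + 4) / 15.
#'
#' @return A 21 x 21 numeric matrix with rownames `ALPHABET21`; row i is
#'   the 21-number encoding of symbol i.
#' @examples
#' enc <- blosum62_encoding()
#' range(enc)  # 0 to 1
#' @export
blosum62_encoding <- function() {
  if (is.null(.enc_cache$m)) {
    b <- get_blosum62()[AA20, AA20]
    norm <- (b - min(b)) / (max(b) - min(b))
    m <- rbind(cbind(norm, 0), c(rep(0, 20), 1))
    rownames(m) <- ALPHABET21
    colnames(m) <- ALPHABET21
    .enc_cache$m <- m
  }
  .enc_cache$m
}

.enc_cache <- new.env(parent = emptyenv())

# BLOSUM62 substitution matrix (half-bit scores) as shipped with Biostrings.
get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Uppercase a sequence and map non-standard residue codes to the terminal
# symbol, warning once per offending record.
normalize_sequence <- function(seq, id = "<sequence>") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA20)
  if (any(bad)) {
    nonstd <- unique(chars[bad])
    unknown <- setdiff(nonstd, NONSTANDARD)
    if (length(unknown) > 0) {
      stop(sprintf("record '%s': invalid sequence characters: %s",
                   id, paste(unknown, collapse = ", ")))
    }
    warning(sprintf(
      "record '%s': non-standard residues (%s) mapped to terminal symbol '%s'",
      id, paste(nonstd, collapse = ", "), TERMINAL), call. = FALSE)
    chars[bad] <- TERMINAL
    seq <- paste(chars, collapse = "")
  }
  seq
}
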