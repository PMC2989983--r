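# Shared fixture builders and independent oracles for the test suite.

AA20 <- glycorbf:::AA20

# Build a labeled fragment table with the given windows.
make_fragments <- function(windows, labels,
                           protein_ids = sprintf("P%03d", seq_along(windows)),
                           positions = rep(50L, length(windows))) {
  w <- nchar(windows[1])
  n <- (w - 1L) %/% 2L
  data.frame(protein_id = protein_ids, position = positions,
             center = substr(windows, n + 1L, n + 1L),
             window = windows, label = labels, stringsAsFactors = FALSE)
}

# Random windows with an S/T center; optionally force residues at
# relative positions (a named vector rel -> residue).
random_window <- function(n, force = NULL, exclude = character(0)) {
  pool <- setdiff(AA20, exclude)
  ch <- sample(pool, 2 * n + 1, replace = TRUE)
  ch[n + 1] <- sample(c("S", "T"), 1)
  if (!is.null(force)) {
    for (rel in names(force)) ch[n + 1 + as.integer(rel)] <- force[[rel]]
  }
  paste(ch, collapse = "")
}

# Independent scalar F-score: direct transcription of the
# between-over-within scatter formula using mean() and var().
fscore_oracle <- function(xp, xn) {
  m <- mean(c(xp, xn))
  num <- (mean(xp) - m)^2 + (mean(xn) - m)^2
  den <- var(xp) + var(xn)
  if (den == 0) return(if (mean(xp) == mean(xn)) 0 else Inf)
  num / den
}

# Exhaustive Gotoh dynamic-programming oracle for local alignment percent
# identity with affine gaps (cost of a length-L gap = open + L * ext),
# BLOSUM62 scores. Independent of the Biostrings alignment path.
sw_identity_oracle <- function(a, b, open = 11, ext = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      M[i + 1, j + 1] <- sub[A[i], B[j]] +
        max(0, M[i, j], X[i, j], Y[i, j])
    }
  }
  best <- max(M)
  if (best <= 0) return(list(percent_identity = 0, aligned_length = 0L))
  idx <- which(M == best, arr.ind = TRUE)[1, ]
  i <- idx[1] - 1L; j <- idx[2] - 1L
  state <- "M"
  matches <- 0L; columns <- 0L
  repeat {
    if (state == "M") {
      columns <- columns + 1L
      if (A[i] == B[j]) matches <- matches + 1L
      prev <- c(stop = 0, M = M[i, j], X = X[i, j], Y = Y[i, j])
      state <- names(prev)[which.max(prev)]
      i <- i - 1L; j <- j - 1L
      if (state == "stop") break
    } else if (state == "X") {
      columns <- columns + 1L
      state <- if (M[i, j + 1] - open - ext >= X[i, j + 1] - ext) "M" else "X"
      i <- i - 1L
    } else {
      columns <- columns + 1L
      state <- if (M[i + 1, j] - open - ext >= Y[i + 1, j] - ext) "M" else "Y"
      j <- j - 1L
    }
  }
  list(percent_identity = 100 * matches / columns, aligned_length = columns)
}

# Separable synthetic study conditions: two strongly penetrant implanted
# pairs over a rare-in-background anchor residue.
separable_implants <- function(penetrance = 0.95) {
  data.frame(anchor_pos = c(3L, -4L), anchor_res = c("W", "F"),
             partner_pos = c(9L, -8L), partner_set = c("E,T", "G"),
             penetrance = penetrance, stringsAsFactors = FALSE)
}
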