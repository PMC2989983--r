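test_that("F-score matches hand evaluation and its invariances hold", {
  expect_equal(fscore(c(0, 2), c(-1, 1)), 0.125)
  expect_equal(fscore(c(1, 2, 3), c(1, 2, 3)), 0)
  # symmetric in the class labels
  expect_equal(fscore(c(0, 2), c(-1, 1)), fscore(c(-1, 1), c(0, 2)))
  # zero-variance conventions
  expect_equal(fscore(c(1, 1), c(1, 1)), 0)
  expect_equal(fscore(c(1, 1), c(2, 2)), Inf)
  expect_error(fscore(1, c(1, 2)), "at least 2")

  set.seed(3)
  for (i in 1:20) {
    xp <- rnorm(sample(2:30, 1))
    xn <- rnorm(sample(2:30, 1), mean = runif(1, -2, 2))
    f <- fscore(xp, xn)
    expect_equal(f, fscore_oracle(xp, xn))
    expect_gte(f, 0)
    # affine invariance: x -> a x + b, a != 0
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- rnorm(1)
    expect_equal(fscore(a * xp + b, a * xn + b), f, tolerance = 1e-9)
    expect_equal(fscore(xn, xp), f)
  }
})

test_that("BLOSUM62 window encoding has the documented block structure", {
  enc <- blosum62_encoding()
  expect_equal(dim(enc), c(21L, 21L))
  expect_true(all(enc >= 0 & enc <= 1))
  # amino acid rows end in 0; the terminal row is a lone 1 in slot 21
  expect_true(all(enc[1:20, 21] == 0))
  expect_equal(unname(enc["X", ]), c(rep(0, 20), 1))

  fr <- make_fragments(random_window(14), "positive")
  v <- encode_blosum62(fr)
  expect_length(v, 29 * 21)

  # identical windows give identical vectors; distinct windows distinct ones
  w <- random_window(3)
  expect_identical(encode_windows(c(w, w))[1, ], encode_windows(c(w, w))[2, ])
  set.seed(9)
  ws <- unique(replicate(15, random_window(3)))
  M <- encode_windows(ws)
  expect_equal(nrow(unique(M)), length(ws))

  # all-terminal flanks contribute exactly one 1 per position
  v2 <- as.numeric(encode_windows(strrep("X", 9)))
  expect_equal(sum(v2 == 1), 9)
  expect_equal(sum(v2), 9)
  expect_error(encode_windows("AB*"), "alphabet")
})

test_that("positional residue F-scores find an implanted discriminative residue", {
  set.seed(21)
  pos <- replicate(30, random_window(4, force = c("2" = "P")))
  neg <- replicate(60, random_window(4, exclude = "P"))
  frs <- make_fragments(c(pos, neg),
                        rep(c("positive", "negative"), c(30, 60)))
  pf <- positional_residue_fscores(frs)
  top <- pf$table[which.max(pf$table$fscore), ]
  expect_equal(top$pos, 2)
  expect_equal(top$residue, "P")
  expect_equal(unname(which.max(pf$per_position)),
               which(names(pf$per_position) == "2"))
  # every tabulated value agrees with a direct indicator evaluation
  chars <- do.call(rbind, strsplit(frs$window, ""))
  for (k in sample(nrow(pf$table), 25)) {
    ind <- as.numeric(chars[, pf$table$pos[k] + 5] == pf$table$residue[k])
    expect_equal(pf$table$fscore[k],
                 fscore_oracle(ind[frs$label == "positive"],
                               ind[frs$label == "negative"]),
                 tolerance = 1e-12)
  }
  expect_error(positional_residue_fscores(
    make_fragments(pos, rep("positive", 30))), "both classes")
})

test_that("label permutation destroys positional signal relative to its null", {
  set.seed(99)
  pos <- replicate(25, random_window(4, force = c("2" = "P")))
  neg <- replicate(50, random_window(4, exclude = "P"))
  labels <- rep(c("positive", "negative"), c(25, 50))
  frs <- make_fragments(c(pos, neg), labels)
  perm_max <- replicate(200, {
    f <- frs
    f$label <- sample(labels)
    max(positional_residue_fscores(f)$per_position)
  })
  observed <- max(positional_residue_fscores(frs)$per_position)
  null99 <- quantile(perm_max, 0.99)
  expect_gt(observed, null99)
  # one more permuted draw behaves like the null, not like the signal
  f <- frs
  f$label <- sample(labels)
  expect_lt(max(positional_residue_fscores(f)$per_position), observed / 2)
})

test_that("SAAP indicator bits require anchor and any partner-set member", {
  saap <- data.frame(anchor_pos = 3L, anchor_res = "T", partner_pos = 9L,
                     partner_set = "E,T", fscore = 0.071)
  w_hit <- random_window(14, force = c("3" = "T", "9" = "E"))
  w_hit2 <- random_window(14, force = c("3" = "T", "9" = "T"))
  w_anchor_fail <- random_window(14, force = c("3" = "A", "9" = "E"))
  w_partner_fail <- random_window(14, force = c("3" = "T", "9" = "A"))
  frs <- make_fragments(c(w_hit, w_hit2, w_anchor_fail, w_partner_fail),
                        rep("positive", 4))
  bits <- encode_saaps(frs, saap)
  expect_equal(as.integer(bits), c(1L, 1L, 0L, 0L))
  expect_true(all(bits %in% c(0L, 1L)))
  expect_equal(ncol(encode_saaps(frs, saap[0, ])), 0L)
  expect_equal(saap_names(saap), "(+3T, +9E or +9T)")

  bad <- saap
  bad$partner_pos <- 0L
  expect_error(encode_saaps(frs, bad), "position 0")
})

test_that("physicochemical property F-scores reduce to indicator scores", {
  set.seed(31)
  pos <- replicate(20, random_window(4, force = c("-1" = "P")))
  neg <- replicate(40, random_window(4, exclude = "P"))
  frs <- make_fragments(c(pos, neg),
                        rep(c("positive", "negative"), c(20, 40)))
  # constant property: no position discriminates
  const <- setNames(rep(3.5, 20), AA20)
  expect_true(all(property_fscore(frs, const) == 0))
  # indicator-of-proline property reproduces the positional residue score
  ind_p <- setNames(as.numeric(AA20 == "P"), AA20)
  pf <- positional_residue_fscores(frs)
  prop <- property_fscore(frs, ind_p)
  row <- pf$table[pf$table$pos == -1 & pf$table$residue == "P", ]
  expect_equal(unname(prop[["-1"]]), row$fscore, tolerance = 1e-12)
  # affine rescaling leaves every positional score unchanged
  hydro <- setNames(rnorm(20), AA20)
  expect_equal(property_fscore(frs, 2.5 * hydro - 7),
               property_fscore(frs, hydro), tolerance = 1e-9)
  expect_error(property_fscore(frs, hydro[-1]), "lacks")
})

test_that("AAindex flat files and plain property TSVs parse", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "H TEST0001",
    "D A synthetic test index",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.62   -2.53   -0.78   -0.90    0.29   -0.85   -0.74    0.48   -0.40    1.38",
    "    1.06   -1.50    0.64    1.19    0.12   -0.18   -0.05    0.81    0.26    1.08",
    "//"), f)
  idx <- read_aaindex(f)
  expect_named(idx, "TEST0001")
  expect_equal(unname(idx$TEST0001["A"]), 0.62)
  expect_equal(unname(idx$TEST0001["V"]), 1.08)
  expect_length(idx$TEST0001, 20)

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# residue\tvalue", paste(AA20, seq_along(AA20), sep = "\t")), g)
  tab <- read_property_tsv(g)
  expect_equal(unname(tab["R"]), 2)
})
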