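# Discovery fixtures: positives carry an anchor residue and a co-occurring
# partner implanted by the synthetic generator at a known penetrance.
discovery_data <- function(seed, penetrance = 0.9, n = 9) {
  # the partner signal is split over two residues so the anchor position
  # carries the strongest single-residue enrichment
  imp <- data.frame(anchor_pos = 3L, anchor_res = "W", partner_pos = 9L,
                    partner_set = "E,T", penetrance = penetrance)
  d <- generate_glycodata(sim_config(n_proteins = 25, n_positives = 40,
                                     n_negatives = 400,
                                     implanted_saaps = imp, seed = seed))
  extract_fragments(d$records, d$sites, n)
}

test_that("the implanted anchor position and residue are selected", {
  frs <- discovery_data(seed = 101, penetrance = 0.9)
  a <- select_anchor(frs)
  expect_equal(a$position, 3L)
  expect_equal(a$residues[1], "W")
  expect_lte(length(a$residues), 3L)

  # null data: the anchor is unstable but always a valid in-range position
  set.seed(5)
  null_frs <- make_fragments(replicate(60, random_window(4)),
                             sample(rep(c("positive", "negative"), c(20, 40))))
  a0 <- select_anchor(null_frs)
  expect_true(a0$position %in% setdiff(-4:4, 0))
})

test_that("enumerated pair F-scores match an independent recomputation", {
  frs <- discovery_data(seed = 77, penetrance = 0.9)
  anchor <- select_anchor(frs)
  cands <- enumerate_pairs(frs, anchor, f_min = 0.10)
  expect_gt(nrow(cands), 0)
  n <- (nchar(frs$window[1]) - 1) %/% 2
  chars <- do.call(rbind, strsplit(frs$window, ""))
  is_pos <- frs$label == "positive"
  for (k in seq_len(nrow(cands))) {
    partners <- strsplit(cands$partner_set[k], ",")[[1]]
    ind <- as.numeric(chars[, cands$anchor_pos[k] + n + 1] ==
                        cands$anchor_res[k] &
                      chars[, cands$partner_pos[k] + n + 1] %in% partners)
    expect_equal(cands$fscore[k], fscore_oracle(ind[is_pos], ind[!is_pos]),
                 tolerance = 1e-12)
  }
  # the implanted pair outranks every non-implanted candidate
  expect_equal(cands$anchor_pos[1], 3L)
  expect_equal(cands$anchor_res[1], "W")
  expect_equal(cands$partner_pos[1], 9L)
  expect_true("E" %in% strsplit(cands$partner_set[1], ",")[[1]])
})

test_that("two-residue partner merges are kept only when they beat both singletons", {
  # construct positives where the anchor co-occurs with E or T at +4
  set.seed(13)
  pos <- c(replicate(15, random_window(4, force = c("3" = "W", "4" = "E"),
                                       exclude = c("W", "E", "T"))),
           replicate(15, random_window(4, force = c("3" = "W", "4" = "T"),
                                       exclude = c("W", "E", "T"))))
  neg <- replicate(90, random_window(4, exclude = c("W", "E", "T")))
  frs <- make_fragments(c(pos, neg),
                        rep(c("positive", "negative"), c(30, 90)))
  anchor <- list(position = 3L, residues = "W", fscore = Inf, tie = FALSE)
  cands <- enumerate_pairs(frs, anchor, f_min = 0.10)
  merged <- cands[grepl(",", cands$partner_set) & cands$partner_pos == 4, ]
  expect_equal(nrow(merged), 1L)
  expect_setequal(strsplit(merged$partner_set, ",")[[1]], c("E", "T"))
  singles <- cands[cands$partner_pos == 4 &
                     cands$partner_set %in% c("E", "T"), ]
  expect_true(all(merged$fscore > singles$fscore))
})

test_that("forward selection keeps a separating pair and stops at ties", {
  set.seed(5)
  n <- 4
  mkwin <- function(k, kind) {
    replicate(k, {
      w <- random_window(n, exclude = c("W", "F"))
      ch <- strsplit(w, "")[[1]]
      if (kind == "pos") {
        ch[n + 1 + 2] <- "W"
        ch[n + 1 + 4] <- "F"
      } else if (runif(1) < 0.5) ch[n + 1 + 2] <- "W" else ch[n + 1 + 4] <- "F"
      paste(ch, collapse = "")
    })
  }
  frs <- data.frame(protein_id = rep(sprintf("P%02d", 1:20), each = 8),
                    position = rep(seq(20, 160, by = 20), 20), center = "S",
                    window = NA_character_,
                    label = sample(rep(c("positive", "negative"), c(40, 120))),
                    stringsAsFactors = FALSE)
  frs$window[frs$label == "positive"] <- mkwin(40, "pos")
  frs$window[frs$label == "negative"] <- mkwin(120, "neg")
  frs$center <- substr(frs$window, n + 1, n + 1)
  sep <- data.frame(anchor_pos = 2L, anchor_res = "W", partner_pos = 4L,
                    partner_set = "F", fscore = Inf)
  noise <- data.frame(anchor_pos = c(-3L, 1L, -1L), anchor_res = c("A", "G", "L"),
                      partner_pos = c(3L, -2L, 2L),
                      partner_set = c("V", "K", "D"),
                      fscore = c(0.01, 0.005, 0.002))
  seqs <- setNames(rep(strrep("A", 200), 20), sprintf("P%02d", 1:20))
  cfg <- run_config(window_n = n, seed = 3, homology = "none")
  trainer <- cv_bacc_trainer(seqs, cfg)
  sel <- rank_and_select(rbind(sep, noise), frs, trainer, max_pairs = 4)
  expect_equal(nrow(sel$saaps), 1L)
  expect_equal(sel$saaps$anchor_res, "W")
  expect_equal(max(sel$curve$bacc), sel$best_bacc)
  expect_equal(sel$curve$bacc[2], 1)

  # deterministic given data, config and fold seed
  sel2 <- rank_and_select(rbind(sep, noise), frs, trainer, max_pairs = 4)
  expect_identical(sel$curve, sel2$curve)
  expect_error(rank_and_select(sep, frs, trainer, max_pairs = 0), "max_pairs")
})

test_that("permuted labels leave no candidate above the permutation null", {
  frs <- discovery_data(seed = 55, penetrance = 0.9, n = 4)
  set.seed(200)
  labels <- frs$label
  frs$label <- sample(labels)
  anchor <- select_anchor(frs)
  observed <- max(enumerate_pairs(frs, anchor, f_min = 0.10)$fscore)
  null_max <- replicate(200, {
    f <- frs
    f$label <- sample(labels)
    a <- select_anchor(f)
    cands <- enumerate_pairs(f, a, f_min = 0.10)
    if (nrow(cands) == 0) 0 else max(cands$fscore)
  })
  expect_lte(observed, quantile(null_max, 0.99))
})
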