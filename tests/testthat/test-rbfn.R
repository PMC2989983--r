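test_that("the Gaussian kernel has its closed-form values and monotonicity", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, sigma = 5), 1)
  # distance sigma * sqrt(2) gives exp(-1)
  sigma <- 2.5
  c2 <- x + c(sigma * sqrt(2), 0, 0)
  expect_equal(rbf_kernel(x, c2, sigma), exp(-1))
  # monotone decrease with distance
  d <- seq(0, 10, by = 0.5)
  vals <- vapply(d, function(dd) rbf_kernel(c(dd, 0), c(0, 0), 3), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(rbf_kernel(1:3, 1:4, 1), "dimension")
})

test_that("a two-point network reproduces the hand-solved 2x2 system", {
  X <- rbind(c(0, 0), c(3, 4))  # distance 5
  model <- rbfn_fit(X, c("positive", "negative"), sigma = 5)
  e <- exp(-25 / 50)
  # closed form: W = Phi^{-1} Y with Phi = [[1, e], [e, 1]]
  W_oracle <- (1 / (1 - e^2)) * rbind(c(1, -e), c(-e, 1)) %*% diag(2)
  expect_equal(unname(model$weights), unname(W_oracle), tolerance = 1e-10)
  s <- predict_scores(model, X)
  expect_equal(unname(s), diag(2), tolerance = 1e-6)
  expect_equal(predict_class(model, X), c("positive", "negative"))
  # equidistant query point scores the two classes equally
  mid <- c(1.5, 2)
  sm <- predict_scores(model, mid)
  expect_equal(unname(sm[1, "positive"]), unname(sm[1, "negative"]),
               tolerance = 1e-12)
})

test_that("lambda = 0 interpolates one-hot targets on distinct points", {
  set.seed(17)
  for (k in c(10, 50)) {
    X <- matrix(rnorm(k * 6), nrow = k)
    labels <- sample(rep(c("positive", "negative"), length.out = k))
    model <- rbfn_fit(X, labels, sigma = 5)
    Y <- cbind(as.numeric(labels == "positive"),
               as.numeric(labels == "negative"))
    expect_lt(max(abs(predict_scores(model, X) - Y)), 1e-6)
    expect_equal(predict_class(model, X), labels)
  }
})

test_that("predictions are invariant to training-instance order", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4), nrow = 30)
  labels <- sample(rep(c("positive", "negative"), 15))
  q <- matrix(rnorm(5 * 4), nrow = 5)
  m1 <- rbfn_fit(X, labels, sigma = 5)
  perm <- sample(30)
  m2 <- rbfn_fit(X[perm, ], labels[perm], sigma = 5)
  expect_equal(predict_scores(m1, q), predict_scores(m2, q),
               tolerance = 1e-9)
})

test_that("training residual is nondecreasing in the ridge penalty", {
  set.seed(29)
  X <- matrix(rnorm(40 * 5), nrow = 40)
  labels <- sample(rep(c("positive", "negative"), 20))
  Y <- cbind(as.numeric(labels == "positive"),
             as.numeric(labels == "negative"))
  rss <- vapply(c(0, 1e-4, 1e-2, 1, 100), function(l) {
    m <- rbfn_fit(X, labels, sigma = 5, ridge_lambda = l)
    sum((predict_scores(m, X) - Y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8))
})

test_that("conflicting duplicate points trigger the logged ridge fallback", {
  X <- rbind(c(1, 1), c(1, 1), c(0, 5))
  expect_warning(
    model <- rbfn_fit(X, c("positive", "negative", "negative"), sigma = 5),
    "singular")
  expect_equal(model$ridge_lambda, 1e-8)
  expect_true(all(is.finite(model$weights)))
})

test_that("decision thresholds trade sensitivity for specificity", {
  set.seed(31)
  X <- matrix(rnorm(20 * 3), nrow = 20)
  labels <- sample(rep(c("positive", "negative"), 10))
  model <- rbfn_fit(X, labels, sigma = 5)
  q <- matrix(rnorm(8 * 3), nrow = 8)
  expect_true(all(predict_class(model, q, threshold = Inf) == "negative"))
  expect_true(all(predict_class(model, q, threshold = -Inf) == "positive"))
  expect_error(predict_scores(model, matrix(0, 1, 7)), "schema length")
})

test_that("model archives round-trip with a format version check", {
  set.seed(37)
  X <- matrix(rnorm(12 * 4), nrow = 12)
  labels <- sample(rep(c("positive", "negative"), 6))
  saaps <- data.frame(anchor_pos = 3L, anchor_res = "W", partner_pos = 9L,
                      partner_set = "E,T", fscore = 0.5,
                      stringsAsFactors = FALSE)
  model <- rbfn_fit(X, labels, sigma = 5,
                    schema = list(n = 14, saaps = saaps))
  f <- withr::local_tempfile(fileext = ".json")
  write_rbfn(model, f)
  back <- read_rbfn(f)
  q <- matrix(rnorm(3 * 4), nrow = 3)
  # JSON serializes doubles at 15 significant digits
  expect_equal(predict_scores(back, q), predict_scores(model, q),
               tolerance = 1e-8)
  expect_equal(back$schema$saaps$partner_set, "E,T")

  # version mismatch is refused with both version strings visible
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$format_version <- "glycorbf-rbfn-0"
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(read_rbfn(f), "glycorbf-rbfn-1")
})
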