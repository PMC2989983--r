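RBFN_FORMAT_VERSION <- "glycorbf-rbfn-1"

#' Gaussian radial basis kernel
#'
#' \eqn{\phi(x, c) = \exp(-\|x - c\|^2 / (2\sigma^2))}. The 2-sigma-squared
#' denominator convention is used throughout the package; this function is
#' the single place it is defined.
#'
#' @param x,center Numeric vectors of equal length.
#' @param sigma Bandwidth, > 0.
#' @return A number in (0, 1].
#' @export
rbf_kernel <- function(x, center, sigma) {
  if (length(x) != length(center)) stop("dimension mismatch")
  stopifnot(sigma > 0)
  exp(-sum((x - center)^2) / (2 * sigma^2))
}

# k x m kernel matrix between the rows of X and the rows of C.
kernel_matrix <- function(X, C, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fit a radial basis function network classifier
#'
#' Every training instance becomes a kernel center (k = number of
#' instances) with one fixed bandwidth. The two output nodes (positive,
#' negative) are linear combinations of the k activations; their weights
#' solve the regularized normal equations \eqn{(\Phi^T \Phi + \lambda I) W
#' = \Phi^T Y} with one-hot class targets Y. With `ridge_lambda = 0` and
#' distinct training points the network interpolates the targets exactly.
#'
#' @param X Numeric feature matrix, one row per training instance.
#' @param labels Character vector of "positive"/"negative", one per row.
#' @param sigma Kernel bandwidth (default 5).
#' @param ridge_lambda Ridge regularizer (default 0). If the
#'   interpolation system is singular (e.g. duplicate vectors with
#'   conflicting labels) a fallback of 1e-8 is applied with a warning.
#' @param schema Optional feature schema, a list with `n` (flank width)
#'   and `saaps` (SAAP table or NULL); stored for prediction-time checks.
#' @return An object of class `rbfn_model`.
#' @export
rbfn_fit <- function(X, labels, sigma = 5, ridge_lambda = 0, schema = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, sigma > 0, ridge_lambda >= 0)
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  if (length(labels) != nrow(X)) stop("one label per training row required")
  if (!any(labels == "positive") || !any(labels == "negative")) {
    stop("at least one instance of each class is required")
  }
  if (!all(is.finite(X))) stop("non-finite feature values")
  Y <- cbind(positive = as.numeric(labels == "positive"),
             negative = as.numeric(labels == "negative"))
  Phi <- kernel_matrix(X, X, sigma)
  W <- solve_weights(Phi, Y, ridge_lambda)
  structure(list(centers = X, sigma = sigma, weights = W$weights,
                 ridge_lambda = W$lambda, schema = schema,
                 format_version = RBFN_FORMAT_VERSION),
            class = "rbfn_model")
}

solve_weights <- function(Phi, Y, lambda) {
  if (lambda == 0) {
    # Phi is square (all instances are centers); the least-squares solution
    # of the unregularized normal equations is the interpolant Phi W = Y.
    W <- tryCatch(solve(Phi, Y), error = function(e) NULL)
    if (!is.null(W)) return(list(weights = W, lambda = 0))
    warning("kernel matrix is singular; refitting with ridge_lambda = 1e-8",
            call. = FALSE)
    lambda <- 1e-8
  }
  A <- crossprod(Phi) + diag(lambda, nrow(Phi))
  list(weights = solve(A, crossprod(Phi, Y)), lambda = lambda)
}

#' Raw output-node scores of an RBF network
#'
#' @param model An `rbfn_model`.
#' @param x A numeric vector, or a matrix with one row per instance.
#' @return Matrix with columns `positive` and `negative`, one row per
#'   instance.
#' @export
predict_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$centers)) {
    stop(sprintf("feature length %d does not match model schema length %d",
                 ncol(x), ncol(model$centers)))
  }
  kernel_matrix(as.matrix(x), model$centers, model$sigma) %*% model$weights
}

#' Class decision of an RBF network
#'
#' Positive iff `score_positive - score_negative > threshold`. The
#' threshold (default 0) trades sensitivity against specificity.
#'
#' @inheritParams predict_scores
#' @param threshold Decision threshold on the score margin.
#' @return Character vector of "positive"/"negative".
#' @export
predict_class <- function(model, x, threshold = 0) {
  s <- predict_scores(model, x)
  ifelse(s[, "positive"] - s[, "negative"] > threshold, "positive", "negative")
}

#' Serialize an RBF network model to a portable JSON archive
#' @param model An `rbfn_model`.
#' @param path Output path.
#' @export
write_rbfn <- function(model, path) {
  obj <- list(format_version = model$format_version,
              sigma = model$sigma,
              ridge_lambda = model$ridge_lambda,
              schema = if (is.null(model$schema)) NULL else list(
                n = model$schema$n,
                saaps = model$schema$saaps),
              centers = model$centers,
              weights = model$weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Read a serialized RBF network model
#' @param path Path written by [write_rbfn()].
#' @return An `rbfn_model`.
#' @export
read_rbfn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, RBFN_FORMAT_VERSION)) {
    stop(sprintf("model archive version '%s' does not match supported '%s'",
                 obj$format_version, RBFN_FORMAT_VERSION))
  }
  W <- as.matrix(obj$weights)
  colnames(W) <- c("positive", "negative")
  schema <- NULL
  if (!is.null(obj$schema)) {
    saaps <- obj$schema$saaps
    if (!is.null(saaps)) saaps <- as.data.frame(saaps)
    schema <- list(n = obj$schema$n, saaps = saaps)
  }
  structure(list(centers = as.matrix(obj$centers), sigma = obj$sigma,
                 weights = W, ridge_lambda = obj$ridge_lambda,
                 schema = schema, format_version = obj$format_version),
            class = "rbfn_model")
}

#' @export
print.rbfn_model <- function(x, ...) {
  cat(sprintf("RBF network: %d centers, %d features, sigma = %g, lambda = %g\n",
              nrow(x$centers), ncol(x$centers), x$sigma, x$ridge_lambda))
  if (!is.null(x$schema)) {
    cat(sprintf("schema: window n = %d, %d SAAP features\n", x$schema$n,
                if (is.null(x$schema$saaps)) 0L else nrow(x$schema$saaps)))
  }
  invisible(x)
}
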