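## Binary Gaussian-process classification with an isotropic RBF kernel,
## fitted by the Laplace approximation with a logistic link. Kernel
## hyperparameters (length-scale, signal variance) are optimized by the
## approximate log marginal likelihood. Features are z-scored with training
## statistics before entering the kernel (the feature space mixes nm, nN and
## percent scales; an unstandardized RBF distance would be dominated by one
## unit). The Newton iteration of the Laplace mode search is capped at
## max_iter (default 1000).

#' @noRd
rbf_kernel <- function(X1, X2, ell, sf2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  sf2 * exp(-d2 / (2 * ell^2))
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

## Laplace mode search (stable parametrization); y in {0,1}
#' @noRd
gp_laplace <- function(K, y, max_iter, tol = 1e-10) {
  n <- length(y)
  f <- numeric(n)
  obj_old <- -Inf
  iters <- 0L
  repeat {
    p <- sigmoid(f)
    W <- p * (1 - p)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    b <- W * f + (y - p)
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f <- drop(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(stats::plogis((2 * y - 1) * f, log.p = TRUE))
    iters <- iters + 1L
    if (abs(obj - obj_old) < tol || iters >= max_iter) break
    obj_old <- obj
  }
  p <- sigmoid(f)
  sW <- sqrt(p * (1 - p))
  L <- chol(diag(n) + (sW %o% sW) * K)
  lml <- -0.5 * sum(a * f) +
    sum(stats::plogis((2 * y - 1) * f, log.p = TRUE)) -
    sum(log(diag(L)))
  list(f = f, a = a, grad = y - p, sW = sW, L = L, lml = lml, iters = iters)
}

#' Train the Gaussian-process probability classifier
#'
#' Fits a binary GP classifier (positive class \code{"high"}) on the given
#' feature subset of a labeled feature table. Features are standardized by
#' training mean/sd; the isotropic RBF kernel's length-scale and signal
#' variance are optimized by maximizing the Laplace-approximate log marginal
#' likelihood (L-BFGS-B over log parameters, initialized at the median
#' pairwise distance and unit variance); the Newton mode search is capped at
#' \code{max_iter} iterations.
#'
#' @param table a labeled \code{feature_table}.
#' @param features character vector of feature keys to use (e.g. from
#'   \code{\link{select_top_k}}).
#' @param max_iter iteration cap for the Laplace Newton mode search
#'   (default 1000).
#' @param seed integer seed (kept for interface uniformity; the fit itself
#'   is deterministic).
#' @return an object of class \code{gp_classifier} with, among others,
#'   \code{selected_features}, the standardization statistics, kernel
#'   hyperparameters and fitted training probabilities.
#' @export
train_gp <- function(table, features, max_iter = 1000L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(features) >= 1L)
  miss <- setdiff(features, colnames(table$matrix))
  if (length(miss))
    stop_afm("feature(s) absent from table: ", paste(miss, collapse = ", "),
             class = "afm_feature_error")
  y_lab <- table$label
  if (!all(y_lab %in% c("low", "high")) || length(unique(y_lab)) < 2L)
    stop_afm("degenerate labels: need both 'low' and 'high'",
             class = "afm_label_error")
  X <- table$matrix[, features, drop = FALSE]
  if (!all(is.finite(X)))
    stop_afm("non-finite feature values", class = "afm_feature_error")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv <= 0))
    stop_afm("zero-variance selected feature(s): ",
             paste(features[sdv <= 0], collapse = ", "),
             class = "afm_feature_error")
  Xs <- scale(X, center = mu, scale = sdv)
  y <- as.numeric(y_lab == "high")
  set.seed(seed)

  d <- stats::dist(Xs)
  ell0 <- stats::median(d)
  if (!is.finite(ell0) || ell0 <= 0) ell0 <- 1
  jitter <- 1e-8
  nll <- function(theta) {
    K <- rbf_kernel(Xs, Xs, exp(theta[1]), exp(2 * theta[2]))
    diag(K) <- diag(K) + jitter
    fit <- gp_laplace(K, y, max_iter)
    -fit$lml
  }
  ## signal sd bounded in [e^-2, e^2]: the Laplace evidence degrades for
  ## very large signal variance (saturated likelihood, W -> 0) and would
  ## otherwise run to arbitrarily large amplitudes on separable data
  opt <- stats::optim(c(log(ell0), 0), nll, method = "L-BFGS-B",
                      lower = c(log(ell0) - 4, -2),
                      upper = c(log(ell0) + 4, 2),
                      control = list(maxit = 50L, factr = 1e9))
  ell <- exp(opt$par[1]); sf2 <- exp(2 * opt$par[2])
  K <- rbf_kernel(Xs, Xs, ell, sf2)
  diag(K) <- diag(K) + jitter
  fit <- gp_laplace(K, y, max_iter)

  clf <- structure(list(
    selected_features = features,
    standardization = list(mean = mu, sd = sdv),
    ell = ell, sf2 = sf2, jitter = jitter,
    Xs = Xs, grad = fit$grad, sW = fit$sW, L = fit$L,
    log_marginal = fit$lml, newton_iters = fit$iters,
    max_iter = max_iter, positive_class = "high",
    train_labels = y_lab, train_cell_id = table$cell_id),
    class = "gp_classifier")
  clf$fitted <- predict_gp_matrix(clf, Xs, standardized = TRUE)
  clf
}

## batch prediction; X rows are inputs. MacKay's logistic-probit
## approximation integrates the logistic likelihood over the latent
## Gaussian: p = sigmoid(mu / sqrt(1 + pi * s2 / 8)).
#' @noRd
predict_gp_matrix <- function(clf, X, standardized = FALSE) {
  if (!standardized)
    X <- scale(X, center = clf$standardization$mean,
               scale = clf$standardization$sd)
  Ks <- rbf_kernel(clf$Xs, X, clf$ell, clf$sf2)
  mu <- drop(crossprod(Ks, clf$grad))
  V <- forwardsolve(t(clf$L), clf$sW * Ks)
  s2 <- pmax(clf$sf2 + clf$jitter - colSums(V^2), 0)
  sigmoid(mu / sqrt(1 + pi * s2 / 8))
}

#' Predict the probability of high aggressiveness
#'
#' @param clf a \code{gp_classifier}.
#' @param vector a named numeric vector (or a named list) covering all
#'   selected features, e.g. a row of a feature table or a
#'   \code{surface_parameter_vector} collection keyed like the classifier's
#'   features.
#' @return P(label = high) in [0, 1]; the low-class probability is its
#'   complement.
#' @export
predict_probability <- function(clf, vector) {
  stopifnot(inherits(clf, "gp_classifier"))
  v <- unlist(vector)
  miss <- setdiff(clf$selected_features, names(v))
  if (length(miss))
    stop_afm("missing feature key(s): ", paste(miss, collapse = ", "),
             class = "afm_feature_error")
  x <- matrix(v[clf$selected_features], nrow = 1,
              dimnames = list(NULL, clf$selected_features))
  unname(predict_gp_matrix(clf, x))
}

#' @export
#' @rdname predict_probability
#' @param object,newdata,... standard predict-method arguments;
#'   \code{newdata} is a \code{feature_table} or a numeric matrix with
#'   feature-key column names.
predict.gp_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$matrix else newdata
  if (is.null(colnames(X)))
    stop_afm("newdata must carry feature-key column names",
             class = "afm_feature_error")
  miss <- setdiff(object$selected_features, colnames(X))
  if (length(miss))
    stop_afm("missing feature key(s): ", paste(miss, collapse = ", "),
             class = "afm_feature_error")
  predict_gp_matrix(object, X[, object$selected_features, drop = FALSE])
}

#' @export
print.gp_classifier <- function(x, ...) {
  cat("<gp_classifier> binary GP (Laplace, logistic link), RBF kernel\n")
  cat(sprintf("  %d training cells, %d features; length-scale %.3g, signal sd %.3g\n",
              nrow(x$Xs), length(x$selected_features), x$ell, sqrt(x$sf2)))
  cat(sprintf("  log marginal likelihood %.3f (Newton iterations %d, cap %d)\n",
              x$log_marginal, x$newton_iters, x$max_iter))
  invisible(x)
}

#' @export
summary.gp_classifier <- function(object, ...) {
  print(object)
  acc <- mean((object$fitted >= 0.5) == (object$train_labels == "high"))
  cat(sprintf("  training accuracy at 0.5 threshold: %.3f\n", acc))
  cat("  selected features:\n")
  cat(paste0("    ", object$selected_features, collapse = "\n"), "\n")
  invisible(object)
}

#' Serialize a trained GP classifier to a JSON bundle
#'
#' Writes everything prediction needs — selected features, standardization
#' statistics, kernel hyperparameters and the Laplace latent state — as one
#' JSON file at full double precision.
#'
#' @param clf a \code{gp_classifier}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_gp_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "gp_classifier"))
  bundle <- list(
    format = "afmtexture_gp_classifier", version = 1L,
    selected_features = clf$selected_features,
    standardization = clf$standardization,
    ell = clf$ell, sf2 = clf$sf2, jitter = clf$jitter,
    Xs = clf$Xs, grad = clf$grad, sW = clf$sW, L = clf$L,
    log_marginal = clf$log_marginal, newton_iters = clf$newton_iters,
    max_iter = clf$max_iter, positive_class = clf$positive_class,
    train_labels = clf$train_labels, train_cell_id = clf$train_cell_id,
    fitted = clf$fitted)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a GP classifier saved by \code{save_gp_classifier}
#'
#' @param path bundle file.
#' @return a \code{gp_classifier} whose predictions match the saved model.
#' @export
load_gp_classifier <- function(path) {
  b <- tryCatch(suppressWarnings(jsonlite::read_json(path, simplifyVector = TRUE)),
                error = function(e) stop_afm("cannot read classifier bundle ",
                                             path, ": ", conditionMessage(e),
                                             class = "afm_format_error"))
  if (!identical(b$format, "afmtexture_gp_classifier"))
    stop_afm(path, " is not a GP classifier bundle",
             class = "afm_format_error")
  as_mat <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- b$selected_features
    m
  }
  clf <- list(
    selected_features = b$selected_features,
    standardization = list(
      mean = stats::setNames(b$standardization$mean, b$selected_features),
      sd = stats::setNames(b$standardization$sd, b$selected_features)),
    ell = b$ell, sf2 = b$sf2, jitter = b$jitter,
    Xs = as_mat(b$Xs), grad = b$grad, sW = b$sW, L = as.matrix(b$L),
    log_marginal = b$log_marginal, newton_iters = b$newton_iters,
    max_iter = b$max_iter, positive_class = b$positive_class,
    train_labels = b$train_labels, train_cell_id = b$train_cell_id,
    fitted = b$fitted)
  dimnames(clf$L) <- NULL
  class(clf) <- "gp_classifier"
  clf
}

#' Stratified random train/test split
#'
#' Splits a labeled feature table into disjoint train/test subsets covering
#' it, stratified by class (train share within one row of
#' \code{train_fraction} per class) and reproducible from the seed. Each
#' class keeps at least one row on each side.
#'
#' @param table a labeled \code{feature_table} with at least two rows per
#'   class.
#' @param spec list with \code{train_fraction} in (0, 1), optional
#'   \code{stratified} (default TRUE) and \code{seed}.
#' @return list with \code{train} and \code{test} feature tables.
#' @export
split_train_test <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"))
  frac <- spec$train_fraction
  stopifnot(is.numeric(frac), frac > 0, frac < 1)
  y <- table$label
  if (!all(y %in% c("low", "high")) || length(unique(y)) < 2L ||
      min(table(y)) < 2L)
    stop_afm("split requires >= 2 labeled rows per class",
             class = "afm_split_error")
  set.seed(spec$seed %||% 1L)
  idx_train <- integer(0)
  if (isFALSE(spec$stratified)) {
    n <- length(y)
    k <- min(max(floor(n * frac + 0.5), 1L), n - 1L)
    idx_train <- sample(n, k)
    if (length(unique(y[idx_train])) < 2L || length(unique(y[-idx_train])) < 2L)
      stop_afm("unstratified split left a class empty; use stratified = TRUE",
               class = "afm_split_error")
  } else {
    for (cls in c("low", "high")) {
      rows <- which(y == cls)
      k <- min(max(floor(length(rows) * frac + 0.5), 1L), length(rows) - 1L)
      idx_train <- c(idx_train, sample(rows, k))
    }
    idx_train <- sort(idx_train)
  }
  list(train = feature_table_rows(table, idx_train),
       test = feature_table_rows(table, setdiff(seq_along(y), idx_train)))
}

#' Classify cells with a trained GP classifier
#'
#' Applies the classifier to every row of a feature table; a cell is called
#' \code{high} iff its probability is >= \code{threshold} (ties go to high,
#' the deterministic convention used throughout).
#'
#' @param clf a \code{gp_classifier}.
#' @param table a \code{feature_table} (labels optional).
#' @param threshold decision threshold on P(high), default 0.5.
#' @return a data.frame of class \code{cell_classification} with columns
#'   \code{cell_id}, \code{label}, \code{probability}, \code{predicted};
#'   attribute \code{accuracy} is the fraction of correct labels when any
#'   rows are labeled (NA otherwise).
#' @export
classify_cells <- function(clf, table, threshold = 0.5) {
  stopifnot(inherits(clf, "gp_classifier"), inherits(table, "feature_table"))
  p <- predict(clf, table)
  pred <- ifelse(p >= threshold, "high", "low")
  lab <- table$label
  labeled <- lab %in% c("low", "high")
  acc <- if (any(labeled)) mean(pred[labeled] == lab[labeled]) else NA_real_
  structure(data.frame(cell_id = table$cell_id, label = lab,
                       probability = p, predicted = pred,
                       stringsAsFactors = FALSE),
            class = c("cell_classification", "data.frame"),
            accuracy = acc, threshold = threshold)
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("<cell_classification> %d cells, threshold %.2f", nrow(x),
              attr(x, "threshold")))
  if (!is.na(attr(x, "accuracy")))
    cat(sprintf(", accuracy %.3f", attr(x, "accuracy")))
  cat("\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
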