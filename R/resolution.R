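## Step 2: moving-average blur scan. Blurring at growing kernel sizes and
## re-running the whole Step-1 pipeline locates the spatial scale that
## carries the class signal; the zoom (sliding-window) size is the largest
## kernel whose accuracy stays at >= X of the baseline, floored at the
## minimum window needed to compute surface parameters (32 px).

## edge-truncated box mean, window anchored at the pixel's top-left:
## out[i, j] = mean(z[i:(i+k-1), j:(j+k-1)] clipped to the image)
#' @noRd
box_blur <- function(z, k) {
  if (k == 1L) return(z)
  R <- nrow(z); C <- ncol(z)
  ## integral image: S[i+1, j+1] = sum(z[1:i, 1:j])
  S <- matrix(0, R + 1L, C + 1L)
  S[-1L, -1L] <- t(apply(apply(z, 2L, cumsum), 1L, cumsum))
  i2 <- pmin(seq_len(R) + k - 1L, R); j2 <- pmin(seq_len(C) + k - 1L, C)
  i1 <- seq_len(R); j1 <- seq_len(C)
  tot <- S[i2 + 1L, j2 + 1L] - S[i1, j2 + 1L] - S[i2 + 1L, j1] + S[i1, j1]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  tot / cnt
}

#' Moving-average blur of a channel image
#'
#' Each output pixel is the mean of the k x k neighborhood anchored at the
#' pixel's top-left corner, truncated at the image edges (mean over the
#' in-bounds part); shape is preserved and kernel 1 is the identity.
#'
#' @param image a \code{\link{channel_image}}.
#' @param kernel_px kernel side in pixels, 1 <= kernel_px <= min(rows, cols).
#' @return the blurred \code{\link{channel_image}}.
#' @export
blur_average <- function(image, kernel_px) {
  stopifnot(inherits(image, "channel_image"))
  if (!is_count(kernel_px) || kernel_px < 1L)
    stop_afm("kernel_px must be a positive integer", class = "afm_scale_error")
  if (kernel_px > min(dim(image$values)))
    stop_afm("kernel ", kernel_px, " exceeds image size ",
             paste(dim(image$values), collapse = " x "),
             class = "afm_scale_error")
  if (kernel_px == 1L) return(image)
  image$values <- box_blur(image$values, as.integer(kernel_px))
  image
}

#' @noRd
blur_cell <- function(cell, kernel_px) {
  cell$channels <- lapply(cell$channels, blur_average, kernel_px = kernel_px)
  cell
}

#' Classification accuracy as a function of blur kernel size
#'
#' For each kernel size, every channel of every cell is moving-average
#' blurred and the full Step-1 pipeline (feature table, Gini ranking, top-k
#' selection, stratified split, GP training, test accuracy) is re-run with
#' the configured seeds. With several seeds the accuracy at each kernel is
#' the mean over seed replicates (ranking/split/training re-seeded; the
#' blurred feature table is computed once per kernel).
#'
#' @param cells list of labeled \code{\link{cell_record}}s.
#' @param kernels strictly increasing integer kernel sizes; include 1 for
#'   the unblurred baseline.
#' @param config a \code{\link{run_config}}.
#' @return a data.frame of class \code{blur_accuracy_curve} with columns
#'   \code{kernel_px}, \code{accuracy}.
#' @export
accuracy_vs_blur <- function(cells, kernels, config = run_config()) {
  stopifnot(length(kernels) >= 1L, all(diff(kernels) > 0),
            all(kernels >= 1L))
  acc <- vapply(kernels, function(k) {
    blurred <- if (k == 1L) cells else lapply(cells, blur_cell, kernel_px = k)
    res <- tryCatch(
      step1_accuracy(blurred, config),
      error = function(e) stop_afm("pipeline failed at kernel ", k, ": ",
                                   conditionMessage(e),
                                   class = "afm_pipeline_error"))
    res
  }, numeric(1))
  structure(data.frame(kernel_px = as.integer(kernels), accuracy = acc),
            class = c("blur_accuracy_curve", "data.frame"))
}

## mean test accuracy of the Step-1 pipeline over the configured seeds
#' @noRd
step1_accuracy <- function(cells, config, table = NULL) {
  if (is.null(table))
    table <- build_feature_table(cells, config$channel_kinds, config$registry)
  mean(vapply(config$seeds, function(s) {
    ranking <- rank_gini_importance(table, n_trees = config$n_trees, seed = s)
    feats <- select_top_k(ranking, config$k)
    sp <- split_train_test(table, list(train_fraction = config$train_fraction,
                                       stratified = TRUE, seed = s))
    clf <- train_gp(sp$train, feats, max_iter = config$max_iter, seed = s)
    attr(classify_cells(clf, sp$test, config$threshold), "accuracy")
  }, numeric(1)))
}

#' Select the sliding-window (zoom) size from a blur-accuracy curve
#'
#' The zoom is the largest kernel whose accuracy is still at least
#' \code{threshold_X} times the unblurred baseline (relative mode, default)
#' or at least \code{threshold_X} absolute accuracy (absolute mode), floored
#' at \code{min_zoom_px}: below that, too few pixels remain to compute the
#' surface parameters.
#'
#' @param curve a \code{blur_accuracy_curve}; the relative mode requires a
#'   kernel-1 baseline point.
#' @param threshold_X accuracy-retention threshold X (default 0.80).
#' @param min_zoom_px window floor in pixels (default 32).
#' @param mode \code{"relative"} (to baseline) or \code{"absolute"}.
#' @return list of class \code{zoom_selection} with \code{zoom_px},
#'   \code{threshold_X}, \code{min_zoom_px} and a \code{rationale} string.
#' @export
select_zoom <- function(curve, threshold_X = 0.8, min_zoom_px = 32L,
                        mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "blur_accuracy_curve"), nrow(curve) >= 1L,
            threshold_X > 0, threshold_X <= 1)
  if (mode == "relative") {
    if (!any(curve$kernel_px == 1L))
      stop_afm("relative mode needs the kernel-1 baseline in the curve",
               class = "afm_scale_error")
    cutoff <- threshold_X * curve$accuracy[curve$kernel_px == 1L]
  } else cutoff <- threshold_X
  ok <- curve$kernel_px[curve$accuracy >= cutoff]
  raw <- if (length(ok)) max(ok) else min(curve$kernel_px)
  zoom <- max(raw, min_zoom_px)
  rationale <- sprintf(
    "largest kernel with accuracy >= %.3f (%s X = %.2f) is %d px; floor %d px => zoom %d px",
    cutoff, mode, threshold_X, raw, min_zoom_px, zoom)
  structure(list(zoom_px = as.integer(zoom), threshold_X = threshold_X,
                 min_zoom_px = as.integer(min_zoom_px), mode = mode,
                 rationale = rationale),
            class = "zoom_selection")
}

#' @export
print.zoom_selection <- function(x, ...) {
  cat("<zoom_selection>", x$rationale, "\n")
  invisible(x)
}

#' @export
plot.blur_accuracy_curve <- function(x, ...) {
  graphics::plot(x$kernel_px, x$accuracy, type = "b", log = "x",
                 xlab = "averaging kernel size (px)",
                 ylab = "classification accuracy",
                 ylim = c(0.4, 1), pch = 19, ...)
  graphics::abline(h = 0.8 * x$accuracy[x$kernel_px == 1L][1L], lty = 2)
  invisible(x)
}
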