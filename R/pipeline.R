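## End-to-end orchestration of the three workflow steps with one declarative
## configuration. Defaults follow the study's stated settings: top-10
## features for a single channel / top-20 for the channel combination, GP
## iteration cap 1000, accuracy-retention threshold X = 0.8, window 32 px,
## stride 1, decision threshold 0.5.

#' Pipeline run configuration
#'
#' @param channel_kinds channels the classifier uses (default: height plus
#'   the three Ringing-mode channels, the combined mode).
#' @param registry a \code{\link{parameter_registry}} subset.
#' @param k number of top-ranked features; default
#'   \code{\link{default_top_k}} of the channel count (10 single / 20
#'   combined).
#' @param train_fraction stratified train share (default 0.7).
#' @param n_trees Gini-ranking ensemble size (default 500).
#' @param max_iter GP Newton iteration cap (default 1000).
#' @param kernels blur-scan kernel ladder (default 1, 2, 4, 8, 16, 32, 64).
#' @param threshold_X accuracy-retention threshold of the zoom rule
#'   (default 0.8).
#' @param min_zoom_px zoom floor (default 32).
#' @param window_px heatmap window (default 32).
#' @param stride_px heatmap stride (default 1).
#' @param threshold decision threshold on P(high) (default 0.5).
#' @param seeds integer vector; the first seed drives single runs, the whole
#'   vector drives seed-averaged accuracies.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(channel_kinds = c("height", "rm_adhesion",
                                         "rm_restored_adhesion",
                                         "rm_viscoelastic_adhesion"),
                       registry = parameter_registry(),
                       k = default_top_k(length(channel_kinds)),
                       train_fraction = 0.7, n_trees = 500L,
                       max_iter = 1000L,
                       kernels = c(1L, 2L, 4L, 8L, 16L, 32L, 64L),
                       threshold_X = 0.8, min_zoom_px = 32L,
                       window_px = 32L, stride_px = 1L, threshold = 0.5,
                       seeds = 1L) {
  structure(list(channel_kinds = channel_kinds, registry = registry, k = k,
                 train_fraction = train_fraction, n_trees = n_trees,
                 max_iter = max_iter, kernels = kernels,
                 threshold_X = threshold_X, min_zoom_px = min_zoom_px,
                 window_px = window_px, stride_px = stride_px,
                 threshold = threshold, seeds = seeds),
            class = "run_config")
}

#' Step 1: train and evaluate the per-cell classifier
#'
#' Composes feature extraction, Gini ranking, top-k selection, the
#' stratified split, GP training and per-cell classification of the test
#' subset (and of all cells).
#'
#' @param cells list of labeled \code{\link{cell_record}}s.
#' @param config a \code{\link{run_config}}.
#' @param table optional precomputed \code{feature_table} for these cells
#'   (skips extraction).
#' @return an object of class \code{afm_step1}: the classifier, ranking,
#'   selected features, per-cell results and test accuracy.
#' @export
run_step1 <- function(cells, config = run_config(), table = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seeds[1L]
  if (is.null(table))
    table <- build_feature_table(cells, config$channel_kinds, config$registry)
  ranking <- rank_gini_importance(table, n_trees = config$n_trees, seed = seed)
  feats <- select_top_k(ranking, config$k)
  sp <- split_train_test(table, list(train_fraction = config$train_fraction,
                                     stratified = TRUE, seed = seed))
  clf <- train_gp(sp$train, feats, max_iter = config$max_iter, seed = seed)
  test_res <- classify_cells(clf, sp$test, config$threshold)
  all_res <- classify_cells(clf, table, config$threshold)
  structure(list(classifier = clf, ranking = ranking,
                 selected_features = feats, table = table,
                 split = list(train_ids = sp$train$cell_id,
                              test_ids = sp$test$cell_id),
                 test_results = test_res, all_results = all_res,
                 test_accuracy = attr(test_res, "accuracy"),
                 config = config),
            class = "afm_step1")
}

#' @export
print.afm_step1 <- function(x, ...) {
  cat("<afm_step1> per-cell GP classification\n")
  cat(sprintf("  %d cells (%d train / %d test), %d channels, top %d features\n",
              nrow(x$table$matrix), length(x$split$train_ids),
              length(x$split$test_ids), length(x$config$channel_kinds),
              x$config$k))
  cat(sprintf("  test accuracy at %.2f threshold: %.3f\n",
              x$config$threshold, x$test_accuracy))
  invisible(x)
}

#' @export
summary.afm_step1 <- function(object, ...) {
  print(object)
  cat("  top features (Gini importance):\n")
  top <- utils::head(object$ranking, object$config$k)
  cat(sprintf("    %-40s %.4f\n", top$feature, top$importance), sep = "")
  invisible(object)
}

#' @export
#' @rdname run_step1
#' @param x an \code{afm_step1} object (plot method): per-cell probability
#'   bar chart, colored by true label, with the decision threshold line.
#' @param ... passed on to \code{barplot}.
plot.afm_step1 <- function(x, ...) {
  res <- x$all_results
  ord <- order(res$label, res$probability)
  graphics::barplot(res$probability[ord],
                    col = ifelse(res$label[ord] == "high", "#B2182B",
                                 "#2166AC"),
                    border = NA, ylim = c(0, 1),
                    ylab = "P(high aggressiveness)", xlab = "cell", ...)
  graphics::abline(h = x$config$threshold, lty = 2)
  graphics::legend("topleft", fill = c("#2166AC", "#B2182B"),
                   legend = c("low", "high"), bty = "n")
  invisible(x)
}

#' @export
#' @rdname run_step1
#' @param object an \code{afm_step1}; \code{newdata} a list of cell records
#'   or a feature table.
#' @param newdata cells or feature table to classify.
predict.afm_step1 <- function(object, newdata, ...) {
  table <- if (inherits(newdata, "feature_table")) newdata
           else build_feature_table(newdata, object$config$channel_kinds,
                                    object$config$registry)
  classify_cells(object$classifier, table, object$config$threshold)
}

#' Step 2: blur scan and zoom selection
#'
#' @param cells list of labeled \code{\link{cell_record}}s.
#' @param config a \code{\link{run_config}} (fields \code{kernels},
#'   \code{threshold_X}, \code{min_zoom_px}).
#' @return an object of class \code{afm_step2}: the
#'   \code{blur_accuracy_curve} and the \code{zoom_selection}.
#' @export
run_step2 <- function(cells, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  curve <- accuracy_vs_blur(cells, config$kernels, config)
  zoom <- if (any(curve$kernel_px == 1L))
    select_zoom(curve, config$threshold_X, config$min_zoom_px)
  else NULL
  structure(list(curve = curve, zoom = zoom, config = config),
            class = "afm_step2")
}

#' @export
print.afm_step2 <- function(x, ...) {
  cat("<afm_step2> blur-accuracy scan\n")
  print.data.frame(x$curve, row.names = FALSE, digits = 3)
  if (!is.null(x$zoom)) print(x$zoom)
  invisible(x)
}

#' @export
plot.afm_step2 <- function(x, ...) plot(x$curve, ...)

#' Step 3: heatmap, overlay and regions for one cell
#'
#' @param cell a \code{\link{cell_record}}.
#' @param step1 the \code{afm_step1} result whose classifier to raster.
#' @param config a \code{\link{run_config}} (fields \code{window_px},
#'   \code{stride_px}, \code{threshold}).
#' @param overlay_channel channel kind rendered under the overlay (default:
#'   first classifier channel present).
#' @param min_area_px minimal region area (default 16 px).
#' @return an object of class \code{afm_step3}: heatmap, overlay RGB array
#'   and region set.
#' @export
run_step3 <- function(cell, step1, config = step1$config,
                      overlay_channel = NULL, min_area_px = 16L) {
  stopifnot(inherits(step1, "afm_step1"))
  hm <- compute_heatmap(cell, step1$classifier, config$window_px,
                        config$stride_px)
  ch <- overlay_channel %||%
    intersect(config$channel_kinds, names(cell$channels))[1L]
  ov <- overlay_heatmap(hm, cell$channels[[ch]], alpha = 0.5)
  regions <- extract_regions(hm, low_cut = config$threshold,
                             min_area_px = min_area_px)
  structure(list(heatmap = hm, overlay = ov, regions = regions,
                 overlay_channel = ch, config = config),
            class = "afm_step3")
}

#' @export
print.afm_step3 <- function(x, ...) {
  print(x$heatmap)
  print(x$regions)
  invisible(x)
}

#' @export
plot.afm_step3 <- function(x, ...) plot(x$heatmap, ...)

#' Write per-cell classification results as CSV
#' @param results a \code{cell_classification}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as CSV (cells x features, with id/label columns)
#' @param table a \code{feature_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table_csv <- function(table, path) {
  df <- data.frame(cell_id = table$cell_id, label = table$label,
                   table$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
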