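## Step-1 dimensionality reduction: cells x (channel, parameter) feature
## tables, Gini-importance ranking from a bagged decision-tree ensemble, and
## top-k selection (k = 10 for a single channel, 20 for a channel
## combination).

#' @noRd
feature_key <- function(channel, parameter) paste(channel, parameter, sep = ":")

#' @noRd
new_feature_table <- function(matrix, cell_id, label) {
  stopifnot(nrow(matrix) == length(cell_id), length(label) == length(cell_id))
  structure(list(matrix = matrix, cell_id = cell_id, label = label),
            class = "feature_table")
}

#' Build the cells x features surface-parameter table
#'
#' One row per cell, one column per (channel kind, parameter) pair in the
#' order channels-outer / registry-inner. Column keys are
#' \code{"<channel>:<parameter>"}.
#'
#' @param cells list of \code{\link{cell_record}}s.
#' @param channel_kinds channel kinds to include; every cell must carry all
#'   of them.
#' @param registry a \code{\link{parameter_registry}}.
#' @return an object of class \code{feature_table} (fields \code{matrix},
#'   \code{cell_id}, \code{label}).
#' @export
build_feature_table <- function(cells, channel_kinds,
                                registry = parameter_registry()) {
  stopifnot(length(cells) >= 1L, length(channel_kinds) >= 1L)
  rows <- lapply(cells, function(cell) {
    stopifnot(inherits(cell, "cell_record"))
    miss <- setdiff(channel_kinds, names(cell$channels))
    if (length(miss))
      stop_afm("cell ", cell$cell_id, " lacks channel(s): ",
               paste(miss, collapse = ", "), class = "afm_consistency_error")
    unlist(lapply(channel_kinds, function(kind) {
      v <- compute_all(cell$channels[[kind]], registry)
      names(v) <- feature_key(kind, names(v))
      unclass(v)
    }))
  })
  keys <- names(rows[[1]])
  mat <- do.call(rbind, rows)
  colnames(mat) <- keys
  rownames(mat) <- NULL
  new_feature_table(mat,
                    vapply(cells, `[[`, character(1), "cell_id"),
                    vapply(cells, `[[`, character(1), "label"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cells x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (any(x$label != "unlabeled"))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$label)),
                                   table(x$label)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature table by row
#' @param table a \code{feature_table}.
#' @param i row indices.
#' @return the subset \code{feature_table}.
#' @export
feature_table_rows <- function(table, i) {
  new_feature_table(table$matrix[i, , drop = FALSE],
                    table$cell_id[i], table$label[i])
}

#' Build a feature table from windows sampled out of labeled cells
#'
#' Alternative ("window-trained") training table for the heatmap stage: each
#' row is one randomly placed square window of one cell, labeled with the
#' cell's label, so the classifier is trained at the same spatial scale it
#' is later rastered at. The default workflow instead trains on whole-image
#' parameters, faithfully reproducing the scale mismatch of the original
#' procedure; this sampler is the documented extension, off by default.
#'
#' @param cells list of labeled \code{\link{cell_record}}s.
#' @param channel_kinds channel kinds to include.
#' @param registry a \code{\link{parameter_registry}}; parameters needing
#'   windows larger than \code{window_px} are dropped.
#' @param window_px window side in pixels (default 32).
#' @param windows_per_cell windows sampled per cell (default 8).
#' @param seed integer seed for the window placement.
#' @return a \code{feature_table} with \code{windows_per_cell} rows per cell
#'   (cell ids suffixed with the window index).
#' @export
build_window_table <- function(cells, channel_kinds,
                               registry = parameter_registry(),
                               window_px = 32L, windows_per_cell = 8L,
                               seed = 1L) {
  stopifnot(length(cells) >= 1L, windows_per_cell >= 1L)
  registry <- registry[registry$min_window_px <= window_px, , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (cell in cells) {
    d <- dim(cell$channels[[1]]$values)
    stopifnot(window_px <= min(d))
    r0 <- sample(d[1] - window_px + 1L, windows_per_cell, replace = TRUE)
    c0 <- sample(d[2] - window_px + 1L, windows_per_cell, replace = TRUE)
    for (k in seq_len(windows_per_cell)) {
      sub <- cell
      sub$cell_id <- sprintf("%s#w%02d", cell$cell_id, k)
      sub$channels <- lapply(cell$channels, function(ch) {
        ch$values <- ch$values[r0[k]:(r0[k] + window_px - 1L),
                               c0[k]:(c0[k] + window_px - 1L), drop = FALSE]
        ch
      })
      rows[[length(rows) + 1L]] <- sub
    }
  }
  build_feature_table(rows, channel_kinds, registry)
}

#' Rank features by Gini importance
#'
#' Mean decrease in Gini impurity from a bagged decision-tree ensemble
#' (bootstrap rows, random feature subsets of size \code{floor(sqrt(p))},
#' Gini split criterion), normalized to sum to one. Ties are broken by
#' table column order (registry order within channel blocks).
#'
#' @param table a labeled \code{feature_table} with at least two cells per
#'   class.
#' @param n_trees ensemble size (default 500: stable importances at
#'   two-figure precision).
#' @param seed integer seed; rankings are reproducible given it.
#' @return a data.frame of class \code{importance_ranking} with columns
#'   \code{feature} and \code{importance}, sorted non-increasing.
#' @export
rank_gini_importance <- function(table, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$label
  if (!all(y %in% c("low", "high")))
    stop_afm("feature table must be fully labeled low/high",
             class = "afm_label_error")
  if (length(unique(y)) < 2L)
    stop_afm("degenerate labels: both classes required",
             class = "afm_label_error")
  if (min(table(y)) < 2L)
    stop_afm("need at least 2 cells per class", class = "afm_label_error")
  set.seed(seed)
  ## canonical (sorted) column order before fitting: the ensemble's per-node
  ## feature subsampling is positional, so this makes the ranking exactly
  ## invariant to the caller's column permutation
  X <- table$matrix[, order(colnames(table$matrix)), drop = FALSE]
  rf <- randomForest::randomForest(
    x = X, y = factor(y, levels = c("low", "high")),
    ntree = n_trees, importance = FALSE)
  imp <- randomForest::importance(rf, type = 2)[, 1L]
  imp <- imp[colnames(table$matrix)]    # original column order
  tot <- sum(imp)
  if (tot <= 0)
    stop_afm("all features carry zero importance", class = "afm_label_error")
  imp <- imp / tot
  ord <- order(-imp, seq_along(imp))    # stable: ties by column order
  structure(data.frame(feature = colnames(table$matrix)[ord],
                       importance = unname(imp[ord]),
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"),
            n_trees = n_trees, seed = seed)
}

#' Select the top-k ranked features
#'
#' The source study found ten parameters sufficient for a single channel and
#' twenty for the combination of channels; \code{\link{default_top_k}} gives
#' that default.
#'
#' @param ranking an \code{importance_ranking}.
#' @param k number of features (>= 1); capped at the ranking length.
#' @return character vector of feature keys.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "importance_ranking"), k >= 1)
  utils::head(ranking$feature, k)
}

#' Default feature count: 10 for one channel, 20 for a combination
#' @param n_channels number of channels in the run.
#' @return 10 if \code{n_channels == 1}, else 20.
#' @export
default_top_k <- function(n_channels) if (n_channels == 1L) 10L else 20L
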