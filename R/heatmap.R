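## Step 3: raster the trained classifier over overlapping square windows.
## For every window position the selected surface parameters are computed on
## the window (per channel), standardized with the classifier's training
## statistics, and P(high) is stored at the window's center pixel (for even
## windows the center is the top-left pixel of the central 2x2 block).
## Border pixels whose window would leave the image are masked, never
## padded: padding would fabricate texture.

#' @noRd
new_heatmap <- function(probabilities, valid_mask, window_px, stride_px,
                        pitch_nm, cell_id = NULL) {
  structure(list(probabilities = probabilities, valid_mask = valid_mask,
                 window_px = as.integer(window_px),
                 stride_px = as.integer(stride_px),
                 pitch_nm = pitch_nm, positive_class = "high",
                 cell_id = cell_id),
            class = "probability_heatmap")
}

## per-channel sliding-window parameter raster: returns a matrix with one
## row per anchor (row-anchor outer loop, column-anchor inner) and one
## column per parameter name
#' @noRd
sp_window_raster <- function(z, pitch_nm, names, w, anchors_r, anchors_c) {
  out <- matrix(NA_real_, length(anchors_r) * length(anchors_c),
                length(names), dimnames = list(NULL, names))
  k <- 0L
  for (r0 in anchors_r) {
    rr <- r0:(r0 + w - 1L)
    for (c0 in anchors_c) {
      k <- k + 1L
      out[k, ] <- sp_compute(z[rr, c0:(c0 + w - 1L), drop = FALSE],
                             pitch_nm, names)
    }
  }
  out
}

#' Compute a sliding-window probability heatmap
#'
#' Applies a trained classifier to every (stride-spaced) square window of a
#' cell's channels and stores P(high aggressiveness) at each window's center
#' pixel. With stride 1 the valid region is
#' (rows - window + 1) x (cols - window + 1); with larger strides the
#' intermediate pixels of that region are filled with the nearest computed
#' value (ties toward the smaller index).
#'
#' @param cell a \code{\link{cell_record}} carrying every channel the
#'   classifier uses.
#' @param clf a \code{gp_classifier} from \code{\link{train_gp}}.
#' @param window_px square window ("zoom") side, default 32 (the scale
#'   selected by the blur scan, floored by the pixels needed for the surface
#'   parameters).
#' @param stride_px anchor spacing in pixels, default 1.
#' @return a \code{probability_heatmap}: probability matrix aligned with the
#'   source image, valid-region mask, window and stride.
#' @export
compute_heatmap <- function(cell, clf, window_px = 32L, stride_px = 1L) {
  stopifnot(inherits(cell, "cell_record"), inherits(clf, "gp_classifier"),
            is_count(window_px), is_count(stride_px), stride_px >= 1L)
  w <- as.integer(window_px)
  keys <- strsplit(clf$selected_features, ":", fixed = TRUE)
  chans <- vapply(keys, `[`, character(1), 1L)
  pars <- vapply(keys, `[`, character(1), 2L)
  miss <- setdiff(unique(chans), names(cell$channels))
  if (length(miss))
    stop_afm("cell ", cell$cell_id, " lacks channel(s) required by the ",
             "classifier: ", paste(miss, collapse = ", "),
             class = "afm_consistency_error")
  reg <- parameter_registry()
  minw <- reg$min_window_px[match(pars, reg$name)]
  if (any(minw > w))
    stop_afm("window ", w, " px too small for feature(s): ",
             paste(unique(clf$selected_features[minw > w]), collapse = ", "),
             class = "afm_scale_error")
  dims <- dim(cell$channels[[1]]$values)
  R <- dims[1]; C <- dims[2]
  if (w > min(R, C))
    stop_afm("window exceeds image size", class = "afm_scale_error")
  pitch <- cell$channels[[1]]$pitch_nm
  anchors_r <- seq.int(1L, R - w + 1L, by = stride_px)
  anchors_c <- seq.int(1L, C - w + 1L, by = stride_px)

  feat <- matrix(NA_real_, length(anchors_r) * length(anchors_c),
                 length(clf$selected_features),
                 dimnames = list(NULL, clf$selected_features))
  for (ch in unique(chans)) {
    sel <- chans == ch
    vals <- sp_window_raster(cell$channels[[ch]]$values, pitch,
                             unique(pars[sel]), w, anchors_r, anchors_c)
    feat[, sel] <- vals[, pars[sel], drop = FALSE]
  }
  p <- predict_gp_matrix(clf, feat)

  ctr <- (w - 1L) %/% 2L   # even windows: top-left of the central 2x2 block
  prob <- matrix(NA_real_, R, C)
  centers_r <- anchors_r + ctr
  centers_c <- anchors_c + ctr
  prob[centers_r, centers_c] <- matrix(p, length(anchors_r),
                                       length(anchors_c), byrow = TRUE)
  mask <- matrix(FALSE, R, C)
  full_r <- (1L + ctr):(R - w + 1L + ctr)
  full_c <- (1L + ctr):(C - w + 1L + ctr)
  mask[full_r, full_c] <- TRUE
  if (stride_px > 1L) {
    near <- function(x, first, n) first +
      pmin(pmax(round((x - first) / stride_px), 0L), n - 1L) * stride_px
    src_r <- near(full_r, centers_r[1L], length(anchors_r))
    src_c <- near(full_c, centers_c[1L], length(anchors_c))
    prob[full_r, full_c] <- prob[src_r, src_c]
  }
  new_heatmap(prob, mask, w, stride_px, pitch, cell_id = cell$cell_id)
}

#' @export
print.probability_heatmap <- function(x, ...) {
  v <- x$probabilities[x$valid_mask]
  cat(sprintf("<probability_heatmap> %d x %d px, window %d, stride %d\n",
              nrow(x$probabilities), ncol(x$probabilities),
              x$window_px, x$stride_px))
  cat(sprintf("  P(high) over valid region: mean %.3f, range [%.3f, %.3f]\n",
              mean(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.probability_heatmap <- function(x, ...) {
  m <- x$probabilities
  m[!x$valid_mask] <- NA
  cols <- grDevices::rgb(grDevices::colorRamp(
    c("#2166AC", "#F7F7F7", "#B2182B"))(seq(0, 1, length.out = 255)) / 255)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = cols, zlim = c(0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m),
                  main = sprintf("P(high), window %d px", x$window_px), ...)
  invisible(x)
}

#' Alpha-blend a probability heatmap over a channel image
#'
#' The channel is rendered in grayscale (min-max normalized); the heatmap is
#' blended on top through the fixed diverging colormap centered at
#' probability 0.5. Masked pixels show the channel only.
#'
#' @param heatmap a \code{probability_heatmap}.
#' @param image the aligned \code{\link{channel_image}}.
#' @param alpha blend weight in [0, 1] (0 = channel only, 1 = heatmap only
#'   over the valid region).
#' @param path optional PNG output path.
#' @return an rows x cols x 3 RGB array in [0, 1], invisibly if written.
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.5, path = NULL) {
  stopifnot(inherits(heatmap, "probability_heatmap"),
            inherits(image, "channel_image"),
            alpha >= 0, alpha <= 1)
  if (!all(dim(heatmap$probabilities) == dim(image$values)))
    stop_afm("heatmap and image shapes differ", class = "afm_consistency_error")
  z <- image$values
  rng <- max(z) - min(z)
  gray <- if (rng > 0) (z - min(z)) / rng else matrix(0.5, nrow(z), ncol(z))
  m <- heatmap$probabilities
  m[!heatmap$valid_mask] <- NA
  hm <- heatmap_rgb(m)
  out <- array(gray, dim = c(nrow(z), ncol(z), 3L))
  a <- ifelse(heatmap$valid_mask, alpha, 0)
  for (k in 1:3) out[, , k] <- (1 - a) * out[, , k] + a * hm[, , k]
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

## 8-connected component labelling by breadth-first flood fill
#' @noRd
label_components <- function(mask) {
  R <- nrow(mask); C <- ncol(mask)
  lab <- matrix(0L, R, C)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      qi <- (frontier - 1L) %% R + 1L
      qj <- (frontier - 1L) %/% R + 1L
      nxt <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        ni <- qi + dr; nj <- qj + dc
        ok <- ni >= 1L & ni <= R & nj >= 1L & nj <= C
        if (!any(ok)) next
        nid <- (nj[ok] - 1L) * R + ni[ok]
        nid <- nid[mask[nid] & lab[nid] == 0L]
        if (length(nid)) {
          lab[nid] <- cur
          nxt <- c(nxt, nid)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Extract thresholded high/low-aggressiveness regions from a heatmap
#'
#' Within the valid region, the 8-connected components of
#' \code{p < low_cut} are labeled \code{low} and those of
#' \code{p >= low_cut} labeled \code{high}; components smaller than
#' \code{min_area_px} are dropped. Boundaries are traced as closed polylines
#' in physical nanometres (pixel center of 1-based index i sits at
#' (i - 0.5) * pitch).
#'
#' @param heatmap a \code{probability_heatmap}.
#' @param low_cut probability threshold separating low from high (default
#'   0.5).
#' @param min_area_px minimal component area in pixels (default 1).
#' @return a list of class \code{region_set}; each region has \code{label},
#'   \code{pixels} (n x 2 row/col index matrix), \code{area_px} and
#'   \code{boundary_nm} (list of closed x/y polylines).
#' @export
extract_regions <- function(heatmap, low_cut = 0.5, min_area_px = 1L) {
  stopifnot(inherits(heatmap, "probability_heatmap"))
  p <- heatmap$probabilities
  valid <- heatmap$valid_mask
  pitch <- heatmap$pitch_nm
  regions <- list()
  for (side in c("low", "high")) {
    mask <- valid & if (side == "low") p < low_cut else p >= low_cut
    mask[is.na(mask)] <- FALSE
    lab <- label_components(mask)
    for (id in seq_len(max(lab))) {
      px <- which(lab == id, arr.ind = TRUE)
      if (nrow(px) < min_area_px) next
      comp <- matrix(0, nrow(p) + 2L, ncol(p) + 2L)   # pad to close contours
      comp[cbind(px[, 1L] + 1L, px[, 2L] + 1L)] <- 1
      ## contourLines indexes z as [x, y]: x along rows of comp = image rows
      cl <- grDevices::contourLines(
        x = ((seq_len(nrow(comp)) - 1L) - 0.5) * pitch,
        y = ((seq_len(ncol(comp)) - 1L) - 0.5) * pitch,
        z = comp, levels = 0.5)
      boundary <- lapply(cl, function(seg)
        list(x = seg$y, y = seg$x))   # back to x = column axis, y = row axis
      regions[[length(regions) + 1L]] <-
        list(label = side, pixels = unname(px), area_px = nrow(px),
             boundary_nm = boundary)
    }
  }
  structure(regions, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s)\n", length(x)))
  for (r in x)
    cat(sprintf("  %s: %d px\n", r$label, r$area_px))
  invisible(x)
}
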