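## On-disk formats: plain-text whitespace-delimited matrices or single-plane
## TIFF, each with a JSON metadata sidecar (pixel pitch, units, channel kind).
## One directory per cell, one file per channel, plus cell.json.
## Convention: pixel (row 1, col 1) is the top-left of the stored raster;
## physical position of a pixel center is (index - 0.5) * pitch_nm.

CHANNEL_KINDS <- c("height", "adhesion", "peakforce_error", "rm_adhesion",
                   "rm_restored_adhesion", "rm_viscoelastic_adhesion")
CHANNEL_UNITS <- c("nm", "nN", "a.u.")

#' Construct a single-channel AFM image
#'
#' Bundles a rectangular numeric raster with its physical pixel pitch, value
#' units and channel kind. All channel rasters in this package are stored
#' row-major with pixel \code{[1, 1]} at the top-left.
#'
#' @param values numeric matrix (rows x cols), all entries finite, at least
#'   2 x 2.
#' @param pitch_nm physical size of one pixel in nanometres (> 0). The
#'   default acquisition geometry of the source study is 512 x 512 pixels
#'   over 10 x 10 micrometres, i.e. 10000/512 = 19.53 nm per pixel.
#' @param units one of \code{"nm"}, \code{"nN"}, \code{"a.u."}.
#' @param channel_kind one of \code{height}, \code{adhesion},
#'   \code{peakforce_error}, \code{rm_adhesion}, \code{rm_restored_adhesion},
#'   \code{rm_viscoelastic_adhesion}.
#' @return an object of class \code{channel_image}.
#' @export
channel_image <- function(values, pitch_nm, units, channel_kind) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_afm("'values' must be a numeric matrix", class = "afm_format_error")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_afm("channel image must be at least 2 x 2, got ",
             nrow(values), " x ", ncol(values), class = "afm_format_error")
  if (!all(is.finite(values)))
    stop_afm("channel image contains non-finite values",
             class = "afm_format_error")
  if (!is.numeric(pitch_nm) || length(pitch_nm) != 1L || !is.finite(pitch_nm) ||
      pitch_nm <= 0)
    stop_afm("'pitch_nm' must be a single positive number",
             class = "afm_format_error")
  if (!is.character(units) || length(units) != 1L || !(units %in% CHANNEL_UNITS))
    stop_afm("'units' must be one of ", paste(CHANNEL_UNITS, collapse = ", "),
             class = "afm_format_error")
  if (!is.character(channel_kind) || length(channel_kind) != 1L ||
      !(channel_kind %in% CHANNEL_KINDS))
    stop_afm("unknown channel_kind '", channel_kind, "'",
             class = "afm_format_error")
  storage.mode(values) <- "double"
  structure(list(values = values, pitch_nm = as.numeric(pitch_nm),
                 units = units, channel_kind = channel_kind),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px, pitch %.4g nm, units %s\n",
              x$channel_kind, nrow(x$values), ncol(x$values),
              x$pitch_nm, x$units))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @noRd
default_sidecar_path <- function(path) paste0(sub("\\.[^./]+$", "", path), ".json")

#' @noRd
is_tiff_path <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' @noRd
read_text_matrix <- function(path, na_token = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_afm("empty matrix file: ", path, class = "afm_format_error")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1L)
    stop_afm("ragged matrix in ", path, ": row ",
             which(len != len[1])[1], " has ", len[len != len[1]][1],
             " entries, expected ", len[1], class = "afm_format_error")
  flat <- unlist(toks, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- is.na(vals) & !(tolower(flat) %in% c("nan", "na"))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop_afm("non-numeric entry '", flat[idx], "' in ", path, " (row ",
             (idx - 1) %/% len[1] + 1, ")", class = "afm_format_error")
  }
  matrix(vals, nrow = length(lines), ncol = len[1], byrow = TRUE)
}

#' @noRd
write_text_matrix <- function(m, path) {
  ## %.17g round-trips IEEE doubles exactly; NA/NaN serialized as "nan"
  txt <- apply(m, 1L, function(r) {
    s <- sprintf("%.17g", r)
    s[!is.finite(r)] <- "nan"
    paste(s, collapse = " ")
  })
  writeLines(txt, path)
}

#' @noRd
read_sidecar <- function(path, required) {
  if (!file.exists(path))
    stop_afm("missing metadata sidecar: ", path, class = "afm_format_error")
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) stop_afm("invalid JSON sidecar ", path,
                                                ": ", conditionMessage(e),
                                                class = "afm_format_error"))
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop_afm("sidecar ", path, " lacks required field(s): ",
             paste(miss, collapse = ", "), class = "afm_format_error")
  meta
}

#' Read a single-channel AFM image
#'
#' Reads a plain-text whitespace-delimited numeric matrix or a single-plane
#' TIFF together with its JSON metadata sidecar (fields \code{pitch_nm},
#' \code{units}, \code{channel_kind}; TIFFs written by
#' \code{\link{write_channel_image}} additionally carry \code{zmin}/
#' \code{zmax} used to undo the [0, 1] normalization of the stored samples).
#'
#' @param path image file (\code{.txt}/any text extension, or
#'   \code{.tif}/\code{.tiff}).
#' @param metadata sidecar path; default replaces the file extension with
#'   \code{.json}.
#' @return a \code{\link{channel_image}}.
#' @export
read_channel_image <- function(path, metadata = NULL) {
  if (!file.exists(path))
    stop_afm("no such file: ", path, class = "afm_format_error")
  meta <- read_sidecar(metadata %||% default_sidecar_path(path),
                       c("pitch_nm", "units", "channel_kind"))
  if (is_tiff_path(path)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) != 2L)
      stop_afm(path, " is not a single-plane grayscale TIFF",
               class = "afm_format_error")
    if (!is.null(meta$zmin) && !is.null(meta$zmax))
      m <- m * (meta$zmax - meta$zmin) + meta$zmin
  } else {
    m <- read_text_matrix(path)
    if (anyNA(m))
      stop_afm("channel image ", path, " contains non-finite entries",
               class = "afm_format_error")
  }
  channel_image(m, meta$pitch_nm, meta$units, meta$channel_kind)
}

#' Write a single-channel AFM image
#'
#' Writes the raster plus a JSON sidecar. Text files store full
#' double-precision values (\code{\%.17g}); TIFF files store 32-bit samples
#' normalized to [0, 1] with the original range recorded in the sidecar
#' (\code{zmin}, \code{zmax}), giving ~2^-32 relative representation
#' precision on the value range.
#'
#' @param image a \code{\link{channel_image}}.
#' @param path destination file; a \code{.tif}/\code{.tiff} extension selects
#'   TIFF, anything else text.
#' @param metadata sidecar path (default: extension replaced by
#'   \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_channel_image <- function(image, path, metadata = NULL) {
  stopifnot(inherits(image, "channel_image"))
  meta <- list(pitch_nm = image$pitch_nm, units = image$units,
               channel_kind = image$channel_kind)
  if (is_tiff_path(path)) {
    zmin <- min(image$values); zmax <- max(image$values)
    rng <- if (zmax > zmin) zmax - zmin else 1
    tiff::writeTIFF((image$values - zmin) / rng, path,
                    bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    meta$zmin <- zmin
    meta$zmax <- if (zmax > zmin) zmax else zmin + 1
  } else {
    write_text_matrix(image$values, path)
  }
  jsonlite::write_json(meta, metadata %||% default_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a labeled multi-channel cell record
#'
#' @param cell_id character scalar identifier.
#' @param channels named list of \code{\link{channel_image}}s, names equal to
#'   their channel kinds; all channels must be co-registered (identical rows,
#'   cols and pitch).
#' @param label \code{"low"}, \code{"high"} or \code{"unlabeled"}.
#' @return an object of class \code{cell_record}.
#' @export
cell_record <- function(cell_id, channels, label = "unlabeled") {
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id))
    stop_afm("'cell_id' must be a non-empty string", class = "afm_format_error")
  if (!is.list(channels) || length(channels) == 0L)
    stop_afm("cell ", cell_id, ": at least one channel required",
             class = "afm_consistency_error")
  if (!(label %in% c("low", "high", "unlabeled")))
    stop_afm("label must be 'low', 'high' or 'unlabeled', got '", label, "'",
             class = "afm_format_error")
  kinds <- vapply(channels, function(ch) {
    stopifnot(inherits(ch, "channel_image")); ch$channel_kind
  }, character(1))
  if (is.null(names(channels)) || !identical(unname(kinds), names(channels)))
    names(channels) <- kinds
  if (anyDuplicated(kinds))
    stop_afm("cell ", cell_id, ": duplicated channel kind",
             class = "afm_consistency_error")
  dims <- vapply(channels, function(ch) c(dim(ch$values), ch$pitch_nm),
                 numeric(3))
  if (length(channels) > 1L && any(apply(dims, 1L, function(v) length(unique(v)) > 1L)))
    stop_afm("cell ", cell_id,
             ": channels are not co-registered (rows/cols/pitch differ)",
             class = "afm_consistency_error")
  structure(list(cell_id = cell_id, label = label, channels = channels),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  d <- dim(x$channels[[1]]$values)
  cat(sprintf("<cell_record> %s (label: %s), %d channel(s), %d x %d px @ %.4g nm/px\n",
              x$cell_id, x$label, length(x$channels), d[1], d[2],
              x$channels[[1]]$pitch_nm))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read a cell directory into a cell record
#'
#' The directory must contain \code{cell.json} (fields \code{cell_id},
#' optional \code{label}, and \code{channels}: a map channel kind -> file
#' name) plus one raster file (+ sidecar) per declared channel.
#'
#' @param directory path to one cell's directory.
#' @return a \code{\link{cell_record}}; a missing \code{label} field yields
#'   an unlabeled record.
#' @export
read_cell_record <- function(directory) {
  meta <- read_sidecar(file.path(directory, "cell.json"),
                       c("cell_id", "channels"))
  chans <- meta$channels
  if (is.data.frame(chans)) chans <- as.list(chans)
  imgs <- lapply(names(chans), function(kind) {
    f <- file.path(directory, chans[[kind]])
    if (!file.exists(f))
      stop_afm("cell ", meta$cell_id, ": declared channel file missing: ", f,
               class = "afm_consistency_error")
    img <- read_channel_image(f)
    if (img$channel_kind != kind)
      stop_afm("cell ", meta$cell_id, ": file ", f, " declares kind ",
               img$channel_kind, " but is listed as ", kind,
               class = "afm_consistency_error")
    img
  })
  names(imgs) <- names(chans)
  rec <- cell_record(meta$cell_id, imgs, label = meta$label %||% "unlabeled")
  if (!is.null(meta$truth_mask)) {
    m <- read_text_matrix(file.path(directory, meta$truth_mask))
    attr(rec, "truth_mask") <- ifelse(m > 0.5, "high", "low")
  }
  rec
}

#' Write a cell record as a directory of channel files
#'
#' @param record a \code{\link{cell_record}}.
#' @param directory destination directory (created if needed).
#' @param format \code{"text"} or \code{"tiff"} for the channel rasters.
#' @return \code{directory}, invisibly.
#' @export
write_cell_record <- function(record, directory, format = c("text", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "cell_record"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") ".tif" else ".txt"
  files <- paste0(names(record$channels), ext)
  for (i in seq_along(record$channels))
    write_channel_image(record$channels[[i]], file.path(directory, files[i]))
  meta <- list(cell_id = record$cell_id, channels = as.list(files))
  names(meta$channels) <- names(record$channels)
  if (record$label != "unlabeled") meta$label <- record$label
  if (!is.null(attr(record, "truth_mask"))) {
    write_text_matrix(ifelse(attr(record, "truth_mask") == "high", 1, 0),
                      file.path(directory, "truth_mask.txt"))
    meta$truth_mask <- "truth_mask.txt"
  }
  jsonlite::write_json(meta, file.path(directory, "cell.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Write a probability heatmap (text matrix + PNG render)
#'
#' Writes \code{<path>.txt} (the probability matrix, masked pixels as
#' \code{nan}), \code{<path>.json} (window, stride, pitch) and
#' \code{<path>.png} (8-bit render through a fixed diverging colormap
#' centered at probability 0.5; masked pixels rendered mid-gray).
#'
#' @param heatmap a \code{probability_heatmap} (see
#'   \code{\link{compute_heatmap}}).
#' @param path output path prefix (extensions are appended).
#' @return \code{path}, invisibly.
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "probability_heatmap"))
  m <- heatmap$probabilities
  m[!heatmap$valid_mask] <- NaN
  write_text_matrix(m, paste0(path, ".txt"))
  jsonlite::write_json(
    list(window_px = heatmap$window_px, stride_px = heatmap$stride_px,
         pitch_nm = heatmap$pitch_nm, positive_class = "high",
         cell_id = heatmap$cell_id %||% NA),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  rgb_arr <- heatmap_rgb(m)
  png::writePNG(rgb_arr, paste0(path, ".png"))
  invisible(path)
}

#' Read back a heatmap written by \code{write_heatmap}
#'
#' @param path the same prefix passed to \code{\link{write_heatmap}}.
#' @return a \code{probability_heatmap}.
#' @export
read_heatmap <- function(path) {
  meta <- read_sidecar(paste0(path, ".json"),
                       c("window_px", "stride_px", "pitch_nm"))
  m <- read_text_matrix(paste0(path, ".txt"))
  mask <- is.finite(m)
  new_heatmap(m, mask, meta$window_px, meta$stride_px, meta$pitch_nm,
              cell_id = if (is.null(meta$cell_id) || is.na(meta$cell_id)) NULL
                        else meta$cell_id)
}

## Fixed diverging colormap (blue -> white -> red, centered at p = 0.5);
## masked (non-finite) pixels render mid-gray.
#' @noRd
heatmap_rgb <- function(m) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  out <- array(0.5, dim = c(nrow(m), ncol(m), 3L))
  ok <- is.finite(m)
  if (any(ok)) {
    cols <- ramp(pmin(pmax(m[ok], 0), 1)) / 255
    for (k in 1:3) {
      plane <- out[, , k]
      plane[ok] <- cols[, k]
      out[, , k] <- plane
    }
  }
  out
}
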