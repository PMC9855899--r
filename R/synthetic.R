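## Seed-deterministic synthetic two-class AFM-like textures. Each channel is
## a sum of (i) a large-scale Gaussian random field (spectral synthesis with
## Gaussian correlation, ~0.5 um correlation length), (ii) Gaussian-profile
## bumps at Poisson centers emulating microvilli/microridges (~0.5 um
## diameter), and (iii) fine-scale granularity (a second random field with
## 20-40 nm correlation length). Class contrast in the default configuration
## lives in the two scales the method probes: the fine-scale amplitude
## (20-40 nm) and the bump density (~0.5 um), with identical large-scale
## fields, so the blur scan has an interpretable collapse scale. Channels
## share latent white noise mixed at cross_channel_corr.

#' Stationary Gaussian random field by spectral synthesis
#'
#' White noise is filtered in Fourier space with a Gaussian amplitude filter
#' chosen so the field's autocorrelation is approximately
#' \code{exp(-(r/corr_len_px)^2)} (1/e decay at \code{corr_len_px}), then
#' centered and rescaled so the sample RMS equals \code{amp} exactly.
#' Synthesis is periodic (wrap-around).
#'
#' @param rows,cols grid size.
#' @param corr_len_px correlation length in pixels (> 0).
#' @param amp target sample RMS (0 gives the zero grid).
#' @param seed integer seed; same seed, same field.
#' @return a rows x cols numeric matrix.
#' @export
gaussian_random_field <- function(rows, cols, corr_len_px, amp, seed) {
  stopifnot(corr_len_px > 0, rows >= 2, cols >= 2)
  set.seed(seed)
  w <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (amp == 0) return(matrix(0, rows, cols))
  grf_filter(w, corr_len_px, amp)
}

## filter given white noise; shared by generate_cell so channels can mix
## latent and private noise before filtering
#' @noRd
grf_filter <- function(w, corr_len_px, amp) {
  rows <- nrow(w); cols <- ncol(w)
  fy <- fft_freq(rows); fx <- fft_freq(cols)
  k2 <- outer((2 * pi * fy)^2, rep(1, cols)) +
        outer(rep(1, rows), (2 * pi * fx)^2)
  H <- exp(-k2 * corr_len_px^2 / 8)
  z <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (rows * cols)
  z <- z - mean(z)
  rms <- sqrt(mean(z^2))
  if (rms == 0) return(z)
  z * (amp / rms)
}

#' Add Gaussian-profile bumps at Poisson-distributed centers
#'
#' Emulates protruding sub-micron features (microvilli/microridges). The
#' number of bumps is Poisson with mean \code{density_per_um2 * area}; the
#' centers are uniform, snapped to the nearest pixel center so each bump's
#' peak value is exactly \code{height}. The profile is a Gaussian with
#' full-width-half-maximum \code{diam_nm}.
#'
#' @param grid numeric matrix to add bumps to.
#' @param density_per_um2 expected bump count per square micrometre.
#' @param diam_nm bump FWHM in nm.
#' @param height peak height in grid units.
#' @param pitch_nm pixel pitch in nm.
#' @param seed integer seed.
#' @return the grid with bumps added.
#' @export
add_bumps <- function(grid, density_per_um2, diam_nm, height, pitch_nm, seed) {
  stopifnot(is.matrix(grid), density_per_um2 >= 0, diam_nm > 0, pitch_nm > 0)
  if (density_per_um2 == 0) return(grid)
  set.seed(seed)
  R <- nrow(grid); C <- ncol(grid)
  area_um2 <- R * C * pitch_nm^2 / 1e6
  n <- stats::rpois(1L, density_per_um2 * area_um2)
  if (n == 0L) return(grid)
  ri <- pmin(R, pmax(1L, round(stats::runif(n, 0.5, R + 0.5))))
  ci <- pmin(C, pmax(1L, round(stats::runif(n, 0.5, C + 0.5))))
  sigma_px <- diam_nm / pitch_nm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma_px)
  for (b in seq_len(n)) {
    r0 <- max(1L, ri[b] - half); r1 <- min(R, ri[b] + half)
    c0 <- max(1L, ci[b] - half); c1 <- min(C, ci[b] + half)
    dr <- (r0:r1) - ri[b]; dc <- (c0:c1) - ci[b]
    d2 <- outer(dr^2, rep(1, length(dc))) + outer(rep(1, length(dr)), dc^2)
    grid[r0:r1, c0:c1] <- grid[r0:r1, c0:c1] +
      height * exp(-d2 / (2 * sigma_px^2))
  }
  grid
}

#' @noRd
texture_spec <- function(field_corr_len_nm, field_amp, bump_density_per_um2,
                         bump_diam_nm, bump_height, nano_feature_size_nm,
                         nano_feature_amp, noise_white_amp = 0,
                         noise_line_amp = 0) {
  stopifnot(field_corr_len_nm > 0, bump_diam_nm > 0,
            nano_feature_size_nm > 0, bump_density_per_um2 >= 0,
            noise_white_amp >= 0, noise_line_amp >= 0)
  list(field_corr_len_nm = field_corr_len_nm, field_amp = field_amp,
       bump_density_per_um2 = bump_density_per_um2,
       bump_diam_nm = bump_diam_nm, bump_height = bump_height,
       nano_feature_size_nm = nano_feature_size_nm,
       nano_feature_amp = nano_feature_amp,
       noise_white_amp = noise_white_amp,
       noise_line_amp = noise_line_amp)
}

#' @noRd
channel_units_for <- function(kind) {
  switch(kind, height = "nm", peakforce_error = "a.u.", "nN")
}

#' Synthetic dataset configuration
#'
#' Builds the full two-class generation configuration: geometry (default
#' 512 x 512 pixels over 10 x 10 micrometres, i.e. 19.53 nm pitch), the
#' channel list, the per-channel/per-class texture specs and the
#' cross-channel correlation of the latent noise (default 0.5, a documented
#' placeholder: the real cross-channel structure of cells is unknown).
#'
#' Class contrast modes:
#' \describe{
#'   \item{two_scale (default)}{fine-scale (30 nm) granularity amplitude
#'     doubled in the high class and bump density 2.0 vs 0.8 per square um;
#'     large-scale fields identical. This mirrors the two informative scales
#'     the blur scan is meant to find (20-40 nm and ~0.5 um).}
#'   \item{nano_only}{classes differ only in the fine-scale amplitude
#'     (correlation length ~1.5 px), so moving-average blurring beyond that
#'     scale removes the entire class signal.}
#'   \item{field_amp}{classes differ only in the large-scale (0.5 um) field
#'     amplitude, a scale that small-kernel blurring barely touches.}
#' }
#'
#' @param rows,cols image size in pixels (default 512).
#' @param pitch_nm pixel pitch (default 10000/512 = 19.53 nm).
#' @param channels channel kinds to generate (default: height plus the three
#'   Ringing-mode channels used in the combined classification mode).
#' @param cross_channel_corr latent-noise correlation across channels in
#'   [-1, 1].
#' @param contrast one of \code{"two_scale"}, \code{"nano_only"},
#'   \code{"field_amp"}.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(rows = 512L, cols = 512L,
                             pitch_nm = 10000 / 512,
                             channels = c("height", "rm_adhesion",
                                          "rm_restored_adhesion",
                                          "rm_viscoelastic_adhesion"),
                             cross_channel_corr = 0.5,
                             contrast = c("two_scale", "nano_only",
                                          "field_amp"),
                             heterogeneity_cv = 0.15) {
  contrast <- match.arg(contrast)
  stopifnot(rows >= 8, cols >= 8, pitch_nm > 0,
            abs(cross_channel_corr) <= 1,
            all(channels %in% CHANNEL_KINDS), heterogeneity_cv >= 0)
  ## base amplitudes per channel kind (field, bump height, nano amp), in the
  ## channel's units: tens of nm relief for height, sub-nN contrasts for
  ## adhesion-type maps
  ## base amplitudes plus instrument-noise levels (class-independent):
  ## white = per-pixel sensor noise RMS, line = per-scan-line offset RMS
  ## (the classic AFM streak artifact, pronounced on soft living cells)
  ## Noise-to-texture ratios are identical across channels; the line level
  ## is set so that the line-artifact residual (attenuating ~ k^-1 under a
  ## k x k average) overtakes the fine-scale class signal (attenuating
  ## ~ k^-3/2) at kernels of a few tens of pixels -- the module's required
  ## blur-collapse behavior -- while staying ~3x below the fine-scale
  ## amplitude at full resolution.
  base <- list(
    height                   = c(field = 40,  bump = 150, nano = 4,    white = 0.4,   line = 5),
    adhesion                 = c(field = 0.5, bump = 1.0, nano = 0.05, white = 0.005, line = 0.0625),
    peakforce_error          = c(field = 1.0, bump = 2.0, nano = 0.10, white = 0.01,  line = 0.125),
    rm_adhesion              = c(field = 0.5, bump = 1.0, nano = 0.05, white = 0.005, line = 0.0625),
    rm_restored_adhesion     = c(field = 0.6, bump = 1.2, nano = 0.06, white = 0.006, line = 0.075),
    rm_viscoelastic_adhesion = c(field = 0.4, bump = 0.8, nano = 0.04, white = 0.004, line = 0.05))
  specs <- lapply(channels, function(kind) {
    b <- base[[kind]]
    low <- texture_spec(field_corr_len_nm = 500, field_amp = b["field"],
                        bump_density_per_um2 = 2.0, bump_diam_nm = 400,
                        bump_height = b["bump"],
                        nano_feature_size_nm = 30, nano_feature_amp = b["nano"],
                        noise_white_amp = b["white"],
                        noise_line_amp = b["line"])
    high <- low
    switch(contrast,
      two_scale = {
        high$nano_feature_amp <- 2 * b["nano"]
        high$bump_density_per_um2 <- 0.8
      },
      nano_only = {
        high$nano_feature_amp <- 2 * b["nano"]
      },
      field_amp = {
        high$field_amp <- 1.5 * b["field"]
      })
    list(low = low, high = high)
  })
  names(specs) <- channels
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_nm = pitch_nm, channels = specs,
                 cross_channel_corr = cross_channel_corr,
                 contrast = contrast, heterogeneity_cv = heterogeneity_cv),
            class = "synthetic_config")
}

## derive bounded child seeds from a base seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Generate one synthetic labeled cell
#'
#' Per requested channel the class's texture spec is realized as
#' field + bumps + fine granularity. Channels share latent white noise for
#' the random-field components (mixed at \code{cross_channel_corr}) and
#' share the bump center stream, so the channels are co-registered the way
#' simultaneously recorded AFM maps are. Adhesion-type channels (nN units)
#' are offset to be non-negative (cosmetic: all parameters level internally).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param label \code{"low"} or \code{"high"}.
#' @param cell_id identifier string.
#' @param seed integer seed; generation is fully determined by it.
#' @return a \code{\link{cell_record}}.
#' @export
generate_cell <- function(config, label, cell_id, seed) {
  stopifnot(inherits(config, "synthetic_config"), label %in% c("low", "high"))
  R <- config$rows; C <- config$cols; p <- config$pitch_nm
  rho <- config$cross_channel_corr
  ## shared latent white noise (coarse + nano) and shared bump stream
  set.seed(derive_seed(seed, 1L)); Wc <- matrix(stats::rnorm(R * C), R, C)
  set.seed(derive_seed(seed, 2L)); Wn <- matrix(stats::rnorm(R * C), R, C)
  ## per-cell biological heterogeneity: one log-normal multiplier per
  ## texture component, drawn once per cell and applied to every channel
  ## (the surface state of one cell is common to its simultaneously
  ## recorded maps)
  cv <- config$heterogeneity_cv %||% 0
  het <- c(field = 1, nano = 1, bumps = 1)
  if (cv > 0) {
    set.seed(derive_seed(seed, 5L))
    sl <- sqrt(log(1 + cv^2))
    het <- exp(stats::rnorm(3L, -sl^2 / 2, sl))
    names(het) <- c("field", "nano", "bumps")
  }
  chans <- vector("list", length(config$channels))
  for (i in seq_along(config$channels)) {
    kind <- names(config$channels)[i]
    spec <- config$channels[[i]][[label]]
    spec$field_amp <- spec$field_amp * het[["field"]]
    spec$nano_feature_amp <- spec$nano_feature_amp * het[["nano"]]
    spec$bump_density_per_um2 <- spec$bump_density_per_um2 * het[["bumps"]]
    set.seed(derive_seed(seed, 10L + 2L * i)); Vc <- matrix(stats::rnorm(R * C), R, C)
    set.seed(derive_seed(seed, 11L + 2L * i)); Vn <- matrix(stats::rnorm(R * C), R, C)
    mixc <- rho * Wc + sqrt(1 - rho^2) * Vc
    mixn <- rho * Wn + sqrt(1 - rho^2) * Vn
    z <- grf_filter(mixc, spec$field_corr_len_nm / p, spec$field_amp) +
         grf_filter(mixn, spec$nano_feature_size_nm / p, spec$nano_feature_amp)
    z <- add_bumps(z, spec$bump_density_per_um2, spec$bump_diam_nm,
                   spec$bump_height, p, seed = derive_seed(seed, 3L))
    ## instrument noise: per-pixel sensor noise + per-scan-line offsets,
    ## independent across channels
    if (spec$noise_white_amp > 0) {
      set.seed(derive_seed(seed, 50L + i))
      z <- z + matrix(stats::rnorm(R * C, sd = spec$noise_white_amp), R, C)
    }
    if (spec$noise_line_amp > 0) {
      set.seed(derive_seed(seed, 70L + i))
      z <- z + stats::rnorm(R, sd = spec$noise_line_amp)  # column-major recycling: one offset per row (scan line)
    }
    units <- channel_units_for(kind)
    if (units == "nN") z <- z - min(z)
    chans[[i]] <- channel_image(z, p, units, kind)
  }
  names(chans) <- names(config$channels)
  cell_record(cell_id, chans, label = label)
}

#' Generate a balanced two-class dataset
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n_per_class cells per class.
#' @param base_seed integer; per-cell seeds are derived deterministically
#'   from it.
#' @return a list of 2 * \code{n_per_class} \code{\link{cell_record}}s, low
#'   class first.
#' @export
generate_dataset <- function(config, n_per_class, base_seed) {
  stopifnot(n_per_class >= 1)
  cells <- vector("list", 2L * n_per_class)
  k <- 0L
  for (label in c("low", "high")) for (i in seq_len(n_per_class)) {
    k <- k + 1L
    cells[[k]] <- generate_cell(config, label,
                                sprintf("%s_%02d", label, i),
                                seed = derive_seed(base_seed, 100L + k))
  }
  cells
}

#' Generate a composite cell with a known class map
#'
#' Generates the low-class and high-class realization of the same latent
#' noise (same seed) and blends them pixel-wise according to \code{mask},
#' with the 0/1 blend weights smoothed by a 4-pixel moving average so the
#' class transition is at most ~4 px wide. The ground-truth mask is attached
#' as attribute \code{truth_mask}. An all-low (or all-high) mask reproduces
#' \code{generate_cell} with the same seed exactly.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param mask character matrix (\code{"low"}/\code{"high"}) of the
#'   configured size.
#' @param seed integer seed.
#' @param cell_id identifier (default \code{"composite"}).
#' @return a \code{\link{cell_record}} (unlabeled) with attribute
#'   \code{truth_mask}.
#' @export
generate_composite <- function(config, mask, seed, cell_id = "composite") {
  stopifnot(inherits(config, "synthetic_config"),
            is.matrix(mask), nrow(mask) == config$rows,
            ncol(mask) == config$cols, all(mask %in% c("low", "high")))
  lowc <- generate_cell(config, "low", cell_id, seed)
  highc <- generate_cell(config, "high", cell_id, seed)
  w <- ifelse(mask == "high", 1, 0)
  if (!all(w == w[1L])) w <- box_blur(w, 4L)
  chans <- lapply(names(lowc$channels), function(kind) {
    zl <- lowc$channels[[kind]]$values
    zh <- highc$channels[[kind]]$values
    channel_image((1 - w) * zl + w * zh, config$pitch_nm,
                  lowc$channels[[kind]]$units, kind)
  })
  names(chans) <- names(lowc$channels)
  rec <- cell_record(cell_id, chans, label = "unlabeled")
  attr(rec, "truth_mask") <- mask
  rec
}
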