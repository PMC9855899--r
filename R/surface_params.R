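## Areal surface-texture parameters (ISO-25178 / SPIP style), computed on a
## mean-leveled raster. Definitions, with z the leveled heights (value units
## u = nm, nN or a.u.), N the pixel count and pitch the pixel size in nm:
##
## amplitude: Sa = mean|z|; Sq = sqrt(mean z^2); Ssk = mean z^3 / Sq^3;
##   Sku = mean z^4 / Sq^4; Sp = max z; Sv = -min z; Sz = Sp + Sv;
##   S5p / S5v = mean height/depth of the 5 highest peaks / deepest valleys
##   (strict local extrema of the 8-neighborhood, interior pixels);
##   S10z = S5p + S5v.
## hybrid: Sdq = RMS of the central-difference gradient magnitude (one-sided
##   at edges, per-nm, units u/nm); Sdr = (developed area / projected area
##   - 1) * 100 % via bilinear facet triangulation; Ssc = mean summit
##   curvature -(z_xx + z_yy)/2 at local maxima (units u/nm^2); Sds = summit
##   density per um^2.
## spatial: Sal = shortest radial decay length of the normalized circular
##   autocorrelation to 0.2 (FFT-based, 72 directions, 0.5 px radial step,
##   bilinear interpolation, linear crossing; nm); Str = Sal / longest such
##   decay length (in (0, 1]); Std = angle of the dominant Fourier component
##   (degrees from the +x/column axis, in [0, 180)).
## functional (Abbott-Firestone bearing curve, heights sorted descending,
##   material ratio mr_i = (i - 0.5)/N * 100): Sk core depth via the
##   minimal-slope 40%-width secant extended to mr = 0 and 100; Spk/Svk as
##   2 A1/Smr1 and 2 A2/(100 - Smr2) from the areas between curve and the
##   secant intercept levels; Smr1/Smr2 the interpolated crossings; Sbi =
##   Sq / h(5%); Sci = (Vv(5%) - Vv(80%))/Sq; Svi = Vv(80%)/Sq; Sxp =
##   h(2.5%) - h(50%).
## volume (per unit area, height units): Vmp = Vm(10%); Vmc = Vm(80%) -
##   Vm(10%); Vvc = Vv(10%) - Vv(80%); Vvv = Vv(80%), with Vm/Vv the
##   material/void volumes of the bearing curve.

#' The canonical surface-parameter registry
#'
#' The ordered set of 30 areal surface-texture parameters this package
#' computes, grouped into the amplitude, hybrid, spatial, functional and
#' volume families, with the minimal square window (pixels) each parameter
#' needs. The ordering is fixed and is the tie-break/column order used
#' throughout the pipeline. The registry can be subset (by row) to restrict
#' the feature space.
#'
#' @param names optional character vector restricting (and reordering is not
#'   allowed: the canonical order is kept) the registry to a subset.
#' @return a data.frame of class \code{parameter_registry} with columns
#'   \code{name}, \code{family}, \code{min_window_px}.
#' @export
parameter_registry <- function(names = NULL) {
  reg <- data.frame(
    name = c("Sa", "Sq", "Ssk", "Sku", "Sp", "Sv", "Sz", "S10z", "S5p", "S5v",
             "Sdq", "Sdr", "Ssc", "Sds",
             "Sal", "Str", "Std",
             "Sbi", "Sci", "Svi", "Sk", "Spk", "Svk", "Smr1", "Smr2", "Sxp",
             "Vmp", "Vmc", "Vvc", "Vvv"),
    family = c(rep("amplitude", 10), rep("hybrid", 4), rep("spatial", 3),
               rep("functional", 9), rep("volume", 4)),
    min_window_px = c(rep(4L, 10), rep(4L, 4), rep(8L, 3), rep(8L, 9),
                      rep(8L, 4)),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    bad <- setdiff(names, reg$name)
    if (length(bad))
      stop_afm("unknown parameter name(s): ", paste(bad, collapse = ", "),
               class = "afm_parameter_error")
    reg <- reg[reg$name %in% names, , drop = FALSE]
    rownames(reg) <- NULL
  }
  class(reg) <- c("parameter_registry", "data.frame")
  reg
}

#' Subtract the mean plane level from a channel image
#'
#' All amplitude/functional parameters are defined about the mean surface;
#' this is the only leveling applied inside parameter computation (no
#' plane/polynomial fit), so that windowed computation treats every window
#' identically.
#'
#' @param image a \code{\link{channel_image}}.
#' @return the image with values shifted to zero mean.
#' @export
level_mean <- function(image) {
  stopifnot(inherits(image, "channel_image"))
  image$values <- image$values - mean(image$values)
  image
}

## ---- internal computation core ----
## sp_compute works on a raw numeric matrix and returns the requested
## parameters, sharing intermediates (moments, sorted heights, ACF) across
## names. All families level internally (mean subtraction).

#' @noRd
sp_local_extrema <- function(z) {
  R <- nrow(z); C <- ncol(z)
  ctr <- z[2:(R - 1), 2:(C - 1), drop = FALSE]
  hi <- lo <- matrix(TRUE, R - 2, C - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- z[(2 + dr):(R - 1 + dr), (2 + dc):(C - 1 + dc), drop = FALSE]
    hi <- hi & (ctr > nb)
    lo <- lo & (ctr < nb)
  }
  list(peaks = ctr[hi], valleys = ctr[lo], peak_idx = which(hi))
}

## exact integral of the piecewise-linear bearing curve h(q) over [a, b],
## constant-extended outside the node range; mr ascending, s descending.
#' @noRd
pl_integral <- function(mr, s, a, b) {
  xs <- c(0, mr, 100)
  ys <- c(s[1L], s, s[length(s)])
  x0 <- xs[-length(xs)]; x1 <- xs[-1L]
  y0 <- ys[-length(ys)]; y1 <- ys[-1L]
  lo <- pmax(x0, a); hi <- pmin(x1, b)
  keep <- hi > lo & x1 > x0
  if (!any(keep)) return(0)
  x0 <- x0[keep]; x1 <- x1[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  lo <- lo[keep]; hi <- hi[keep]
  sl <- (y1 - y0) / (x1 - x0)
  ylo <- y0 + sl * (lo - x0)
  yhi <- y0 + sl * (hi - x0)
  sum((ylo + yhi) / 2 * (hi - lo))
}

## periodic bilinear interpolation of the ACF matrix at real lags
## (dy = row lag, dx = col lag)
#' @noRd
acf_bilinear <- function(racf, dy, dx) {
  R <- nrow(racf); C <- ncol(racf)
  y <- dy %% R; x <- dx %% C
  i0 <- floor(y); j0 <- floor(x)
  fy <- y - i0; fx <- x - j0
  i1 <- (i0 + 1) %% R; j1 <- (j0 + 1) %% C
  i0 <- i0 %% R
  j0 <- j0 %% C
  v00 <- racf[cbind(i0 + 1, j0 + 1)]
  v01 <- racf[cbind(i0 + 1, j1 + 1)]
  v10 <- racf[cbind(i1 + 1, j0 + 1)]
  v11 <- racf[cbind(i1 + 1, j1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' @noRd
sp_compute <- function(z, pitch_nm, names) {
  R <- nrow(z); C <- ncol(z); N <- R * C
  z <- z - mean(z)
  out <- numeric(0)
  want <- function(nm) any(nm %in% names)

  Sq <- sqrt(mean(z * z))
  need_moments <- c("Ssk", "Sku")
  need_sq_pos <- c("Ssk", "Sku", "Sbi", "Sci", "Svi", "Sal", "Str", "Std")
  if (Sq == 0 && want(need_sq_pos))
    stop_afm("zero-variance surface: ",
             paste(intersect(names, need_sq_pos), collapse = ", "),
             " undefined (undefined-moment error)",
             class = "afm_undefined_moment_error")

  if (want("Sa")) out["Sa"] <- mean(abs(z))
  if (want("Sq")) out["Sq"] <- Sq
  if (want(need_moments)) {
    if (want("Ssk")) out["Ssk"] <- mean(z^3) / Sq^3
    if (want("Sku")) out["Sku"] <- mean(z^4) / Sq^4
  }
  if (want(c("Sp", "Sv", "Sz"))) {
    Sp <- max(z); Sv <- -min(z)
    if (want("Sp")) out["Sp"] <- Sp
    if (want("Sv")) out["Sv"] <- Sv
    if (want("Sz")) out["Sz"] <- Sp + Sv
  }

  if (want(c("S10z", "S5p", "S5v", "Ssc", "Sds"))) {
    ex <- sp_local_extrema(z)
    S5p <- if (length(ex$peaks)) mean(sort(ex$peaks, decreasing = TRUE)[
      seq_len(min(5L, length(ex$peaks)))]) else 0
    S5v <- if (length(ex$valleys)) -mean(sort(ex$valleys)[
      seq_len(min(5L, length(ex$valleys)))]) else 0
    if (want("S5p")) out["S5p"] <- S5p
    if (want("S5v")) out["S5v"] <- S5v
    if (want("S10z")) out["S10z"] <- S5p + S5v
    if (want(c("Ssc", "Sds"))) {
      area_um2 <- N * pitch_nm^2 / 1e6
      if (want("Sds")) out["Sds"] <- length(ex$peaks) / area_um2
      if (want("Ssc")) {
        if (length(ex$peak_idx)) {
          ij <- arrayInd(ex$peak_idx, c(R - 2L, C - 2L)) + 1L  # interior coords
          i <- ij[, 1L]; j <- ij[, 2L]
          zxx <- (z[cbind(i, j + 1L)] - 2 * z[cbind(i, j)] + z[cbind(i, j - 1L)]) / pitch_nm^2
          zyy <- (z[cbind(i + 1L, j)] - 2 * z[cbind(i, j)] + z[cbind(i - 1L, j)]) / pitch_nm^2
          out["Ssc"] <- mean(-(zxx + zyy) / 2)
        } else out["Ssc"] <- 0
      }
    }
  }

  if (want("Sdq")) {
    gx <- z; gx[, 2:(C - 1)] <- (z[, 3:C] - z[, 1:(C - 2)]) / (2 * pitch_nm)
    gx[, 1] <- (z[, 2] - z[, 1]) / pitch_nm
    gx[, C] <- (z[, C] - z[, C - 1]) / pitch_nm
    gy <- z; gy[2:(R - 1), ] <- (z[3:R, ] - z[1:(R - 2), ]) / (2 * pitch_nm)
    gy[1, ] <- (z[2, ] - z[1, ]) / pitch_nm
    gy[R, ] <- (z[R, ] - z[R - 1, ]) / pitch_nm
    out["Sdq"] <- sqrt(mean(gx^2 + gy^2))
  }

  if (want("Sdr")) {
    p <- pitch_nm
    z00 <- z[-R, -C]; z01 <- z[-R, -1]; z10 <- z[-1, -C]; z11 <- z[-1, -1]
    a1 <- z01 - z00; b1 <- z10 - z00
    a2 <- z01 - z11; b2 <- z10 - z11
    dev <- 0.5 * p * (sum(sqrt(a1^2 + b1^2 + p^2)) + sum(sqrt(a2^2 + b2^2 + p^2)))
    proj <- (R - 1) * (C - 1) * p^2
    out["Sdr"] <- (dev / proj - 1) * 100
  }

  if (want(c("Sal", "Str", "Std"))) {
    F <- stats::fft(z)
    if (want(c("Sal", "Str"))) {
      P <- Mod(F)^2
      racf <- Re(stats::fft(P, inverse = TRUE)) / N
      racf <- racf / racf[1L, 1L]
      rmax <- floor(min(R, C) / 2) - 1L
      radii <- seq(0.5, rmax, by = 0.5)
      ndir <- 72L
      theta <- (seq_len(ndir) - 1L) * pi / ndir
      dxm <- outer(cos(theta), radii)   # ndir x nrad, column lags
      dym <- outer(sin(theta), radii)   # row lags
      vals <- matrix(acf_bilinear(racf, as.vector(dym), as.vector(dxm)),
                     nrow = ndir)
      decay <- vapply(seq_len(ndir), function(k) {
        v <- vals[k, ]
        m <- which(v < 0.2)
        if (!length(m)) return(radii[length(radii)])
        m <- m[1L]
        a <- if (m == 1L) 1 else v[m - 1L]
        r0 <- if (m == 1L) 0 else radii[m - 1L]
        r0 + (radii[2] - radii[1]) * (a - 0.2) / (a - v[m]) *
          (if (m == 1L) radii[1L] / (radii[2] - radii[1]) else 1)
      }, numeric(1))
      if (want("Sal")) out["Sal"] <- min(decay) * pitch_nm
      if (want("Str")) out["Str"] <- min(decay) / max(decay)
    }
    if (want("Std")) {
      P2 <- Mod(F)^2
      fy <- fft_freq(R); fx <- fft_freq(C)
      FY <- matrix(fy, R, C); FX <- matrix(fx, R, C, byrow = TRUE)
      half <- FY > 0 | (FY == 0 & FX > 0)
      P2[!half] <- -Inf
      k <- which.max(P2)     # first max in column-major scan (documented tie-break)
      ang <- atan2(FY[k], FX[k]) * 180 / pi
      out["Std"] <- ang %% 180
    }
  }

  fnames <- c("Sbi", "Sci", "Svi", "Sk", "Spk", "Svk", "Smr1", "Smr2", "Sxp",
              "Vmp", "Vmc", "Vvc", "Vvv")
  if (want(fnames)) {
    s <- sort(as.vector(z), decreasing = TRUE)
    mr <- (seq_len(N) - 0.5) / N * 100
    h <- function(p) stats::approx(mr, s, xout = p, rule = 2)$y
    Vm <- function(p) (pl_integral(mr, s, 0, p) - p * h(p)) / 100
    Vv <- function(p) (h(p) * (100 - p) - pl_integral(mr, s, p, 100)) / 100

    if (want(c("Sk", "Spk", "Svk", "Smr1", "Smr2"))) {
      w <- max(2L, round(0.4 * N))
      if (w > N) w <- N
      i0 <- seq_len(N - w + 1L)
      slopes <- (s[i0 + w - 1L] - s[i0]) / (mr[i0 + w - 1L] - mr[i0])
      istar <- which.max(slopes)       # flattest (least negative); first on ties
      slope <- slopes[istar]
      z_up <- s[istar] - slope * mr[istar]
      z_low <- z_up + slope * 100
      if (want("Sk")) out["Sk"] <- z_up - z_low
      j <- which(s <= z_up)[1L]
      if (is.na(j) || j == 1L) mr1 <- 0
      else mr1 <- mr[j - 1L] + (s[j - 1L] - z_up) / (s[j - 1L] - s[j]) *
        (mr[j] - mr[j - 1L])
      jj <- which(s >= z_low)
      if (!length(jj)) mr2 <- 100
      else {
        j2 <- jj[length(jj)]
        mr2 <- if (j2 == N) 100 else
          mr[j2] + (s[j2] - z_low) / (s[j2] - s[j2 + 1L]) * (mr[j2 + 1L] - mr[j2])
      }
      if (want("Smr1")) out["Smr1"] <- mr1
      if (want("Smr2")) out["Smr2"] <- mr2
      if (want("Spk")) {
        A1 <- pl_integral(mr, s, 0, mr1) - z_up * mr1
        out["Spk"] <- if (mr1 > 0) 2 * A1 / mr1 else 0
      }
      if (want("Svk")) {
        A2 <- z_low * (100 - mr2) - pl_integral(mr, s, mr2, 100)
        out["Svk"] <- if (mr2 < 100) 2 * A2 / (100 - mr2) else 0
      }
    }
    if (want("Sbi")) out["Sbi"] <- Sq / h(5)
    if (want("Sci")) out["Sci"] <- (Vv(5) - Vv(80)) / Sq
    if (want("Svi")) out["Svi"] <- Vv(80) / Sq
    if (want("Sxp")) out["Sxp"] <- h(2.5) - h(50)
    if (want("Vmp")) out["Vmp"] <- Vm(10)
    if (want("Vmc")) out["Vmc"] <- Vm(80) - Vm(10)
    if (want("Vvc")) out["Vvc"] <- Vv(10) - Vv(80)
    if (want("Vvv")) out["Vvv"] <- Vv(80)
  }

  out[names]
}

#' Compute one surface parameter
#'
#' Computes a single named parameter of the registry on a channel image. The
#' image is mean-leveled internally; the window (the smaller image side)
#' must be at least the parameter's \code{min_window_px}.
#'
#' @param image a \code{\link{channel_image}}.
#' @param name a registry parameter name (see
#'   \code{\link{parameter_registry}}).
#' @return a single numeric value, in the units documented in the registry
#'   (value units for amplitude/functional/volume, value-per-nm for Sdq, nm
#'   for Sal, percent for Sdr/Smr1/Smr2, degrees for Std, per-square-um for
#'   Sds).
#' @export
compute_parameter <- function(image, name) {
  stopifnot(inherits(image, "channel_image"))
  reg <- parameter_registry()
  row <- match(name, reg$name)
  if (length(name) != 1L || is.na(row))
    stop_afm("unknown parameter name '", paste(name, collapse = ","), "'",
             class = "afm_parameter_error")
  win <- min(dim(image$values))
  if (win < reg$min_window_px[row])
    stop_afm("window ", win, " px is below min_window_px = ",
             reg$min_window_px[row], " for ", name,
             class = "afm_scale_error")
  unname(sp_compute(image$values, image$pitch_nm, name))
}

#' Compute all applicable surface parameters of a registry
#'
#' Evaluates every registry parameter whose \code{min_window_px} does not
#' exceed the smaller image side, in registry order.
#'
#' @param image a \code{\link{channel_image}}.
#' @param registry a \code{\link{parameter_registry}} (default: the full
#'   canonical registry).
#' @return a named numeric vector of class \code{surface_parameter_vector}
#'   with attribute \code{source_window_px}.
#' @export
compute_all <- function(image, registry = parameter_registry()) {
  stopifnot(inherits(image, "channel_image"))
  win <- min(dim(image$values))
  names <- registry$name[registry$min_window_px <= win]
  vals <- tryCatch(
    sp_compute(image$values, image$pitch_nm, names),
    error = function(e) stop_afm("surface-parameter computation failed: ",
                                 conditionMessage(e),
                                 class = "afm_parameter_error"))
  structure(vals, source_window_px = win,
            class = c("surface_parameter_vector", class(vals)))
}

#' @export
print.surface_parameter_vector <- function(x, ...) {
  cat(sprintf("<surface_parameter_vector> %d parameters (window %d px)\n",
              length(x), attr(x, "source_window_px")))
  print(round(unclass(x), 6), ...)
  invisible(x)
}
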