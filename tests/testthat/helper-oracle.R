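# Independent naive reference implementation of every registry parameter,
# written as plain loops straight from the documented definitions. Kept
# deliberately separate from the package internals: the package must agree
# with this code, not share it.

oracle_params <- function(z, pitch) {
  R <- nrow(z); C <- ncol(z); N <- R * C
  z <- z - sum(z) / N
  out <- c()

  ## amplitude moments, plain accumulation
  s1 <- s2 <- s3 <- s4 <- 0
  zmax <- -Inf; zmin <- Inf
  for (i in 1:R) for (j in 1:C) {
    v <- z[i, j]
    s1 <- s1 + abs(v); s2 <- s2 + v^2; s3 <- s3 + v^3; s4 <- s4 + v^4
    if (v > zmax) zmax <- v
    if (v < zmin) zmin <- v
  }
  Sq <- sqrt(s2 / N)
  out["Sa"] <- s1 / N
  out["Sq"] <- Sq
  out["Ssk"] <- (s3 / N) / Sq^3
  out["Sku"] <- (s4 / N) / Sq^4
  out["Sp"] <- zmax
  out["Sv"] <- -zmin
  out["Sz"] <- zmax - zmin

  ## strict 8-neighborhood extrema on the interior
  peaks <- c(); valleys <- c(); peak_pos <- NULL
  for (i in 2:(R - 1)) for (j in 2:(C - 1)) {
    v <- z[i, j]
    is_pk <- TRUE; is_vl <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- z[i + dr, j + dc]
      if (v <= nb) is_pk <- FALSE
      if (v >= nb) is_vl <- FALSE
    }
    if (is_pk) { peaks <- c(peaks, v); peak_pos <- rbind(peak_pos, c(i, j)) }
    if (is_vl) valleys <- c(valleys, v)
  }
  S5p <- if (length(peaks)) mean(rev(sort(peaks))[1:min(5, length(peaks))]) else 0
  S5v <- if (length(valleys)) -mean(sort(valleys)[1:min(5, length(valleys))]) else 0
  out["S5p"] <- S5p; out["S5v"] <- S5v; out["S10z"] <- S5p + S5v

  ## hybrid
  acc <- 0
  for (i in 1:R) for (j in 1:C) {
    gx <- if (j == 1) (z[i, 2] - z[i, 1]) / pitch
          else if (j == C) (z[i, C] - z[i, C - 1]) / pitch
          else (z[i, j + 1] - z[i, j - 1]) / (2 * pitch)
    gy <- if (i == 1) (z[2, j] - z[1, j]) / pitch
          else if (i == R) (z[R, j] - z[R - 1, j]) / pitch
          else (z[i + 1, j] - z[i - 1, j]) / (2 * pitch)
    acc <- acc + gx^2 + gy^2
  }
  out["Sdq"] <- sqrt(acc / N)

  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  dev <- 0
  for (i in 1:(R - 1)) for (j in 1:(C - 1)) {
    p00 <- c(0, 0, z[i, j]); p01 <- c(pitch, 0, z[i, j + 1])
    p10 <- c(0, pitch, z[i + 1, j]); p11 <- c(pitch, pitch, z[i + 1, j + 1])
    dev <- dev + tri_area(p00, p01, p10) + tri_area(p11, p01, p10)
  }
  out["Sdr"] <- (dev / ((R - 1) * (C - 1) * pitch^2) - 1) * 100

  if (length(peaks)) {
    cur <- 0
    for (k in seq_len(nrow(peak_pos))) {
      i <- peak_pos[k, 1]; j <- peak_pos[k, 2]
      zxx <- (z[i, j + 1] - 2 * z[i, j] + z[i, j - 1]) / pitch^2
      zyy <- (z[i + 1, j] - 2 * z[i, j] + z[i - 1, j]) / pitch^2
      cur <- cur + (-(zxx + zyy) / 2)
    }
    out["Ssc"] <- cur / length(peaks)
  } else out["Ssc"] <- 0
  out["Sds"] <- length(peaks) / (N * pitch^2 / 1e6)

  ## spatial: circular ACF by direct lag loops
  racf <- matrix(0, R, C)
  for (dy in 0:(R - 1)) for (dx in 0:(C - 1)) {
    zi <- z[((seq_len(R) - 1 + dy) %% R) + 1, ((seq_len(C) - 1 + dx) %% C) + 1]
    racf[dy + 1, dx + 1] <- sum(z * zi)
  }
  racf <- racf / racf[1, 1]
  bil <- function(dy, dx) {
    y <- dy %% R; x <- dx %% C
    i0 <- floor(y); j0 <- floor(x); fy <- y - i0; fx <- x - j0
    i1 <- (i0 + 1) %% R; j1 <- (j0 + 1) %% C
    i0 <- i0 %% R; j0 <- j0 %% C
    (1 - fy) * ((1 - fx) * racf[i0 + 1, j0 + 1] + fx * racf[i0 + 1, j1 + 1]) +
      fy * ((1 - fx) * racf[i1 + 1, j0 + 1] + fx * racf[i1 + 1, j1 + 1])
  }
  rmax <- floor(min(R, C) / 2) - 1
  radii <- seq(0.5, rmax, by = 0.5)
  decay <- numeric(72)
  for (k in 1:72) {
    th <- (k - 1) * pi / 72
    L <- radii[length(radii)]
    prev_v <- 1; prev_r <- 0
    for (r in radii) {
      v <- bil(r * sin(th), r * cos(th))
      if (v < 0.2) {
        L <- prev_r + (radii[2] - radii[1]) * (prev_v - 0.2) / (prev_v - v) *
          (if (prev_r == 0) radii[1] / (radii[2] - radii[1]) else 1)
        break
      }
      prev_v <- v; prev_r <- r
    }
    decay[k] <- L
  }
  out["Sal"] <- min(decay) * pitch
  out["Str"] <- min(decay) / max(decay)

  ## Std by direct DFT over the fy > 0 (or fy = 0, fx > 0) half-plane
  fy <- c(0:floor((R - 1) / 2), -(floor(R / 2):1)) / R
  fx <- c(0:floor((C - 1) / 2), -(floor(C / 2):1)) / C
  best <- -Inf; best_ang <- NA
  m_idx <- 0:(R - 1); n_idx <- 0:(C - 1)
  for (v in 1:C) for (u in 1:R) {       # column-major scan like which.max
    if (!(fy[u] > 0 || (fy[u] == 0 && fx[v] > 0))) next
    F_uv <- sum(z * exp(-2i * pi * (outer(m_idx, rep(1, C)) * (u - 1) / R +
                                    outer(rep(1, R), n_idx) * (v - 1) / C)))
    p <- Mod(F_uv)^2
    if (p > best) { best <- p; best_ang <- atan2(fy[u], fx[v]) * 180 / pi }
  }
  out["Std"] <- best_ang %% 180

  ## bearing curve and functional/volume families
  s <- rev(sort(as.vector(z)))
  mr <- ((1:N) - 0.5) / N * 100
  hfun <- function(p) {
    if (p <= mr[1]) return(s[1])
    if (p >= mr[N]) return(s[N])
    j <- findInterval(p, mr)
    s[j] + (s[j + 1] - s[j]) * (p - mr[j]) / (mr[j + 1] - mr[j])
  }
  int_h <- function(a, b) {       # integral of bearing curve over [a, b]
    xs <- c(0, mr, 100); ys <- c(s[1], s, s[N])
    tot <- 0
    for (q in seq_len(length(xs) - 1)) {
      lo <- max(xs[q], a); hi <- min(xs[q + 1], b)
      if (hi <= lo || xs[q + 1] <= xs[q]) next
      sl <- (ys[q + 1] - ys[q]) / (xs[q + 1] - xs[q])
      ylo <- ys[q] + sl * (lo - xs[q]); yhi <- ys[q] + sl * (hi - xs[q])
      tot <- tot + (ylo + yhi) / 2 * (hi - lo)
    }
    tot
  }
  w <- max(2, round(0.4 * N)); if (w > N) w <- N
  best_sl <- -Inf; istar <- 1
  for (i in 1:(N - w + 1)) {
    sl <- (s[i + w - 1] - s[i]) / (mr[i + w - 1] - mr[i])
    if (sl > best_sl) { best_sl <- sl; istar <- i }
  }
  z_up <- s[istar] - best_sl * mr[istar]
  z_low <- z_up + best_sl * 100
  out["Sk"] <- z_up - z_low
  j <- NA
  for (i in 1:N) if (s[i] <= z_up) { j <- i; break }
  mr1 <- if (is.na(j) || j == 1) 0 else
    mr[j - 1] + (s[j - 1] - z_up) / (s[j - 1] - s[j]) * (mr[j] - mr[j - 1])
  j2 <- NA
  for (i in N:1) if (s[i] >= z_low) { j2 <- i; break }
  mr2 <- if (is.na(j2)) 100 else if (j2 == N) 100 else
    mr[j2] + (s[j2] - z_low) / (s[j2] - s[j2 + 1]) * (mr[j2 + 1] - mr[j2])
  out["Smr1"] <- mr1; out["Smr2"] <- mr2
  A1 <- int_h(0, mr1) - z_up * mr1
  out["Spk"] <- if (mr1 > 0) 2 * A1 / mr1 else 0
  A2 <- z_low * (100 - mr2) - int_h(mr2, 100)
  out["Svk"] <- if (mr2 < 100) 2 * A2 / (100 - mr2) else 0
  Vm <- function(p) (int_h(0, p) - p * hfun(p)) / 100
  Vv <- function(p) (hfun(p) * (100 - p) - int_h(p, 100)) / 100
  out["Sbi"] <- Sq / hfun(5)
  out["Sci"] <- (Vv(5) - Vv(80)) / Sq
  out["Svi"] <- Vv(80) / Sq
  out["Sxp"] <- hfun(2.5) - hfun(50)
  out["Vmp"] <- Vm(10)
  out["Vmc"] <- Vm(80) - Vm(10)
  out["Vvc"] <- Vv(10) - Vv(80)
  out["Vvv"] <- Vv(80)
  out
}

# naive edge-truncated top-left-anchored box blur
oracle_blur <- function(z, k) {
  R <- nrow(z); C <- ncol(z)
  out <- matrix(0, R, C)
  for (i in 1:R) for (j in 1:C) {
    i2 <- min(i + k - 1, R); j2 <- min(j + k - 1, C)
    out[i, j] <- mean(z[i:i2, j:j2])
  }
  out
}

max_rel_diff <- function(a, b) {
  b <- b[names(a)]
  max(abs(a - b) / pmax(abs(b), 1e-9))
}
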