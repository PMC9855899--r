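test_that("random fields hit the requested RMS exactly and reproduce", {
  z <- gaussian_random_field(64, 64, 4, 2.5, seed = 50)
  expect_equal(sqrt(mean((z - mean(z))^2)), 2.5, tolerance = 1e-9)
  expect_identical(z, gaussian_random_field(64, 64, 4, 2.5, seed = 50))
  expect_false(identical(z, gaussian_random_field(64, 64, 4, 2.5, seed = 51)))
  expect_identical(gaussian_random_field(32, 32, 4, 0, seed = 1),
                   matrix(0, 32, 32))
})

test_that("the field autocorrelation decays to 1/e near the set length", {
  lens <- vapply(1:10, function(s) {
    z <- gaussian_random_field(128, 128, 8, 1, seed = 500 + s)
    ## radial ACF estimate along the x axis (circular)
    ac <- vapply(0:32, function(d) {
      zs <- z[, ((seq_len(128) - 1 + d) %% 128) + 1]
      mean(z * zs)
    }, numeric(1))
    ac <- ac / ac[1]
    i <- which(ac < exp(-1))[1]
    (i - 2) + (ac[i - 1] - exp(-1)) / (ac[i - 1] - ac[i])
  }, numeric(1))
  expect_lt(abs(mean(lens) - 8) / 8, 0.25)
})

test_that("bumps are Poisson-placed unit-height Gaussian profiles", {
  z0 <- matrix(0, 64, 64)
  expect_identical(add_bumps(z0, 0, 400, 1, 19.53, seed = 1), z0)

  ## find a seed placing exactly one bump, then its peak must equal height
  lam <- 0.5 * (64 * 64 * 19.53^2 / 1e6)
  seed1 <- NA
  for (s in 1:50) {
    set.seed(s)
    if (rpois(1, lam) == 1L) { seed1 <- s; break }
  }
  expect_false(is.na(seed1))
  z1 <- add_bumps(z0, 0.5, 400, 3, 19.53, seed = seed1)
  expect_gte(max(z1), 0.99 * 3)
  expect_lte(max(z1), 3 + 1e-12)

  ## total deposited mass ~ n * 2*pi*sigma^2 * h: within 3 sigma over seeds
  sigma_px <- 400 / 19.53 / (2 * sqrt(2 * log(2)))
  mass_one <- 2 * pi * sigma_px^2 * 1
  lam2 <- 2 * (256 * 256 * 19.53^2 / 1e6)
  counts <- vapply(1:10, function(s) {
    zb <- add_bumps(matrix(0, 256, 256), 2, 400, 1, 19.53, seed = 600 + s)
    sum(zb) / mass_one
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam2), 3 * sqrt(lam2 / 10) + 2)
})

test_that("generated cells are seed-deterministic and co-registered", {
  cfg <- synthetic_config(rows = 64L, cols = 64L)
  a <- generate_cell(cfg, "high", "c1", seed = 7)
  b <- generate_cell(cfg, "high", "c1", seed = 7)
  expect_identical(a, b)
  expect_length(a$channels, 4L)
  expect_identical(names(a$channels),
                   c("height", "rm_adhesion", "rm_restored_adhesion",
                     "rm_viscoelastic_adhesion"))
  dims <- vapply(a$channels, function(ch) dim(ch$values), integer(2))
  expect_true(all(dims == 64L))
  expect_identical(a$channels$height$units, "nm")
  expect_identical(a$channels$rm_adhesion$units, "nN")
  expect_gte(min(a$channels$rm_adhesion$values), 0)  # offset non-negative
})

test_that("class Sq contrast follows the configured field-amplitude ratio", {
  ## strip bumps, instrument noise and heterogeneity so the ratio contract
  ## is exact up to the small fine-scale contribution
  cfg <- synthetic_config(rows = 128L, cols = 128L, channels = "height",
                          contrast = "field_amp", heterogeneity_cv = 0)
  for (cls in c("low", "high")) {
    cfg$channels$height[[cls]]$bump_density_per_um2 <- 0
    cfg$channels$height[[cls]]$noise_white_amp <- 0
    cfg$channels$height[[cls]]$noise_line_amp <- 0
  }
  f_lo <- cfg$channels$height$low$field_amp
  f_hi <- cfg$channels$height$high$field_amp
  nano <- cfg$channels$height$low$nano_feature_amp
  want <- sqrt(f_hi^2 + nano^2) / sqrt(f_lo^2 + nano^2)
  ratios <- vapply(1:4, function(s) {
    lo <- generate_cell(cfg, "low", "l", seed = 900 + s)
    hi <- generate_cell(cfg, "high", "h", seed = 900 + s)
    compute_parameter(hi$channels$height, "Sq") /
      compute_parameter(lo$channels$height, "Sq")
  }, numeric(1))
  expect_lt(max(abs(ratios - want)) / want, 0.10)
})

test_that("datasets are balanced, deterministic and cell-distinct", {
  cfg <- synthetic_config(rows = 32L, cols = 32L, channels = "height")
  cells <- generate_dataset(cfg, 3, base_seed = 77)
  expect_length(cells, 6L)
  expect_identical(vapply(cells, `[[`, character(1), "label"),
                   rep(c("low", "high"), each = 3))
  cells2 <- generate_dataset(cfg, 3, base_seed = 77)
  expect_identical(cells, cells2)
  expect_false(identical(cells[[1]]$channels$height$values,
                         cells[[2]]$channels$height$values))
})

test_that("composites blend per-pixel classes and keep the truth mask", {
  cfg <- synthetic_config(rows = 64L, cols = 64L, channels = "height")
  all_low <- matrix("low", 64, 64)
  comp <- generate_composite(cfg, all_low, seed = 13)
  ref <- generate_cell(cfg, "low", "composite", seed = 13)
  expect_identical(comp$channels$height$values, ref$channels$height$values)
  expect_identical(attr(comp, "truth_mask"), all_low)

  half <- matrix("low", 128, 128); half[, 65:128] <- "high"
  cfg2 <- synthetic_config(rows = 128L, cols = 128L, channels = "height",
                           contrast = "field_amp")
  comp2 <- generate_composite(cfg2, half, seed = 14)
  lo <- generate_cell(cfg2, "low", "x", seed = 14)
  hi <- generate_cell(cfg2, "high", "x", seed = 14)
  z <- comp2$channels$height$values
  sq <- function(m) sqrt(mean((m - mean(m))^2))
  ## away from the seam each half matches its class realization
  expect_lt(abs(sq(z[, 1:56]) - sq(lo$channels$height$values[, 1:56])) /
              sq(lo$channels$height$values[, 1:56]), 0.10)
  expect_lt(abs(sq(z[, 73:128]) - sq(hi$channels$height$values[, 73:128])) /
              sq(hi$channels$height$values[, 73:128]), 0.10)

  d <- withr::local_tempdir()
  write_cell_record(comp, file.path(d, "comp"))
  back <- read_cell_record(file.path(d, "comp"))
  expect_identical(attr(back, "truth_mask"), all_low)
})
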