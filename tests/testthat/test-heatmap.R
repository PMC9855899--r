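# a small trained classifier shared by the heatmap tests: amplitude/hybrid
# features only, so 16-px windows are admissible
hm_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- tiny_world()
      tb <- build_feature_table(w$cells, c("height", "rm_restored_adhesion"),
                                parameter_registry(c("Sa", "Sq", "Sku", "Sdq",
                                                     "Sds", "Ssc")))
      clf <- train_gp(tb, colnames(tb$matrix), seed = 1)
      cache <<- list(world = w, clf = clf)
    }
    cache
  }
})

test_that("the valid region follows the (n - w + 1) arithmetic", {
  hw <- hm_world()
  cell <- hw$world$cells[[1]]
  hm <- compute_heatmap(cell, hw$clf, window_px = 16L)
  expect_equal(sum(hm$valid_mask), (64 - 16 + 1)^2)
  ## even window: center at anchor + w/2 - 1; border widths 7 and 8
  expect_true(all(hm$valid_mask[8:56, 8:56]))
  expect_false(any(hm$valid_mask[1:7, ]))
  expect_false(any(hm$valid_mask[57:64, ]))
  v <- hm$probabilities[hm$valid_mask]
  expect_true(all(is.finite(v) & v >= 0 & v <= 1))
  expect_true(all(is.na(hm$probabilities[!hm$valid_mask])))
})

test_that("heatmap values equal the no-raster oracle at random positions", {
  hw <- hm_world()
  cell <- hw$world$cells[[3]]
  hm <- compute_heatmap(cell, hw$clf, window_px = 16L)
  set.seed(40)
  anchors <- cbind(sample(64 - 15, 20, replace = TRUE),
                   sample(64 - 15, 20, replace = TRUE))
  for (i in seq_len(20)) {
    r0 <- anchors[i, 1]; c0 <- anchors[i, 2]
    vec <- unlist(lapply(c("height", "rm_restored_adhesion"), function(ch) {
      win <- channel_image(cell$channels[[ch]]$values[r0:(r0 + 15),
                                                      c0:(c0 + 15)],
                           cell$channels[[ch]]$pitch_nm,
                           cell$channels[[ch]]$units, ch)
      v <- compute_all(win, parameter_registry(c("Sa", "Sq", "Sku", "Sdq",
                                                 "Sds", "Ssc")))
      names(v) <- paste0(ch, ":", names(v))
      unclass(v)
    }))
    want <- predict_probability(hw$clf, vec)
    got <- hm$probabilities[r0 + 7, c0 + 7]
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("heatmaps are translation consistent and reproducible", {
  hw <- hm_world()
  base <- hw$world$cells[[2]]
  z1 <- lapply(base$channels, function(ch)
    channel_image(ch$values[1:48, 1:48], ch$pitch_nm, ch$units,
                  ch$channel_kind))
  z2 <- lapply(base$channels, function(ch)
    channel_image(ch$values[5:52, 3:50], ch$pitch_nm, ch$units,
                  ch$channel_kind))
  hm1 <- compute_heatmap(cell_record("a", z1), hw$clf, 16L)
  hm2 <- compute_heatmap(cell_record("b", z2), hw$clf, 16L)
  ## windows with identical content must give identical probabilities
  a <- hm1$probabilities[12:40, 10:40]
  b <- hm2$probabilities[(12:40) - 4, (10:40) - 2]
  expect_equal(a, b, tolerance = 1e-12)
  hm1b <- compute_heatmap(cell_record("a", z1), hw$clf, 16L)
  expect_identical(hm1$probabilities, hm1b$probabilities)
})

test_that("stride > 1 fills intermediate pixels with the nearest value", {
  hw <- hm_world()
  cell <- hw$world$cells[[4]]
  hm1 <- compute_heatmap(cell, hw$clf, 16L, 1L)
  hm3 <- compute_heatmap(cell, hw$clf, 16L, 3L)
  expect_identical(hm1$valid_mask, hm3$valid_mask)
  ## computed anchors coincide with the stride-1 values
  centers <- seq(8, 8 + 48, by = 3)
  expect_equal(hm3$probabilities[centers, centers],
               hm1$probabilities[centers, centers], tolerance = 1e-12)
  ## an off-anchor pixel equals its nearest computed neighbor
  expect_identical(hm3$probabilities[9, 8], hm3$probabilities[8, 8])
  expect_true(all(is.finite(hm3$probabilities[hm3$valid_mask])))
})

test_that("windows below a feature's minimal scale are refused", {
  w <- tiny_world()
  tb <- build_feature_table(w$cells[c(1, 2, 7, 8)],
                            "height", parameter_registry(c("Sq", "Sal")))
  clf <- train_gp(tb, colnames(tb$matrix), seed = 1)
  expect_error(compute_heatmap(w$cells[[1]], clf, window_px = 6L),
               "Sal", class = "afm_scale_error")
})

test_that("region extraction labels 8-connected components with areas", {
  p <- matrix(0.9, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[5:36, 5:36] <- TRUE
  hm <- afmtexture:::new_heatmap(p, mask, 8L, 1L, 19.53)
  rs <- extract_regions(hm, min_area_px = 4L)
  expect_length(rs, 1L)
  expect_identical(rs[[1]]$label, "high")
  expect_identical(rs[[1]]$area_px, as.integer(sum(mask)))

  p2 <- p; p2[10:19, 12:21] <- 0.1
  hm2 <- afmtexture:::new_heatmap(p2, mask, 8L, 1L, 19.53)
  rs2 <- extract_regions(hm2, min_area_px = 4L)
  lows <- Filter(function(r) r$label == "low", rs2)
  expect_length(lows, 1L)
  expect_identical(lows[[1]]$area_px, 100L)
  ## boundary polyline in physical units around the block
  bx <- range(unlist(lapply(lows[[1]]$boundary_nm, `[[`, "x")))
  expect_gt(bx[1], 10 * 19.53)
  expect_lt(bx[2], 22 * 19.53)

  rs3 <- extract_regions(hm2, min_area_px = 101L)
  expect_length(Filter(function(r) r$label == "low", rs3), 0L)
})

test_that("diagonal components are 8-connected", {
  p <- matrix(0.9, 10, 10)
  p[cbind(c(2, 3, 4), c(2, 3, 4))] <- 0.1   # diagonal chain
  hm <- afmtexture:::new_heatmap(p, matrix(TRUE, 10, 10), 2L, 1L, 10)
  lows <- Filter(function(r) r$label == "low", extract_regions(hm))
  expect_length(lows, 1L)
  expect_identical(lows[[1]]$area_px, 3L)
})

test_that("overlays honor alpha and reject mismatched shapes", {
  hw <- hm_world()
  cell <- hw$world$cells[[1]]
  hm <- compute_heatmap(cell, hw$clf, 16L)
  img <- cell$channels$height
  ov0 <- overlay_heatmap(hm, img, alpha = 0)
  gray <- (img$values - min(img$values)) / diff(range(img$values))
  expect_equal(ov0[, , 1], gray, tolerance = 1e-12)
  expect_equal(ov0[, , 2], ov0[, , 1])

  ov1 <- overlay_heatmap(hm, img, alpha = 1)
  rgb <- afmtexture:::heatmap_rgb(ifelse(hm$valid_mask, hm$probabilities, NA))
  expect_equal(ov1[, , 1][hm$valid_mask], rgb[, , 1][hm$valid_mask],
               tolerance = 1e-12)
  expect_equal(ov1[, , 1][!hm$valid_mask], gray[!hm$valid_mask],
               tolerance = 1e-12)

  expect_identical(overlay_heatmap(hm, img, 0.4), overlay_heatmap(hm, img, 0.4))
  small <- mk_img(matrix(0, 8, 8))
  expect_error(overlay_heatmap(hm, small), class = "afm_consistency_error")
})
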