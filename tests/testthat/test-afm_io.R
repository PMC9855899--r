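test_that("text channel images round-trip values and metadata exactly", {
  d <- withr::local_tempdir()
  set.seed(1)
  img <- mk_img(matrix(rnorm(20) * 1e3, 4, 5), pitch = 19.53)
  f <- file.path(d, "height.txt")
  write_channel_image(img, f)
  back <- read_channel_image(f)
  expect_identical(back$values, img$values)
  expect_identical(back$pitch_nm, 19.53)
  expect_identical(back$units, "nm")
  expect_identical(back$channel_kind, "height")
})

test_that("an all-zero matrix with a sidecar reads as a zero image", {
  d <- withr::local_tempdir()
  writeLines(rep("0 0 0", 3), file.path(d, "z.txt"))
  jsonlite::write_json(list(pitch_nm = 19.53, units = "nm",
                            channel_kind = "height"),
                       file.path(d, "z.json"), auto_unbox = TRUE)
  img <- read_channel_image(file.path(d, "z.txt"))
  expect_equal(img$values, matrix(0, 3, 3))
  expect_equal(img$pitch_nm, 19.53)
})

test_that("stored rasters keep pixel (1,1) at the top-left", {
  d <- withr::local_tempdir()
  z <- matrix(0, 3, 3); z[1, 1] <- 7; z[3, 1] <- -2
  write_channel_image(mk_img(z), file.path(d, "a.txt"))
  lines <- readLines(file.path(d, "a.txt"))
  expect_equal(as.numeric(strsplit(lines[1], " ")[[1]])[1], 7)
  expect_equal(as.numeric(strsplit(lines[3], " ")[[1]])[1], -2)
})

test_that("TIFF round-trip is identity to representation precision", {
  d <- withr::local_tempdir()
  set.seed(2)
  img <- mk_img(matrix(rnorm(64) * 50 + 10, 8, 8), units = "nN",
                kind = "rm_adhesion")
  f <- file.path(d, "ch.tif")
  write_channel_image(img, f)
  back <- read_channel_image(f)
  rng <- diff(range(img$values))
  expect_lt(max(abs(back$values - img$values)), rng * 2^-30)
  expect_identical(back$channel_kind, "rm_adhesion")
  expect_identical(back$units, "nN")
})

test_that("malformed inputs raise format errors naming the problem", {
  d <- withr::local_tempdir()
  writeLines(c("1 2 3", "4 5 6", "7 8"), file.path(d, "ragged.txt"))
  jsonlite::write_json(list(pitch_nm = 1, units = "nm", channel_kind = "height"),
                       file.path(d, "ragged.json"), auto_unbox = TRUE)
  expect_error(read_channel_image(file.path(d, "ragged.txt")),
               "row 3", class = "afm_format_error")

  writeLines(c("1 2", "3 x"), file.path(d, "bad.txt"))
  jsonlite::write_json(list(pitch_nm = 1, units = "nm", channel_kind = "height"),
                       file.path(d, "bad.json"), auto_unbox = TRUE)
  expect_error(read_channel_image(file.path(d, "bad.txt")),
               "non-numeric", class = "afm_format_error")

  writeLines(c("1 2", "3 4"), file.path(d, "nosc.txt"))
  expect_error(read_channel_image(file.path(d, "nosc.txt")),
               "sidecar", class = "afm_format_error")

  jsonlite::write_json(list(units = "nm", channel_kind = "height"),
                       file.path(d, "nosc.json"), auto_unbox = TRUE)
  expect_error(read_channel_image(file.path(d, "nosc.txt")),
               "pitch_nm", class = "afm_format_error")
})

test_that("cell records round-trip through a directory", {
  d <- withr::local_tempdir()
  set.seed(3)
  rec <- cell_record("cell_A", list(
    mk_img(matrix(rnorm(64), 8, 8)),
    mk_img(matrix(rnorm(64), 8, 8), units = "nN", kind = "rm_restored_adhesion")),
    label = "high")
  write_cell_record(rec, file.path(d, "cell_A"))
  back <- read_cell_record(file.path(d, "cell_A"))
  expect_identical(back$cell_id, "cell_A")
  expect_identical(back$label, "high")
  expect_identical(names(back$channels),
                   c("height", "rm_restored_adhesion"))
  expect_identical(back$channels$height$values, rec$channels$height$values)
})

test_that("a cell JSON without a label yields an unlabeled record", {
  d <- withr::local_tempdir()
  rec <- cell_record("c1", list(mk_img(matrix(1:16 / 4, 4, 4))))
  write_cell_record(rec, file.path(d, "c1"))   # unlabeled: no label field
  back <- read_cell_record(file.path(d, "c1"))
  expect_identical(back$label, "unlabeled")
})

test_that("channel dimension or pitch mismatches are rejected", {
  expect_error(
    cell_record("bad", list(
      mk_img(matrix(0:15, 4, 4)),
      mk_img(matrix(0:8, 3, 3), units = "nN", kind = "rm_adhesion"))),
    "co-registered", class = "afm_consistency_error")
  expect_error(
    cell_record("bad2", list(
      mk_img(matrix(0:15, 4, 4), pitch = 10),
      mk_img(matrix(0:15, 4, 4), pitch = 20, units = "nN",
             kind = "rm_adhesion"))),
    class = "afm_consistency_error")
  d <- withr::local_tempdir()
  dir.create(file.path(d, "c2"))
  jsonlite::write_json(list(cell_id = "c2",
                            channels = list(height = "missing.txt")),
                       file.path(d, "c2", "cell.json"), auto_unbox = TRUE)
  expect_error(read_cell_record(file.path(d, "c2")), "missing",
               class = "afm_consistency_error")
})

test_that("heatmaps serialize with a nan sentinel and round-trip", {
  d <- withr::local_tempdir()
  p <- matrix(0.5, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  set.seed(4)
  p[mask] <- runif(sum(mask))
  hm <- afmtexture:::new_heatmap(p, mask, 6L, 1L, 19.53, cell_id = "c")
  path <- file.path(d, "hm")
  write_heatmap(hm, path)
  txt <- readLines(paste0(path, ".txt"))
  expect_match(txt[1], "^nan( nan)*$")         # fully masked border row
  expect_true(file.exists(paste0(path, ".png")))
  back <- read_heatmap(path)
  expect_equal(back$probabilities[back$valid_mask], p[mask], tolerance = 1e-6)
  expect_identical(back$valid_mask, mask)
  expect_identical(back$window_px, 6L)
})

test_that("uniform heatmaps serialize the constant value over the valid region", {
  d <- withr::local_tempdir()
  mask <- matrix(TRUE, 4, 4)
  hm <- afmtexture:::new_heatmap(matrix(0.5, 4, 4), mask, 2L, 1L, 10)
  write_heatmap(hm, file.path(d, "u"))
  m <- afmtexture:::read_text_matrix(file.path(d, "u.txt"))
  expect_true(all(m == 0.5))
})
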