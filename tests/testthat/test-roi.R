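# ROI extraction around the epidermis.

test_that("mode 0 is a pure passthrough", {
  set.seed(1)
  img <- matrix(runif(200 * 30), 200, 30)
  m <- strip_mask(200, 30, 100, 110)
  H <- build_slm(m, 0.05)
  r <- extract_roi(img, m, H, roi_spec(0), 0.05)
  expect_identical(r$image_roi, img)
  expect_identical(r$row_offset, 0L)
  expect_identical(r$rows_kept, 200L)
})

test_that("mode 1 crops 30 px above the top epidermis pixel", {
  img <- matrix(1, 256, 20)
  m <- strip_mask(256, 20, 100, 110)
  H <- build_slm(m, 0.05)
  r <- extract_roi(img, m, H, roi_spec(1), 0.05)
  expect_equal(r$row_offset, 70)
})

test_that("mode 4 margins follow the mm-to-px arithmetic", {
  # top row 100, bottom 140 (0-based), axial 0.05 mm/px:
  # offset = 100 - round(1/0.05) = 80; last = 140 + round(2/0.05) = 180
  img <- matrix(1, 256, 20)
  m <- strip_mask(256, 20, 100, 140)
  H <- build_slm(m, 0.05)
  r <- extract_roi(img, m, H, roi_spec(4), 0.05)
  expect_equal(r$row_offset, 80)
  expect_equal(r$rows_kept, 101)
})

test_that("crop rows match independent mm-to-px arithmetic on random inputs", {
  for (seed in 1:50) {
    set.seed(seed)
    h <- sample(150:300, 1); w <- sample(10:40, 1)
    res <- runif(1, 0.02, 0.09)
    top0 <- sample(40:90, 1); bot0 <- top0 + sample(3:20, 1)
    img <- matrix(runif(h * w), h, w)
    m <- strip_mask(h, w, top0, bot0)
    H <- build_slm(m, res)
    mode <- sample(1:4, 1)
    r <- extract_roi(img, m, H, roi_spec(mode), res)
    up <- if (mode %in% c(1, 3)) 30 else round(1 / res)
    first0 <- max(0, top0 - up)
    last0 <- if (mode %in% c(3, 4)) min(h - 1, bot0 + round(2 / res)) else h - 1
    expect_equal(r$row_offset, first0)
    expect_equal(r$rows_kept, last0 - first0 + 1)
    # zeroing: no retained pixel with SLM = -1 stays non-zero
    slm_roi <- H[(first0 + 1):(last0 + 1), , drop = FALSE]
    expect_true(all(r$image_roi[slm_roi == -1] == 0))
    # and pixels with SLM > -1 are untouched
    keep <- slm_roi != -1
    expect_identical(r$image_roi[keep],
                     img[(first0 + 1):(last0 + 1), , drop = FALSE][keep])
  }
})

test_that("lower crop only removes rows (mode ordering)", {
  img <- matrix(1, 220, 12)
  m <- strip_mask(220, 12, 80, 95)
  H <- build_slm(m, 0.04)
  r1 <- extract_roi(img, m, H, roi_spec(1), 0.04)
  r2 <- extract_roi(img, m, H, roi_spec(2), 0.04)
  r3 <- extract_roi(img, m, H, roi_spec(3), 0.04)
  r4 <- extract_roi(img, m, H, roi_spec(4), 0.04)
  expect_lte(r3$rows_kept, r1$rows_kept)
  expect_lte(r4$rows_kept, r2$rows_kept)
})

test_that("re-applying the extraction to its own output is idempotent", {
  set.seed(8)
  img <- matrix(runif(256 * 16), 256, 16)
  m <- strip_mask(256, 16, 100, 120)
  H <- build_slm(m, 0.05)
  r <- extract_roi(img, m, H, roi_spec(4), 0.05)
  rows <- (r$row_offset + 1):(r$row_offset + r$rows_kept)
  m2 <- m[rows, , drop = FALSE]
  H2 <- H[rows, , drop = FALSE]
  r2 <- extract_roi(r$image_roi, m2, H2, roi_spec(4), 0.05)
  expect_identical(r2$image_roi, r$image_roi)
})

test_that("bounds are clamped and empty masks rejected", {
  img <- matrix(1, 60, 10)
  m <- strip_mask(60, 10, 10, 20)    # margin exceeds the image top
  H <- build_slm(m, 0.05)
  r <- extract_roi(img, m, H, roi_spec(3), 0.05)
  expect_equal(r$row_offset, 0)
  expect_error(extract_roi(img, matrix(FALSE, 60, 10), H, roi_spec(1), 0.05),
               "empty")
})
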