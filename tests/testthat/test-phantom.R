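# Synthetic HFUS phantom generator.

test_that("noiseless phantom obeys the region intensity ordering", {
  s <- generate_phantom(phantom_spec("control", speckle_scale = 0))
  img <- s$image
  reg <- s$region
  expect_gt(mean(img[s$mask]), mean(img[reg == 5]))          # epi > dermis
  expect_gt(mean(img[reg == 2]), mean(img[s$mask]))          # membrane > epi
  expect_gt(mean(img[reg == 5]), mean(img[reg == 1]))        # dermis > gel
})

test_that("generation is deterministic for a fixed spec", {
  sp <- phantom_spec("AD", seed = 123)
  s1 <- generate_phantom(sp)
  s2 <- generate_phantom(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
})

test_that("mask equals the epidermis region of the region map, pixel-exact", {
  for (cl in c("AD", "psoriasis", "tumor", "control")) {
    s <- generate_phantom(phantom_spec(cl, seed = 5))
    expect_identical(s$mask, s$region == 3L)
    expect_true(any(s$mask))
    expect_identical(dim(s$image), dim(s$mask))
  }
})

test_that("SLEB band has exactly round(mm/axial_res) rows per column", {
  # AD with 0.5 mm SLEB at 0.05 mm/px -> 10 rows below the epidermis
  s <- generate_phantom(phantom_spec("AD", sleb_thickness_mm = 0.5,
                                     axial_res = 0.05, speckle_scale = 0))
  sleb <- s$region == 4L
  expect_identical(unique(colSums(sleb)), 10)
  # independent geometry check: SLEB rows sit directly below the mask bottom
  for (j in seq(1, ncol(sleb), by = 37)) {
    bot <- max(which(s$mask[, j]))
    expect_identical(which(sleb[, j]), (bot + 1L):(bot + 10L))
  }
})

test_that("class-specific structure is present", {
  ad <- generate_phantom(phantom_spec("AD", speckle_scale = 0))
  ps <- generate_phantom(phantom_spec("psoriasis", speckle_scale = 0))
  tm <- generate_phantom(phantom_spec("tumor", speckle_scale = 0))
  ct <- generate_phantom(phantom_spec("control", speckle_scale = 0))
  expect_gt(sum(ad$region == 4L), 0)              # AD has a SLEB
  expect_gt(sum(ps$region == 4L), 0)              # psoriasis: thinner SLEB
  expect_lt(sum(ps$region == 4L), sum(ad$region == 4L))
  expect_gt(sum(ps$mask), sum(ct$mask))           # thickened epidermis
  expect_gt(sum(tm$region == 6L), 0)              # hypoechoic disk
  expect_equal(sum(ct$region %in% c(4L, 6L)), 0)  # control: none of these
})

test_that("infeasible geometry is rejected with a descriptive error", {
  expect_error(phantom_spec("AD", height_px = 64, axial_res = 0.02),
               "does not fit")
  expect_error(phantom_spec("control", sleb_thickness_mm = 0.3),
               "must be 0")
})

test_that("a 1 mm sub-epidermis band separates AD from control phantoms", {
  # pixel-statistics probe: the SLEB darkens the band; a single threshold
  # should classify nearly all phantoms at the default speckle level
  set.seed(77)
  band_mean <- function(s) {
    n_band <- round(1 / s$axial_res)
    vals <- unlist(lapply(seq_len(ncol(s$mask)), function(j) {
      bot <- max(which(s$mask[, j]))
      s$image[(bot + 1):(bot + n_band), j]
    }))
    mean(vals)
  }
  x_ad <- vapply(1:50, function(i)
    band_mean(generate_phantom(phantom_spec("AD", seed = i))), numeric(1))
  x_ct <- vapply(1:50, function(i)
    band_mean(generate_phantom(phantom_spec("control", seed = 1000 + i))),
    numeric(1))
  thr <- (mean(x_ad) + mean(x_ct)) / 2
  acc <- (sum(x_ad < thr) + sum(x_ct > thr)) / 100
  expect_gte(acc, 0.95)
})

test_that("generate_dataset assigns patients and balances classes", {
  ds <- generate_dataset(n_per_class = 10, n_patients_per_class = 3, seed = 2)
  man <- ds$manifest
  expect_equal(nrow(man), 40)
  expect_equal(as.integer(table(man$label)), rep(10L, 4))
  expect_equal(length(unique(man$patient_id)), 12)
  # some patients own multiple images
  expect_gt(max(table(man$patient_id)), 1)
  # single-patient classes share one id
  ds1 <- generate_dataset(2, 1, seed = 3)
  expect_equal(length(unique(ds1$manifest$patient_id)), 4)
  # determinism
  ds2 <- generate_dataset(n_per_class = 10, n_patients_per_class = 3, seed = 2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$samples[[17]]$image, ds2$samples[[17]]$image)
})

test_that("dataset files round-trip through disk", {
  ds <- generate_dataset(2, 1, seed = 9, height_px = 64, width_px = 64,
                         axial_res = 0.07, lateral_res = 0.07)
  dir <- withr::local_tempdir()
  man <- write_dataset(ds, dir)
  expect_true(all(file.exists(man$file)))
  expect_true(all(file.exists(man$mask)))
  csv <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_named(csv, c("file", "mask", "label", "patient_id",
                      "lateral_res_mm", "axial_res_mm"))
  img <- png::readPNG(man$mask[1])
  expect_identical(img > 0.5, ds$samples[[1]]$mask)
})
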