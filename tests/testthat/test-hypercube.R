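test_that("reflectance calibration implements (I_S - I_D)/(I_W - I_D)", {
  refs <- reference_frames(white = matrix(110, 5, 6), dark = matrix(10, 5, 6))
  expect_equal(unique(as.vector(
    calibrate_reflectance(flat_cube(110), refs)$data)), 1)     # I_S = I_W
  expect_equal(unique(as.vector(
    calibrate_reflectance(flat_cube(10), refs)$data)), 0)      # I_S = I_D
  out <- calibrate_reflectance(flat_cube(60), refs)
  expect_equal(unique(as.vector(out$data)), 0.5)
  expect_true(out$is_reflectance)

  # identity calibration leaves the data unchanged
  raw <- flat_cube(0.37)
  id <- calibrate_reflectance(raw, reference_frames(matrix(1, 5, 6),
                                                    matrix(0, 5, 6)))
  expect_equal(id$data, raw$data)

  # white <= dark anywhere is an error naming the position
  bad_w <- matrix(110, 5, 6); bad_w[2, 3] <- 5
  expect_error(calibrate_reflectance(flat_cube(60),
                                     reference_frames(bad_w, matrix(10, 5, 6))),
               "pixel 2.*band 3|band 3")
  # shape mismatch
  expect_error(calibrate_reflectance(flat_cube(60),
                                     reference_frames(matrix(110, 4, 6),
                                                      matrix(10, 4, 6))),
               "broadcastable")
  # already calibrated input refuses a second pass
  expect_error(calibrate_reflectance(id, refs), "already")
  # 3-D pushbroom references are averaged over scan lines first
  w3 <- array(rep(c(100, 120), 5 * 6), c(2, 5, 6))  # lines 100/120, mean 110
  out2 <- calibrate_reflectance(flat_cube(60),
                                reference_frames(w3, matrix(10, 5, 6)))
  expect_equal(unique(as.vector(out2$data)), 0.5)
})

test_that("hypercube invariants are enforced", {
  expect_error(hypercube(array(1, c(2, 2, 3)), c(1, 2)), "wavelengths")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(3, 2, 1)), "increasing")
  expect_error(hypercube(array(NA_real_, c(2, 2, 3)), 1:3,
                         is_reflectance = TRUE), "finite")
})

test_that("reverse-mask segmentation finds constructed blobs", {
  one <- blob_cube(list(list(rows = 3:7, cols = 4:13, value = 0.8)))
  seg <- segment_reverse_mask(one, threshold = 0.1)
  expect_equal(seg$n_objects, 1L)
  expect_equal(sum(seg$mask), 50)
  expect_identical(seg$mask, seg$object_labels > 0L)

  expect_warning(seg0 <- segment_reverse_mask(blob_cube(list()), threshold = 0.1),
                 "no foreground")
  expect_equal(seg0$n_objects, 0L)

  two <- blob_cube(list(list(rows = 2:5, cols = 2:5, value = 0.7),
                        list(rows = 12:18, cols = 10:14, value = 0.9)))
  seg2 <- segment_reverse_mask(two, threshold = 0.3)
  expect_equal(seg2$n_objects, 2L)
  expect_setequal(tabulate(seg2$object_labels[seg2$object_labels > 0]),
                  c(16, 35))
  # min_area removes speckle
  seg3 <- segment_reverse_mask(two, threshold = 0.3, min_area = 20)
  expect_equal(seg3$n_objects, 1L)
  # object ids contiguous 1..K
  expect_setequal(unique(as.vector(seg2$object_labels)), 0:2)
})

test_that("segmentation recovers the synthetic generator's objects (auto threshold)", {
  hc <- make_hypercube(sim_spec(n_per_class = c(A = 2L, B = 2L), rng_seed = 1L,
                                noise_sd = 0))
  refl <- calibrate_reflectance(hc$cube, hc$refs)
  seg <- segment_reverse_mask(refl)          # Otsu auto mode
  expect_equal(seg$n_objects, max(hc$truth$mask))
  expect_equal(tabulate(seg$object_labels[seg$object_labels > 0]),
               hc$truth$areas)
  expect_identical(seg$object_labels, hc$truth$mask)
})

test_that("extract_spectra averages exactly per object", {
  cube <- blob_cube(list(list(rows = 3:7, cols = 4:13, value = 0.8)),
                    bands = 5)
  # give the object's pixels a known non-constant spectrum
  s <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  for (b in 1:5) cube$data[3:7, 4:13, b] <- s[b]
  seg <- segment_reverse_mask(cube, threshold = 0.1)
  tab <- extract_spectra(cube, seg)
  expect_equal(drop(tab$X), s)
  expect_equal(tab$object_meta$n_pixels, 50L)

  # 2-pixel object: mean of the two spectra
  cube2 <- blob_cube(list(), bands = 4)
  s1 <- c(0.3, 0.5, 0.7, 0.9); s2 <- c(0.5, 0.7, 0.9, 1.1)
  cube2$data[5, 5, ] <- s1; cube2$data[5, 6, ] <- s2
  seg2 <- segment_reverse_mask(cube2, threshold = 0.1, min_area = 1)
  tab2 <- extract_spectra(cube2, seg2)
  expect_equal(drop(tab2$X), (s1 + s2) / 2)

  # brute-force per-pixel recomputation agrees exactly for generator cubes
  hc <- make_hypercube(sim_spec(n_per_class = c(A = 2L, B = 1L), rng_seed = 3L,
                                noise_sd = 0.002,
                                geometry = list(axes = c(6, 3), spacing = 20L,
                                                background = 0.05,
                                                pixel_noise_sd = 0.01)))
  refl <- calibrate_reflectance(hc$cube, hc$refs)
  seg3 <- segment_reverse_mask(refl, threshold = 0.2)
  tab3 <- extract_spectra(refl, seg3, hc$truth$labels)
  for (k in seq_len(seg3$n_objects)) {
    px <- which(seg3$object_labels == k, arr.ind = TRUE)
    brute <- colMeans(t(apply(px, 1, function(rc) refl$data[rc[1], rc[2], ])))
    expect_equal(tab3$X[k, ], brute)
  }
  expect_error(extract_spectra(refl, seg3, hc$truth$labels[1:2, ]), "objects")
})

test_that("ENVI cube and CSV spectra-table round trips are lossless", {
  hc <- make_hypercube(sim_spec(n_per_class = c(A = 2L), rng_seed = 5L))
  refl <- calibrate_reflectance(hc$cube, hc$refs)
  f <- tempfile()
  write_cube(refl, f)
  rt <- read_cube(f)
  expect_identical(rt$data, refl$data)
  expect_identical(rt$wavelengths, refl$wavelengths)
  expect_true(rt$is_reflectance)

  # BIL interleave is accepted on read
  f2 <- tempfile()
  d <- dim(refl$data)
  con <- file(f2, "wb")
  writeBin(as.vector(aperm(refl$data, c(2L, 3L, 1L))), con, size = 8,
           endian = "little")
  close(con)
  hdr <- readLines(paste0(f, ".hdr"))
  writeLines(sub("interleave = bsq", "interleave = bil", hdr),
             paste0(f2, ".hdr"))
  rt2 <- read_cube(f2)
  expect_equal(rt2$data, refl$data)

  # header declaring fewer wavelengths than bands is a format error
  f3 <- tempfile()
  write_cube(refl, f3)
  hdr3 <- readLines(paste0(f3, ".hdr"))
  wl_line <- grep("^wavelength", hdr3)
  wl <- refl$wavelengths[-1]
  hdr3[wl_line] <- sprintf("wavelength = {%s}", paste(wl, collapse = ", "))
  writeLines(hdr3, paste0(f3, ".hdr"))
  expect_error(read_cube(f3), "wavelengths")

  # spectra table CSV round trip
  tab <- extract_spectra(refl, segment_reverse_mask(refl, threshold = 0.2),
                         data.frame(cultivar = c("Alto", "Alto"),
                                    endophyte_status = c("E+", "E+"),
                                    batch_date = "2018-07-11"))
  fc <- tempfile(fileext = ".csv")
  write_spectra_table(tab, fc)
  rt3 <- read_spectra_table(fc)
  expect_equal(rt3$X, tab$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rt3$wavelengths, tab$wavelengths)
  expect_equal(rt3$labels$cultivar, tab$labels$cultivar)
})
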