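test_that("detection finds regions with correct centroids and areas", {
  frame <- matrix(0L, 20, 20)
  frame[1:10, 1:10] <- 1L
  obs <- detect_cells(frame)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$row, 4.5)
  expect_equal(obs$col, 4.5)
  expect_equal(obs$area, 100)

  frame2 <- matrix(0L, 30, 30)
  frame2[2:6, 2:6] <- 3L
  frame2[20:26, 20:26] <- 7L
  obs2 <- detect_cells(frame2)
  expect_equal(obs2$label, c(3, 7))

  # binary input is labelled internally (8-connectivity)
  obs3 <- detect_cells((frame2 > 0) * 1L)
  expect_equal(nrow(obs3), 2L)

  expect_equal(nrow(detect_cells(matrix(0L, 5, 5))), 0L)
  expect_error(detect_cells(array(0L, c(3, 3, 3))), "2-D")
})

test_that("axis lengths match the exact pixel-covariance oracle", {
  bar <- solid_rect(3, 30, pad = 2)
  f <- shape_features(bar)
  expect_equal(f$length_to_width, 10, tolerance = 0.1)
  expect_equal(f$length_to_width, oracle_axis_ratio(bar), tolerance = 1e-10)

  disc <- solid_disc(10)
  fd <- shape_features(disc)
  expect_equal(fd$length_to_width, 1, tolerance = 0.05)

  # random blobs: implementation equals the independent eigen oracle
  set.seed(11)
  for (i in 1:5) {
    m <- solid_rect(sample(2:12, 1), sample(2:40, 1), pad = 1)
    expect_equal(shape_features(m)$length_to_width, oracle_axis_ratio(m),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and nucleus-bearing masks follow the conventions", {
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  f <- shape_features(one)
  expect_equal(f$length, 1)
  expect_equal(f$width, 1)
  expect_equal(f$neurite_count, 0L)

  # nucleus covering 1/6 of the area -> nucleus:cytosol = 1:5
  mask <- solid_rect(6, 10, pad = 1)
  nuc <- matrix(FALSE, nrow(mask), ncol(mask))
  nuc[2:3, 2:6] <- TRUE  # 10 of 60 pixels
  fn <- shape_features(mask, nuc)
  expect_equal(fn$nucleus_to_cytosol, 0.2)
})

test_that("neurite counting equals the constructed ray count", {
  for (k in 2:4) {
    m <- disc_with_rays(radius = 9, n_rays = k, len = 20)
    expect_equal(count_neurites(m, min_len = 5), k)
  }
  # rays shorter than the minimum length do not count
  short <- disc_with_rays(radius = 9, n_rays = 3, len = 3)
  expect_equal(count_neurites(short, min_len = 5), 0L)
  # a bare disc has no neurites
  expect_equal(count_neurites(solid_disc(8)), 0L)
})

test_that("classification rules fire in order with first match winning", {
  t <- class_thresholds()
  mk <- function(lw, neur = 0, area = 500, nc = NA_real_)
    data.frame(length_to_width = lw, neurite_count = neur, area = area,
               nucleus_to_cytosol = nc)
  expect_equal(classify_cell(mk(6.2, neur = 2), t), "neuron-like")
  expect_equal(classify_cell(mk(1.2, area = 120, nc = 0.3), t), "shrunken")
  expect_equal(classify_cell(mk(2.0, area = 1200, nc = 0.05), t), "MEF-like")
  expect_equal(classify_cell(mk(3.0, neur = 1), t), "unclassified")
  # missing nucleus features disable the shrunken and MEF-like rules
  expect_equal(classify_cell(mk(1.2, area = 120), t), "unclassified")
  # a would-be-shrunken cell that satisfies the neuron rule is neuron-like
  expect_equal(classify_cell(mk(6.0, neur = 3, area = 120, nc = 0.3), t),
               "neuron-like")
})

test_that("classification is total over a random feature sweep", {
  set.seed(5)
  t <- class_thresholds()
  for (i in 1:200) {
    obs <- data.frame(length_to_width = runif(1, 1, 8),
                      neurite_count = sample(0:4, 1),
                      area = runif(1, 20, 2000),
                      nucleus_to_cytosol = runif(1, 0.01, 0.5))
    cls <- classify_cell(obs, t)
    expect_true(cls %in% MORPH_CLASSES)
  }
})

test_that("marker overlap follows the Jaccard convention", {
  expect_equal(marker_overlap(1:10, 1:10)$jaccard, 100)
  expect_equal(marker_overlap(1:9, 1:10)$jaccard, 90)
  expect_equal(marker_overlap(1:5, 6:10)$jaccard, 0)
  ov <- marker_overlap(integer(), integer())
  expect_equal(ov$jaccard, 100)
  expect_true(ov$both_empty)
})

test_that("shape ratios are scale-invariant while perimeter-to-area halves", {
  m <- disc_with_rays(radius = 8, n_rays = 2, len = 14)
  f1 <- shape_features(m)
  up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  f2 <- shape_features(up)
  expect_equal(f2$length_to_width / f1$length_to_width, 1, tolerance = 0.05)
  expect_equal(f2$perimeter_to_area / f1$perimeter_to_area, 0.5,
               tolerance = 0.1)

  # nucleus-to-cytosol invariant under upscaling
  mask <- solid_rect(6, 10, pad = 1)
  nuc <- matrix(FALSE, nrow(mask), ncol(mask)); nuc[2:3, 2:6] <- TRUE
  mu <- mask[rep(seq_len(nrow(mask)), each = 2), rep(seq_len(ncol(mask)),
                                                     each = 2)]
  nu <- nuc[rep(seq_len(nrow(nuc)), each = 2), rep(seq_len(ncol(nuc)),
                                                   each = 2)]
  expect_equal(shape_features(mu, nu)$nucleus_to_cytosol,
               shape_features(mask, nuc)$nucleus_to_cytosol,
               tolerance = 1e-10)
})

test_that("rendered archetypes always satisfy their class contract", {
  set.seed(99)
  t <- class_thresholds()
  for (a in c("MEF-like", "neuron-like", "shrunken")) {
    for (i in 1:8) {
      r <- render_archetype(a)
      expect_equal(classify_cell(r$features, t), a)
    }
  }
  # impossible parameters fail loudly instead of emitting off-contract masks
  bad <- default_shape_params()
  bad[["neuron-like"]]$soma_lw <- 1        # round soma,
  bad[["neuron-like"]]$soma_area_mean <- 500  # too bulky to elongate
  bad[["neuron-like"]]$neurite_len_mean <- 1
  expect_error(render_archetype("neuron-like", bad, max_tries = 5),
               "contract")
})
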