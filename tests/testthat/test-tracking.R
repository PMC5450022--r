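obs_at <- function(...) {
  pts <- list(...)
  do.call(rbind, lapply(seq_along(pts), function(i)
    data.frame(label = i, row = pts[[i]][1], col = pts[[i]][2])))
}

test_that("a single moving cell is linked with its displacement", {
  l <- link_frames(obs_at(c(0, 0)), obs_at(c(3, 4)), gate = 10)
  expect_equal(nrow(l$links), 1L)
  expect_equal(l$links$distance, 5)
  expect_equal(nrow(l$appearances), 0L)
  expect_error(link_frames(obs_at(c(0, 0)), obs_at(c(3, 4)), gate = -1),
               "gate")
})

test_that("mutual-NN linking agrees with brute-force optimal assignment", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(2:6, 1)
    a <- data.frame(label = seq_len(n), row = runif(n, 0, 300),
                    col = runif(n, 0, 300))
    # each cell steps far less than the inter-cell spacing
    b <- a
    b$row <- b$row + rnorm(n, 0, 3)
    b$col <- b$col + rnorm(n, 0, 3)
    b$label <- sample(b$label)  # shuffled labels must not matter
    l <- link_frames(a, b, gate = 30)
    oracle <- oracle_assignment(a, b, gate = 30)
    got <- l$links[order(l$links$from), c("from", "to")]
    # oracle "to" refers to positions: map back through b's labels
    want <- oracle[order(oracle$from), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("a parent with two adjacent daughters is recorded as a division", {
  parent <- obs_at(c(50, 50))
  parent$length <- 20
  kids <- obs_at(c(44, 50), c(56, 50))
  l <- link_frames(parent, kids, gate = 50)
  expect_equal(nrow(l$divisions), 1L)
  expect_equal(l$divisions$parent, 1L)
  expect_setequal(c(l$divisions$child_a, l$divisions$child_b), c(1L, 2L))
  expect_equal(nrow(l$links), 0L)
  expect_equal(nrow(l$appearances), 0L)
})

test_that("links are deterministic under input reordering", {
  set.seed(8)
  n <- 6
  a <- data.frame(label = 1:n, row = runif(n, 0, 200), col = runif(n, 0, 200))
  b <- a; b$row <- b$row + rnorm(n); b$col <- b$col + rnorm(n)
  l1 <- link_frames(a, b, gate = 20)
  perm <- sample(n)
  l2 <- link_frames(a[perm, ], b[rev(perm), ], gate = 20)
  expect_identical(l1, l2)
})

test_that("migration distances follow the closest-cell imputation rule", {
  a <- obs_at(c(0, 0), c(100, 100))
  b <- obs_at(c(1, 1))  # second cell vanished
  l <- link_frames(a, b, gate = 10)
  m <- migration_distance(a, b, l)
  expect_equal(m$distance[1], sqrt(2))
  expect_false(m$imputed[1])
  # untraceable cell: distance to the globally closest next-frame cell
  expect_equal(m$distance[2], sqrt(2 * 99^2))
  expect_true(m$imputed[2])
  # last frame: absent, not zero
  m2 <- migration_distance(a, a[0, ], link_frames(a, a[0, ]))
  expect_true(all(is.na(m2$distance)))
})

test_that("stationary cells migrate zero", {
  a <- obs_at(c(5, 5), c(50, 50))
  m <- migration_distance(a, a, link_frames(a, a, gate = 10))
  expect_equal(m$distance, c(0, 0))
})

test_that("lineage forests mirror simple event histories", {
  # 1 cell, no events, 10 frames -> one track spanning all frames
  obs <- lapply(1:10, function(t) obs_at(c(5, 5)))
  links <- lapply(1:9, function(t) link_frames(obs[[t]], obs[[t + 1]]))
  f <- build_lineages(links, obs)
  expect_equal(nrow(f$tracks), 1L)
  expect_equal(f$tracks$start_frame, 1L)
  expect_equal(f$tracks$end_frame, 10L)

  # 1 cell dividing at frame 5 -> 1 root, 2 leaves branching at 5
  obs2 <- c(lapply(1:5, function(t) obs_at(c(50, 50))),
            lapply(6:8, function(t) obs_at(c(44, 50), c(56, 50))))
  links2 <- lapply(1:7, function(t)
    link_frames(obs2[[t]], obs2[[t + 1]], gate = 50, division_radius = 30))
  f2 <- build_lineages(links2, obs2)
  expect_equal(nrow(f2$tracks), 3L)
  roots <- f2$tracks[is.na(f2$tracks$parent_track), ]
  expect_equal(nrow(roots), 1L)
  expect_equal(roots$end_frame, 5L)
  leaves <- f2$tracks[!is.na(f2$tracks$parent_track), ]
  expect_equal(leaves$start_frame, c(6L, 6L))
  expect_equal(leaves$end_frame, c(8L, 8L))
})

test_that("per-frame conservation holds on a seeded synthetic movie", {
  m <- small_movie()
  obs <- small_movie_obs()
  for (t in seq_len(length(obs) - 1)) {
    l <- link_frames(obs[[t]], obs[[t + 1]],
                     gate = 5 * max(m$config$motion_step_sd))
    expect_equal(nrow(obs[[t + 1]]),
                 nrow(l$links) + 2 * nrow(l$divisions) + nrow(l$appearances))
  }
})

test_that("tracking reconstructs the generator lineage exactly when sparse", {
  m <- small_movie()
  obs <- small_movie_obs()
  links <- lapply(seq_len(length(obs) - 1), function(t)
    link_frames(obs[[t]], obs[[t + 1]],
                gate = 5 * max(m$config$motion_step_sd)))
  acc <- tracking_accuracy(links, m$truth)
  expect_equal(acc$identity_accuracy, 1)
  expect_equal(acc$division_recall, 1)
  f <- build_lineages(links, obs)
  # every observation belongs to exactly one track
  expect_equal(nrow(f$map), sum(vapply(obs, nrow, integer(1))))
  expect_false(anyDuplicated(f$map[c("frame", "label")]) > 0)
})

test_that("inconsistent links fail naming the frame", {
  obs <- lapply(1:2, function(t) obs_at(c(5, 5), c(50, 50)))
  l <- link_frames(obs[[1]], obs[[2]])
  l$links <- rbind(l$links, l$links[1, ])  # corrupt: label linked twice
  expect_error(build_lineages(list(l), obs), "frame 1")
})
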