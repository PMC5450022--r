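test_that("doubling time reproduces the analytic cases", {
  expect_equal(doubling_time(100, 200), 24)
  expect_equal(doubling_time(100, 400), 12)
  expect_true(is.na(doubling_time(100, 100)))
  expect_true(is.na(doubling_time(100, 80)))
  expect_error(doubling_time(0, 100), "positive")
})

test_that("doubling time decreases as the 24-h count increases", {
  n24 <- seq(110, 800, by = 30)
  td <- doubling_time(rep(100, length(n24)), n24)
  expect_true(all(diff(td) < 0))
})

test_that("class time courses partition surviving cells per day", {
  obs <- data.frame(frame = rep(1:48, each = 4),
                    class = rep(c("neuron-like", "shrunken", "MEF-like",
                                  "MEF-like"), 48))
  tc <- class_time_course(obs)
  expect_true(all(abs(tapply(tc$percent, tc$day, sum) - 100) < 1e-9))
  d0 <- tc[tc$day == 0, ]
  expect_equal(d0$percent[d0$class == "MEF-like"], 50)

  # single-class population: 100% that class every day
  uni <- data.frame(frame = 1:30, class = "neuron-like")
  tcu <- class_time_course(uni)
  expect_true(all(tcu$percent[tcu$class == "neuron-like"] == 100))
  expect_true(all(tcu$count[tcu$class != "neuron-like"] == 0))
})

make_forest <- function(tracks, map) {
  structure(list(tracks = tracks, map = map), class = "lineage_forest")
}

test_that("conversions are detected with division counts and modes", {
  # track 1 (MEF) divides at frame 49 -> tracks 2 and 3 neuron-like
  tracks <- data.frame(track = 1:3, parent_track = c(NA, 1L, 1L),
                       start_frame = c(1L, 50L, 50L),
                       end_frame = c(49L, 60L, 60L), root = c(1L, 1L, 1L))
  map <- rbind(
    data.frame(frame = 1:49, label = 1L, track = 1L),
    data.frame(frame = 50:60, label = 2L, track = 2L),
    data.frame(frame = 50:60, label = 3L, track = 3L))
  obs <- data.frame(frame = map$frame, label = map$label,
                    class = ifelse(map$track == 1L, "MEF-like",
                                   "neuron-like"))
  ev <- detect_conversions(make_forest(tracks, map), obs)
  # both daughters born converted -> the division is one event
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$divisions_before, 1L)
  expect_equal(ev$mode, "high-mitosis")
  expect_equal(ev$emergence_hour, 49L)
  expect_equal(ev$final_descendants, 2L)

  # conversion with no divisions at all -> low-mitosis
  tr2 <- data.frame(track = 1L, parent_track = NA_integer_,
                    start_frame = 1L, end_frame = 30L, root = 1L)
  map2 <- data.frame(frame = 1:30, label = 1L, track = 1L)
  obs2 <- data.frame(frame = 1:30, label = 1L,
                     class = c(rep("MEF-like", 19), rep("neuron-like", 11)))
  ev2 <- detect_conversions(make_forest(tr2, map2), obs2)
  expect_equal(ev2$mode, "low-mitosis")
  expect_equal(ev2$divisions_before, 0L)
  expect_equal(ev2$conversion_frame, 20L)

  expect_error(detect_conversions(make_forest(tr2, map2), obs2,
                                  persistence = 0), "persistence")
})

test_that("brief class flicker below the persistence window is ignored", {
  tr <- data.frame(track = 1L, parent_track = NA_integer_,
                   start_frame = 1L, end_frame = 30L, root = 1L)
  map <- data.frame(frame = 1:30, label = 1L, track = 1L)
  cls <- rep("MEF-like", 30)
  cls[10:11] <- "neuron-like"  # 2-frame flicker
  cls[20:30] <- "neuron-like"  # stable conversion
  obs <- data.frame(frame = 1:30, label = 1L, class = cls)
  ev <- detect_conversions(make_forest(tr, map), obs, persistence = 3)
  expect_equal(ev$conversion_frame, 20L)
})

test_that("mode contributions census the final population exactly", {
  # 1 high-mitosis founder with 8 final neuron-like descendants;
  # 6 low-mitosis founders with 1 each
  tracks <- data.frame(
    track = 1:7, parent_track = NA_integer_, start_frame = 1L,
    end_frame = 40L, root = 1:7)
  map <- do.call(rbind, lapply(1:7, function(tr)
    data.frame(frame = 1:40, label = tr, track = tr)))
  obs <- data.frame(frame = map$frame, label = map$label, class = "MEF-like")
  obs$class[map$frame >= 10] <- "neuron-like"
  ev <- detect_conversions(make_forest(tracks, map), obs)
  ev$mode <- c("high-mitosis", rep("low-mitosis", 6))
  ev$final_descendants <- c(8L, rep(1L, 6))
  # final frame must contain 14 neuron-like cells for the census
  obs14 <- rbind(obs, do.call(rbind, lapply(8:14, function(l)
    data.frame(frame = 40L, label = l, class = "neuron-like"))))
  s <- mitosis_contribution_summary(ev, make_forest(tracks, map), obs14)
  expect_equal(s$n_founders, c(1L, 6L))
  expect_equal(s$contribution_percent[s$mode == "low-mitosis"], 100 * 6 / 14)
  expect_equal(s$contribution_percent[s$mode == "high-mitosis"], 100 * 8 / 14)
  expect_equal(sum(s$contribution_percent), 100)

  # all conversions low-mitosis -> contribution 100%
  ev2 <- ev; ev2$mode <- "low-mitosis"; ev2$final_descendants <- 2L
  obs_all <- rbind(obs[obs$frame < 40, ],
                   do.call(rbind, lapply(1:7, function(l) rbind(
                     data.frame(frame = 40L, label = l,
                                class = "neuron-like"),
                     data.frame(frame = 40L, label = l + 100L,
                                class = "neuron-like")))))
  s2 <- mitosis_contribution_summary(ev2, make_forest(tracks, map), obs_all)
  expect_equal(s2$contribution_percent[s2$mode == "low-mitosis"], 100)

  # no events -> empty, flagged
  s3 <- mitosis_contribution_summary(ev[0, ], make_forest(tracks, map), obs)
  expect_equal(nrow(s3), 0L)
  expect_true(attr(s3, "no_events"))
})

test_that("detected conversions match the generator schedule", {
  m <- small_movie()
  obs <- small_movie_obs()
  obs_all <- do.call(rbind, lapply(seq_along(obs), function(t)
    cbind(data.frame(frame = t), obs[[t]])))
  links <- lapply(seq_len(length(obs) - 1), function(t)
    link_frames(obs[[t]], obs[[t + 1]],
                gate = 5 * max(m$config$motion_step_sd)))
  forest <- build_lineages(links, obs)
  ev <- detect_conversions(forest, obs_all, persistence = 3)
  truth_conv <- m$truth$conversions[m$truth$conversions$to == "neuron-like", ]
  expect_equal(nrow(ev), nrow(truth_conv))
  expect_setequal(ev$conversion_frame, truth_conv$frame)
})

test_that("grid sampling equals the exhaustive per-field search", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(c(1, 5, 30, 60), 1)
    obs <- data.frame(label = seq_len(n), row = runif(n, 0, 499),
                      col = runif(n, 0, 499))
    k <- sample(c(2, 5), 1)
    expect_equal(grid_sample(obs, c(500, 500), k),
                 oracle_grid_sample(obs, c(500, 500), k))
  }
  # one cell per field centre -> all k^2 selected
  k <- 5; h <- 500 / k
  ctrs <- expand.grid(gi = 1:k, gj = 1:k)
  obs <- data.frame(label = seq_len(k^2),
                    row = (ctrs$gi - 0.5) * h - 0.5,
                    col = (ctrs$gj - 0.5) * h - 0.5)
  expect_equal(grid_sample(obs, c(500, 500), k), seq_len(k^2))
  # a single cell is selected regardless of k
  one <- data.frame(label = 9L, row = 250, col = 250)
  expect_equal(grid_sample(one, c(500, 500), 5), 9L)
  expect_equal(grid_sample(one, c(500, 500), 1), 9L)
})
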