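#' Population doubling time from a 24-hour count increase
#'
#' `Td = 24 / log2(N_t24 / N_t)` hours. When the count does not increase
#' the doubling time is undefined and `NA` is returned (explicitly absent,
#' not zero or infinite).
#'
#' @param n_t cell count at hour t (must be > 0).
#' @param n_t24 cell count at hour t + 24.
#' @return doubling time in hours, or `NA`.
#' @export
doubling_time <- function(n_t, n_t24) {
  if (any(n_t <= 0)) stop("n_t must be positive")
  out <- 24 / log2(n_t24 / n_t)
  out[n_t24 <= n_t] <- NA_real_
  out
}

#' Doubling-time course from per-frame cell counts
#'
#' Applies [doubling_time()] to every frame pair 24 hours apart.
#'
#' @param counts per-frame cell counts (frame 1 = hour 0).
#' @param frames_per_day frames per 24 h (default 24: hourly frames).
#' @return data.frame `hour`, `n_t`, `n_t24`, `td`.
#' @export
doubling_time_course <- function(counts, frames_per_day = 24L) {
  idx <- seq_len(max(0L, length(counts) - frames_per_day))
  data.frame(hour = idx - 1L, n_t = counts[idx],
             n_t24 = counts[idx + frames_per_day],
             td = if (length(idx)) doubling_time(counts[idx],
                                                 counts[idx + frames_per_day])
             else numeric())
}

#' Per-day class composition of the surviving population
#'
#' Counts classified cells per day and class; day `d` covers hours
#' `[24 d, 24 (d + 1))`. Each cell-frame observation contributes to its
#' day's tally; percentages are of all surviving (observed) cells that day
#' and sum to 100.
#'
#' @param obs classified observations for all frames (needs `frame`,
#'   `class`).
#' @param frames_per_day frames per 24 h.
#' @return data.frame `day`, `class`, `count`, `percent`; days with no
#'   cells are flagged with zero counts and `NA` percent.
#' @export
class_time_course <- function(obs, frames_per_day = 24L) {
  stopifnot("class" %in% names(obs))
  days <- seq(0L, max(0L, (max(obs$frame) - 1L) %/% frames_per_day))
  out <- expand.grid(day = days, class = MORPH_CLASSES,
                     stringsAsFactors = FALSE)
  obs$day <- (obs$frame - 1L) %/% frames_per_day
  tab <- as.data.frame(table(day = obs$day, class = obs$class),
                       stringsAsFactors = FALSE)
  tab$day <- as.integer(tab$day)
  m <- match(paste(out$day, out$class), paste(tab$day, tab$class))
  out$count <- ifelse(is.na(m), 0L, tab$Freq[m])
  tot <- stats::ave(out$count, out$day, FUN = sum)
  out$percent <- ifelse(tot > 0, 100 * out$count / tot, NA_real_)
  out[order(out$day, match(out$class, MORPH_CLASSES)), , drop = FALSE]
}

## class sequence of a track, ordered by frame
track_classes <- function(forest, obs) {
  key <- paste(obs$frame, obs$label)
  mk <- paste(forest$map$frame, forest$map$label)
  cls <- obs$class[match(mk, key)]
  data.frame(track = forest$map$track, frame = forest$map$frame, class = cls)
}

## number of division edges and their frames along the path root -> track
path_divisions <- function(tracks, track) {
  frames <- integer()
  tr <- track
  repeat {
    p <- tracks$parent_track[tracks$track == tr]
    if (is.na(p)) break
    frames <- c(frames, tracks$start_frame[tracks$track == tr])
    tr <- p
  }
  frames
}

#' Detect conversion events in a classified lineage forest
#'
#' A conversion is the first frame at which a track's class switches into
#' `target` and stays there for at least `persistence` consecutive frames
#' (a run cut short by the end of the movie counts). Events are detected
#' per lineage branch: once a branch has converted, its descendants do not
#' generate further events. Each event records the divisions along the path
#' from the lineage root, its mode (high-mitosis when at least
#' `mitosis_threshold` divisions occurred within the 24 h preceding the
#' conversion, low-mitosis otherwise), the emergence time in hours, and the
#' number of final-frame descendants of the converting track.
#'
#' @param forest a [build_lineages()] result.
#' @param obs classified observations for all frames.
#' @param target class converted into (default `"neuron-like"`).
#' @param persistence minimum persistence in frames (>= 1).
#' @param mitosis_threshold divisions within the preceding day that make an
#'   event high-mitosis.
#' @param frames_per_day frames per 24 h.
#' @return data.frame with one row per event: `track`, `root`,
#'   `conversion_frame`, `emergence_hour`, `divisions_before`,
#'   `divisions_last_day`, `mode`, `final_descendants`.
#' @export
detect_conversions <- function(forest, obs, target = "neuron-like",
                               persistence = 3L, mitosis_threshold = 1L,
                               frames_per_day = 24L) {
  if (persistence < 1) stop("persistence must be >= 1")
  tc <- track_classes(forest, obs)
  tracks <- forest$tracks
  n_frames <- max(forest$map$frame)
  final_by_track <- table(forest$map$track[forest$map$frame == n_frames])

  descendants <- function(tr) {
    out <- tr; frontier <- tr
    repeat {
      kids <- tracks$track[!is.na(tracks$parent_track) &
                             tracks$parent_track %in% frontier]
      if (length(kids) == 0L) break
      out <- c(out, kids); frontier <- kids
    }
    out
  }

  # first stable entry into `target` per track
  first_stable <- function(tr) {
    seqs <- tc[tc$track == tr, , drop = FALSE]
    seqs <- seqs[order(seqs$frame), , drop = FALSE]
    is_t <- !is.na(seqs$class) & seqs$class == target
    if (!any(is_t)) return(NA_integer_)
    r <- rle(is_t)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run_len <- r$lengths[k]
      at_end <- ends[k] == length(is_t) &&
        seqs$frame[ends[k]] == n_frames
      if (run_len >= persistence || at_end)
        return(seqs$frame[starts[k]])
    }
    NA_integer_
  }

  conv_frame <- setNames(
    vapply(tracks$track, first_stable, integer(1L)), tracks$track)

  events <- list()
  claimed <- integer()
  # roots first, then deeper tracks, so ancestors claim their subtree
  ord <- tracks$track[order(tracks$start_frame, tracks$track)]
  for (tr in ord) {
    if (tr %in% claimed) next
    f <- conv_frame[[as.character(tr)]]
    if (is.na(f)) next
    row <- tracks[tracks$track == tr, ]
    divs <- path_divisions(tracks, tr)
    # when both daughters of a division are born converted, the division
    # itself is the conversion: one event, one founder, both subtrees
    event_track <- tr
    subtree_root <- tr
    if (f == row$start_frame && !is.na(row$parent_track)) {
      sib <- tracks$track[!is.na(tracks$parent_track) &
                            tracks$parent_track == row$parent_track &
                            tracks$track != tr]
      if (length(sib) == 1L) {
        fs <- conv_frame[[as.character(sib)]]
        if (!is.na(fs) &&
            fs == tracks$start_frame[tracks$track == sib] && fs == f) {
          event_track <- row$parent_track
          subtree_root <- row$parent_track
        }
      }
    }
    # a division immediately preceding the conversion counts (daughter
    # starts converted)
    recent <- sum(divs > f - frames_per_day & divs <= f)
    events[[length(events) + 1L]] <- data.frame(
      track = event_track, root = tracks$root[tracks$track == tr],
      conversion_frame = f, emergence_hour = f - 1L,
      divisions_before = length(divs), divisions_last_day = recent,
      mode = if (recent >= mitosis_threshold) "high-mitosis"
      else "low-mitosis",
      final_descendants = sum(
        final_by_track[as.character(descendants(subtree_root))],
        na.rm = TRUE))
    claimed <- c(claimed, descendants(subtree_root))
  }
  if (length(events) == 0L)
    return(data.frame(track = integer(), root = integer(),
                      conversion_frame = integer(), emergence_hour = integer(),
                      divisions_before = integer(),
                      divisions_last_day = integer(), mode = character(),
                      final_descendants = integer()))
  do.call(rbind, events)
}

#' Contribution of high- versus low-mitosis conversions
#'
#' Summarises [detect_conversions()] events per mode: number of converting
#' founder cells, mean emergence time (hours), and the percentage of
#' final-frame target-class cells that descend from that mode's founders.
#'
#' @param events a [detect_conversions()] result.
#' @param forest the matching [build_lineages()] forest.
#' @param obs classified observations (to count final-frame target cells).
#' @param target target class.
#' @return data.frame per mode: `mode`, `n_founders`,
#'   `mean_emergence_hour`, `final_cells`, `contribution_percent`; an empty
#'   events table yields an empty, flagged summary.
#' @export
mitosis_contribution_summary <- function(events, forest, obs,
                                         target = "neuron-like") {
  n_frames <- max(forest$map$frame)
  final_obs <- obs[obs$frame == n_frames & !is.na(obs$class) &
                     obs$class == target, , drop = FALSE]
  n_final <- nrow(final_obs)
  if (nrow(events) == 0L) {
    out <- data.frame(mode = character(), n_founders = integer(),
                      mean_emergence_hour = numeric(), final_cells = integer(),
                      contribution_percent = numeric())
    attr(out, "no_events") <- TRUE
    return(out)
  }
  modes <- c("high-mitosis", "low-mitosis")
  out <- do.call(rbind, lapply(modes, function(md) {
    e <- events[events$mode == md, , drop = FALSE]
    data.frame(mode = md, n_founders = nrow(e),
               mean_emergence_hour = if (nrow(e)) mean(e$emergence_hour)
               else NA_real_,
               final_cells = sum(e$final_descendants),
               contribution_percent = if (n_final > 0)
                 100 * sum(e$final_descendants) / n_final else NA_real_)
  }))
  attr(out, "n_final_target") <- n_final
  out
}

#' Grid-based random cell selection
#'
#' Emulates unbiased manual sampling: the field is divided into `k` x `k`
#' equal rectangles and, in each, the cell whose centroid lies closest to
#' the rectangle centre is selected (ties to the lower label). Empty
#' rectangles contribute nothing, so at most `k^2` cells are returned.
#'
#' @param obs observation table (needs `label`, `row`, `col`).
#' @param bounds field size `c(rows, cols)` in pixels; must enclose all
#'   centroids.
#' @param k grid dimension (default 5, i.e. 25 fields).
#' @return integer vector of selected labels.
#' @export
grid_sample <- function(obs, bounds, k = 5L) {
  stopifnot(k >= 1, length(bounds) == 2L)
  if (nrow(obs) == 0L) return(integer())
  stopifnot(all(obs$row >= -0.5 & obs$row <= bounds[1L] - 0.5),
            all(obs$col >= -0.5 & obs$col <= bounds[2L] - 0.5))
  h <- bounds[1L] / k; w <- bounds[2L] / k
  sel <- integer()
  for (gi in seq_len(k)) {
    for (gj in seq_len(k)) {
      ctr <- c((gi - 0.5) * h - 0.5, (gj - 0.5) * w - 0.5)
      d <- sqrt((obs$row - ctr[1L])^2 + (obs$col - ctr[2L])^2)
      ord <- order(d, obs$label)
      # the winner must actually lie in this rectangle
      inside <- obs$row + 0.5 >= (gi - 1) * h & obs$row + 0.5 < gi * h &
        obs$col + 0.5 >= (gj - 1) * w & obs$col + 0.5 < gj * w
      ord <- ord[inside[ord]]
      if (length(ord)) sel <- c(sel, obs$label[ord[1L]])
    }
  }
  sort(unique(sel))
}
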