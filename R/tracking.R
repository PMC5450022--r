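#' Link cell observations between two consecutive frames
#'
#' Identity links are greedy mutual nearest neighbours on centroid distance
#' within `gate` pixels. After identity linking, an unmatched source cell
#' with at least two unmatched next-frame cells inside `division_radius` is
#' recorded as a division to the two nearest; an unmatched next-frame cell
#' whose nearest linked source has both it and its link target inside the
#' division radius upgrades that link to a division (the geometry a split
#' region leaves behind). Remaining unmatched source
#' cells are disappearances (reason `"untraceable"` when some next-frame
#' cell lies within the gate, `"death"` otherwise); remaining unmatched
#' next-frame cells are appearances. Ties are broken by (distance, lower
#' label), so the result does not depend on input row order.
#'
#' @param obs_n,obs_n1 observation tables of frames n and n+1
#'   (from [detect_cells()]; need `label`, `row`, `col`).
#' @param gate maximum identity-link distance in pixels.
#' @param division_radius maximum parent-to-daughter distance; default twice
#'   the mean major-axis length of the frame-n cells (40 px when lengths are
#'   unavailable).
#' @return a `frame_link` list with data.frames `links` (`from`, `to`,
#'   `distance`), `divisions` (`parent`, `child_a`, `child_b`),
#'   `disappearances` (`label`, `reason`) and `appearances` (`label`).
#' @export
link_frames <- function(obs_n, obs_n1, gate = 50, division_radius = NULL) {
  if (gate < 0) stop("gate must be non-negative")
  if (is.null(division_radius)) {
    division_radius <- if (nrow(obs_n) > 0 && "length" %in% names(obs_n))
      2 * mean(obs_n$length) else 40
  }
  obs_n <- obs_n[order(obs_n$label), , drop = FALSE]
  obs_n1 <- obs_n1[order(obs_n1$label), , drop = FALSE]
  n <- nrow(obs_n); m <- nrow(obs_n1)
  empty <- list(
    links = data.frame(from = integer(), to = integer(),
                       distance = numeric()),
    divisions = data.frame(parent = integer(), child_a = integer(),
                           child_b = integer()),
    disappearances = data.frame(label = integer(), reason = character()),
    appearances = data.frame(label = integer()))
  if (n == 0L || m == 0L) {
    out <- empty
    if (n > 0L) out$disappearances <- data.frame(
      label = obs_n$label, reason = "death")
    if (m > 0L) out$appearances <- data.frame(label = obs_n1$label)
    return(structure(out, class = "frame_link"))
  }
  D <- outer(obs_n$row, obs_n1$row, "-")^2 + outer(obs_n$col, obs_n1$col, "-")^2
  D <- sqrt(D)
  # argmin with deterministic tie-break: rows/cols are label-sorted, and
  # which.min returns the first (= lower label) of tied minima
  nn1 <- apply(D, 1L, which.min)
  nn2 <- apply(D, 2L, which.min)
  mutual <- which(nn2[nn1] == seq_len(n) & D[cbind(seq_len(n), nn1)] <= gate)
  links <- data.frame(from = obs_n$label[mutual],
                      to = obs_n1$label[nn1[mutual]],
                      distance = D[cbind(mutual, nn1[mutual])])
  used_n <- seq_len(n) %in% mutual
  used_m <- seq_len(m) %in% nn1[mutual]
  divisions <- empty$divisions
  # divisions, rule 1: an unmatched source with >= 2 unmatched next-frame
  # cells inside the division radius splits to the two nearest
  for (i in which(!used_n)) {
    cand <- which(!used_m & D[i, ] <= division_radius)
    if (length(cand) >= 2L) {
      ord <- cand[order(D[i, cand], obs_n1$label[cand])]
      ch <- sort(obs_n1$label[ord[1:2]])
      divisions <- rbind(divisions, data.frame(
        parent = obs_n$label[i], child_a = ch[1L], child_b = ch[2L]))
      used_n[i] <- TRUE
      used_m[ord[1:2]] <- TRUE
    }
  }
  # divisions, rule 2: a daughter pair is usually resolved as an identity
  # link to the nearer daughter plus one leftover cell; when a leftover
  # next-frame cell and a linked target both sit inside the division radius
  # of the same source, the link is upgraded to a division
  for (j in which(!used_m)) {
    cand <- which(D[, j] <= division_radius &
                    obs_n$label %in% links$from)
    if (length(cand) == 0L) next
    i <- cand[order(D[cand, j], obs_n$label[cand])][1L]
    k <- match(obs_n$label[i], links$from)
    sib <- match(links$to[k], obs_n1$label)
    if (D[i, sib] <= division_radius) {
      ch <- sort(c(obs_n1$label[j], obs_n1$label[sib]))
      divisions <- rbind(divisions, data.frame(
        parent = obs_n$label[i], child_a = ch[1L], child_b = ch[2L]))
      links <- links[-k, , drop = FALSE]
      used_m[j] <- TRUE
    }
  }
  dis <- empty$disappearances
  for (i in which(!used_n)) {
    reason <- if (any(D[i, ] <= gate)) "untraceable" else "death"
    dis <- rbind(dis, data.frame(label = obs_n$label[i], reason = reason))
  }
  structure(list(links = links, divisions = divisions, disappearances = dis,
                 appearances = data.frame(label = obs_n1$label[!used_m])),
            class = "frame_link")
}

#' Per-cell migration distance between hour n and hour n+1
#'
#' For every frame-n cell, the Euclidean centroid distance to its linked
#' frame-n+1 cell. A divided cell uses the nearer daughter. A cell with no
#' link ("untraceable") falls back to the globally closest frame-n+1
#' observation and is flagged as imputed. When frame n is the last frame
#' (empty `obs_n1`) the distance is absent (`NA`), not zero.
#'
#' @param obs_n,obs_n1 observation tables of frames n and n+1.
#' @param link the [link_frames()] result for this frame pair; computed when
#'   omitted.
#' @return data.frame `label`, `distance`, `imputed`.
#' @export
migration_distance <- function(obs_n, obs_n1, link = NULL) {
  if (nrow(obs_n) == 0L)
    return(data.frame(label = integer(), distance = numeric(),
                      imputed = logical()))
  if (is.null(link)) link <- link_frames(obs_n, obs_n1)
  res <- data.frame(label = sort(obs_n$label), distance = NA_real_,
                    imputed = FALSE)
  if (nrow(obs_n1) == 0L) return(res)
  dist_to <- function(from_label, to_labels) {
    i <- match(from_label, obs_n$label)
    j <- match(to_labels, obs_n1$label)
    sqrt((obs_n$row[i] - obs_n1$row[j])^2 + (obs_n$col[i] - obs_n1$col[j])^2)
  }
  for (k in seq_len(nrow(res))) {
    lab <- res$label[k]
    if (lab %in% link$links$from) {
      res$distance[k] <- link$links$distance[match(lab, link$links$from)]
    } else if (lab %in% link$divisions$parent) {
      dv <- link$divisions[match(lab, link$divisions$parent), ]
      res$distance[k] <- min(dist_to(lab, c(dv$child_a, dv$child_b)))
    } else {
      res$distance[k] <- min(dist_to(lab, obs_n1$label))
      res$imputed[k] <- TRUE
    }
  }
  res
}

#' Reconstruct the lineage forest from consecutive frame links
#'
#' Identity links concatenate observations into tracks; divisions close the
#' parent track and open two daughter tracks; appearances open new roots.
#' Every observation belongs to exactly one track.
#'
#' @param links list of [link_frames()] results for frames (1,2), (2,3), ...
#' @param obs_list list of per-frame observation tables (frame 1 first).
#' @return a `lineage_forest`: list with `tracks` (data.frame `track`,
#'   `parent_track`, `root`, `start_frame`, `end_frame`) and `map`
#'   (data.frame `frame`, `label`, `track`).
#' @export
build_lineages <- function(links, obs_list) {
  n_frames <- length(obs_list)
  stopifnot(length(links) == n_frames - 1L)
  tracks <- data.frame(track = integer(), parent_track = integer(),
                       start_frame = integer(), end_frame = integer())
  map <- vector("list", n_frames)
  next_track <- 1L
  new_track <- function(parent, start) {
    tracks <<- rbind(tracks, data.frame(
      track = next_track, parent_track = parent, start_frame = start,
      end_frame = NA_integer_))
    next_track <<- next_track + 1L
    next_track - 1L
  }
  active <- setNames(
    vapply(obs_list[[1L]]$label, function(l) new_track(NA_integer_, 1L),
           integer(1L)),
    as.character(obs_list[[1L]]$label))
  map[[1L]] <- data.frame(frame = 1L,
                          label = as.integer(names(active)),
                          track = as.integer(active))
  for (t in seq_len(n_frames - 1L)) {
    l <- links[[t]]
    src <- c(l$links$from, l$divisions$parent, l$disappearances$label)
    tgt <- c(l$links$to, l$divisions$child_a, l$divisions$child_b,
             l$appearances$label)
    if (anyDuplicated(src) || anyDuplicated(tgt))
      stop("inconsistent links at frame ", t,
           ": a cell is linked more than once")
    nxt <- integer(0); nxt_names <- character(0)
    for (k in seq_len(nrow(l$links))) {
      tr <- active[[as.character(l$links$from[k])]]
      nxt <- c(nxt, tr); nxt_names <- c(nxt_names, as.character(l$links$to[k]))
    }
    for (k in seq_len(nrow(l$divisions))) {
      ptr <- active[[as.character(l$divisions$parent[k])]]
      tracks$end_frame[tracks$track == ptr] <- t
      ta <- new_track(ptr, t + 1L); tb <- new_track(ptr, t + 1L)
      nxt <- c(nxt, ta, tb)
      nxt_names <- c(nxt_names, as.character(l$divisions$child_a[k]),
                     as.character(l$divisions$child_b[k]))
    }
    for (k in seq_len(nrow(l$disappearances))) {
      tr <- active[[as.character(l$disappearances$label[k])]]
      tracks$end_frame[tracks$track == tr] <- t
    }
    for (k in seq_len(nrow(l$appearances))) {
      ta <- new_track(NA_integer_, t + 1L)
      nxt <- c(nxt, ta)
      nxt_names <- c(nxt_names, as.character(l$appearances$label[k]))
    }
    active <- setNames(nxt, nxt_names)
    map[[t + 1L]] <- data.frame(frame = t + 1L,
                                label = as.integer(nxt_names),
                                track = as.integer(nxt))
  }
  tracks$end_frame[is.na(tracks$end_frame)] <- n_frames
  # root of each track (follow parent links)
  root_of <- tracks$track
  parent <- setNames(tracks$parent_track, tracks$track)
  for (i in seq_len(nrow(tracks))) {
    r <- tracks$track[i]
    while (!is.na(parent[[as.character(r)]])) r <- parent[[as.character(r)]]
    root_of[i] <- r
  }
  tracks$root <- root_of
  structure(list(tracks = tracks, map = do.call(rbind, map)),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat("lineage_forest:", nrow(x$tracks), "tracks,",
      sum(is.na(x$tracks$parent_track)), "roots,",
      sum(!is.na(x$tracks$parent_track)) / 2, "divisions\n")
  invisible(x)
}
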