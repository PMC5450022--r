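#' Configuration of a synthetic live-cell movie
#'
#' Defines the acquisition emulated by [generate_movie()]: frames are 60 min
#' apart (frame `t` is hour `t - 1`), cells of three morphological
#' archetypes move as an isotropic Gaussian random walk with reflecting
#' boundaries, divide and die with per-frame probabilities, and scheduled
#' lineages convert to another archetype either together with a mitosis
#' ("with-mitosis") or in place ("without-mitosis").
#'
#' @param n_frames number of frames (hours + 1).
#' @param field_size c(rows, cols) of the field in pixels.
#' @param n_initial_cells number of cells at frame 1.
#' @param archetype_mix named fractions over the three archetypes; must sum
#'   to 1.
#' @param motion_step_sd per-frame displacement standard deviation in
#'   pixels; scalar or named per archetype.
#' @param division_prob per-frame division probability; scalar or named per
#'   archetype.
#' @param apoptosis_prob per-frame death probability; scalar or named.
#' @param conversion_schedule data.frame with columns `fraction` (of initial
#'   lineages), `mode` ("with-mitosis" or "without-mitosis"), `frame_lo`,
#'   `frame_hi` (conversion frame window) and `target` (archetype converted
#'   to); may have zero rows.
#' @param shape_params per-archetype shape distributions, see
#'   [default_shape_params()].
#' @param seed integer seed; identical config and seed give bit-identical
#'   movies.
#' @return a `movie_config` object.
#' @export
movie_config <- function(n_frames = 48,
                         field_size = c(1500L, 1500L),
                         n_initial_cells = 110,
                         archetype_mix = c("MEF-like" = 1, "neuron-like" = 0,
                                           "shrunken" = 0),
                         motion_step_sd = c("MEF-like" = 3, "neuron-like" = 1.5,
                                            "shrunken" = 2),
                         division_prob = c("MEF-like" = 0.015,
                                           "neuron-like" = 0.045,
                                           "shrunken" = 0.040),
                         apoptosis_prob = 0.001,
                         conversion_schedule = data.frame(
                           fraction = c(0.25, 0.25, 0.15),
                           mode = c("with-mitosis", "without-mitosis",
                                    "without-mitosis"),
                           frame_lo = c(12, 24, 20),
                           frame_hi = c(30, 44, 40),
                           target = c("neuron-like", "neuron-like",
                                      "shrunken")),
                         shape_params = default_shape_params(),
                         seed = 20260101L) {
  arche <- c("MEF-like", "neuron-like", "shrunken")
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 3L), arche)
    if (!all(arche %in% names(x)))
      stop(what, " must be a scalar or named per archetype")
    x[arche]
  }
  stopifnot(is_count(n_frames), n_frames >= 1,
            length(field_size) == 2L, all(field_size >= 32),
            is_count(n_initial_cells), n_initial_cells >= 1)
  archetype_mix <- expand(archetype_mix, "archetype_mix")
  if (!is_prob(archetype_mix))
    stop("archetype_mix fractions must lie in [0, 1]")
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix fractions must sum to 1")
  motion_step_sd <- expand(motion_step_sd, "motion_step_sd")
  division_prob <- expand(division_prob, "division_prob")
  apoptosis_prob <- expand(apoptosis_prob, "apoptosis_prob")
  if (!is_prob(division_prob) || !is_prob(apoptosis_prob))
    stop("probabilities must lie in [0, 1]")
  stopifnot(all(motion_step_sd >= 0))
  if (nrow(conversion_schedule) > 0) {
    stopifnot(all(c("fraction", "mode", "frame_lo", "frame_hi", "target")
                  %in% names(conversion_schedule)),
              is_prob(conversion_schedule$fraction),
              all(conversion_schedule$mode %in%
                    c("with-mitosis", "without-mitosis")),
              all(conversion_schedule$target %in% arche),
              all(conversion_schedule$frame_lo >= 2),
              all(conversion_schedule$frame_hi <= n_frames),
              all(conversion_schedule$frame_lo <= conversion_schedule$frame_hi),
              sum(conversion_schedule$fraction) <= 1 + 1e-9)
  }
  structure(list(n_frames = as.integer(n_frames),
                 field_size = as.integer(field_size),
                 n_initial_cells = as.integer(n_initial_cells),
                 archetype_mix = archetype_mix,
                 motion_step_sd = motion_step_sd,
                 division_prob = division_prob,
                 apoptosis_prob = apoptosis_prob,
                 conversion_schedule = conversion_schedule,
                 shape_params = shape_params,
                 seed = as.integer(seed)),
            class = "movie_config")
}

## Offsets of mask pixels relative to the crop centre (and bounding radius).
crop_offsets <- function(crop) {
  ctr <- (nrow(crop$mask) + 1) / 2
  px <- which(crop$mask, arr.ind = TRUE)
  npx <- which(crop$nucleus, arr.ind = TRUE)
  dr <- px[, 1L] - ctr; dc <- px[, 2L] - ctr
  list(dr = dr, dc = dc,
       ndr = npx[, 1L] - ctr, ndc = npx[, 2L] - ctr,
       radius = sqrt(max(dr^2 + dc^2)),
       features = crop$features)
}

#' Generate a synthetic time-lapse movie with ground truth
#'
#' Produces `n_frames` label images (one distinct integer label per cell;
#' a matching nucleus label image) together with the full ground truth:
#' per-cell per-frame archetype, lineage, position and displacement, plus
#' event tables for divisions, deaths and conversions, and the
#' marker-positivity flag (true for cells whose archetype is neuron-like at
#' the final frame, emulating TuJ staining).
#'
#' Cell placements are kept apart by a conservative bounding-circle test
#' (rejected placements are re-drawn and displacements damped); if cells
#' cannot be placed at all the generator fails naming the frame.
#'
#' @param config a [movie_config()].
#' @return a list of class `synthetic_movie` with elements `frames`
#'   (list of integer label matrices), `nuclei` (matching nucleus labels),
#'   `truth` (list of data.frames: `cells`, `divisions`, `deaths`,
#'   `conversions`, `tuj`) and `config`.
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  set.seed(config$seed)
  nr <- config$field_size[1L]; nc <- config$field_size[2L]
  arche <- c("MEF-like", "neuron-like", "shrunken")

  n0 <- config$n_initial_cells
  types <- sample(arche, n0, replace = TRUE, prob = config$archetype_mix)
  if (n0 <= 3) types <- rep(sample(arche, 1, prob = config$archetype_mix), n0)

  cells <- new.env(parent = emptyenv())
  cells$id <- integer(); cells$lineage <- integer()
  cells$parent <- integer(); cells$arche <- character()
  cells$r <- numeric(); cells$c <- numeric()
  cells$offs <- list()
  next_id <- 1L

  radius_of <- function(i) cells$offs[[i]]$radius
  # conservative bounding-circle test; `factor` < 1 relaxes it when space
  # is tight (circles overestimate the footprint of elongated cells)
  collides <- function(r, c, rad, exclude = integer(), factor = 1) {
    if (length(cells$id) == 0L) return(FALSE)
    keep <- !(seq_along(cells$id) %in% exclude)
    if (!any(keep)) return(FALSE)
    rr <- cells$r[keep]; cc <- cells$c[keep]
    rads <- vapply(which(keep), radius_of, numeric(1L))
    any((rr - r)^2 + (cc - c)^2 < (factor * (rads + rad) + 1)^2)
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  # pixel-accurate free-space test: TRUE when the candidate mask, placed at
  # (r, c), overlaps no painted pixel of any other cell (touching allowed;
  # labels stay distinct). Used when the circle test finds no room inside
  # contact-dense clusters.
  pixels_free <- function(r, c, off, exclude = integer()) {
    rr <- round(r) + round(off$dr); cc <- round(c) + round(off$dc)
    rmin <- min(rr); cmin <- min(cc)
    win <- matrix(FALSE, max(rr) - rmin + 1L, max(cc) - cmin + 1L)
    for (j in seq_along(cells$id)) {
      if (j %in% exclude) next
      oj <- cells$offs[[j]]
      if ((cells$r[j] - r)^2 + (cells$c[j] - c)^2 >
          (oj$radius + off$radius + 2)^2) next
      jr <- round(cells$r[j]) + round(oj$dr)
      jc <- round(cells$c[j]) + round(oj$dc)
      inw <- jr >= rmin & jr <= nrow(win) + rmin - 1L &
        jc >= cmin & jc <= ncol(win) + cmin - 1L
      win[cbind(jr[inw] - rmin + 1L, jc[inw] - cmin + 1L)] <- TRUE
    }
    !any(win[cbind(rr - rmin + 1L, cc - cmin + 1L)])
  }
  masks_disjoint <- function(ra, ca, off_a, rb, cb, off_b) {
    ka <- (round(ra) + round(off_a$dr)) * 1e5 + round(ca) + round(off_a$dc)
    kb <- (round(rb) + round(off_b$dr)) * 1e5 + round(cb) + round(off_b$dc)
    !any(ka %in% kb)
  }

  add_cell <- function(lineage, parent, archetype, r, c) {
    crop <- render_archetype(archetype, config$shape_params)
    off <- crop_offsets(crop)
    rad <- off$radius
    r <- clamp(r, rad + 1, nr - rad - 1)
    c <- clamp(c, rad + 1, nc - rad - 1)
    i <- length(cells$id) + 1L
    cells$id[i] <- next_id; cells$lineage[i] <- lineage
    cells$parent[i] <- parent; cells$arche[i] <- archetype
    cells$r[i] <- r; cells$c[i] <- c
    cells$offs[[i]] <- off
    next_id <<- next_id + 1L
    i
  }

  # --- initial placement (dart throwing over the field) -------------------
  for (k in seq_len(n0)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      crop <- render_archetype(types[k], config$shape_params)
      off <- crop_offsets(crop)
      rad <- off$radius
      r <- runif(1, rad + 1, nr - rad - 1)
      c <- runif(1, rad + 1, nc - rad - 1)
      # seed with extra breathing room so later daughters find space
      if (!collides(r, c, rad + 20)) {
        i <- length(cells$id) + 1L
        cells$id[i] <- next_id; cells$lineage[i] <- next_id
        cells$parent[i] <- NA_integer_; cells$arche[i] <- types[k]
        cells$r[i] <- r; cells$c[i] <- c; cells$offs[[i]] <- off
        next_id <- next_id + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("overcrowded: cannot place initial cell ", k, " at frame 1")
  }

  # --- conversion assignment ---------------------------------------------
  sched <- config$conversion_schedule
  conv_plan <- data.frame(lineage = integer(), frame = integer(),
                          mode = character(), target = character())
  if (nrow(sched) > 0) {
    pool <- cells$id  # initial lineage ids
    for (s in seq_len(nrow(sched))) {
      n_conv <- round(sched$fraction[s] * n0)
      n_conv <- min(n_conv, length(pool))
      if (n_conv == 0) next
      chosen <- if (length(pool) == 1L) pool else sample(pool, n_conv)
      pool <- setdiff(pool, chosen)
      frames <- sample(seq(sched$frame_lo[s], sched$frame_hi[s]),
                       n_conv, replace = TRUE)
      conv_plan <- rbind(conv_plan, data.frame(
        lineage = chosen, frame = frames, mode = sched$mode[s],
        target = sched$target[s]))
    }
  }
  conv_plan$done <- rep(FALSE, nrow(conv_plan))

  # --- simulate ----------------------------------------------------------
  frames <- vector("list", config$n_frames)
  nuclei <- vector("list", config$n_frames)
  truth_cells <- vector("list", config$n_frames)
  divisions <- list(); deaths <- list(); conversions <- list()

  paint <- function() {
    f <- matrix(0L, nr, nc); g <- matrix(0L, nr, nc)
    for (i in seq_along(cells$id)) {
      o <- cells$offs[[i]]
      rr <- round(cells$r[i]); cc <- round(cells$c[i])
      f[cbind(rr + round(o$dr), cc + round(o$dc))] <- cells$id[i]
      g[cbind(rr + round(o$ndr), cc + round(o$ndc))] <- cells$id[i]
    }
    list(f, g)
  }

  snapshot <- function(t, prev_pos) {
    disp <- rep(NA_real_, length(cells$id))
    if (!is.null(prev_pos)) {
      m <- match(cells$id, prev_pos$id)
      ok <- !is.na(m)
      disp[ok] <- sqrt((cells$r[ok] - prev_pos$r[m[ok]])^2 +
                         (cells$c[ok] - prev_pos$c[m[ok]])^2)
    }
    data.frame(frame = t, cell = cells$id, lineage = cells$lineage,
               parent = cells$parent, archetype = cells$arche,
               row = cells$r - 1, col = cells$c - 1, displacement = disp)
  }

  pf <- paint()
  frames[[1L]] <- pf[[1L]]; nuclei[[1L]] <- pf[[2L]]
  truth_cells[[1L]] <- snapshot(1L, NULL)

  for (t in seq_len(config$n_frames)[-1L]) {
    prev_pos <- data.frame(id = cells$id, r = cells$r, c = cells$c)

    # apoptosis
    if (any(config$apoptosis_prob > 0) && length(cells$id) > 0) {
      p_die <- config$apoptosis_prob[cells$arche]
      die <- runif(length(cells$id)) < p_die
      if (any(die)) {
        deaths[[length(deaths) + 1L]] <-
          data.frame(frame = t, cell = cells$id[die])
        keep <- !die
        cells$id <- cells$id[keep]; cells$lineage <- cells$lineage[keep]
        cells$parent <- cells$parent[keep]; cells$arche <- cells$arche[keep]
        cells$r <- cells$r[keep]; cells$c <- cells$c[keep]
        cells$offs <- cells$offs[keep]
      }
    }

    # scheduled conversions due this frame (with-mitosis conversions whose
    # division found no room stay pending and retry next frame)
    due_idx <- which(!conv_plan$done & conv_plan$frame <= t)
    force_div <- integer(); force_target <- character()
    force_plan <- integer()
    for (si in due_idx) {
      due <- conv_plan[si, , drop = FALSE]
      members <- which(cells$lineage == due$lineage &
                         cells$arche != due$target)
      if (length(members) == 0L) {
        conv_plan$done[si] <- TRUE  # lineage extinct or already converted
        next
      }
      i <- if (length(members) == 1L) members else sample(members, 1L)
      if (due$mode == "without-mitosis") {
        old <- cells$arche[i]
        cells$arche[i] <- due$target
        crop <- render_archetype(due$target, config$shape_params)
        cells$offs[[i]] <- crop_offsets(crop)
        rad <- radius_of(i)
        r2 <- clamp(cells$r[i], rad + 1, nr - rad - 1)
        c2 <- clamp(cells$c[i], rad + 1, nc - rad - 1)
        # the new shape may be bulkier; nudge until it fits (the circle
        # test is conservative, so a final non-fit is tolerated)
        for (try in seq_len(20L)) {
          if (!collides(r2, c2, rad, exclude = i, factor = 0.85) ||
              pixels_free(r2, c2, cells$offs[[i]], exclude = i)) break
          r2 <- clamp(cells$r[i] + rnorm(1, 0, 6), rad + 1, nr - rad - 1)
          c2 <- clamp(cells$c[i] + rnorm(1, 0, 6), rad + 1, nc - rad - 1)
        }
        cells$r[i] <- r2; cells$c[i] <- c2
        conversions[[length(conversions) + 1L]] <- data.frame(
          frame = t, cell = cells$id[i], lineage = cells$lineage[i],
          mode = "without-mitosis", from = old, to = due$target)
        conv_plan$done[si] <- TRUE
      } else {
        force_div <- c(force_div, cells$id[i])
        force_target <- c(force_target, due$target)
        force_plan <- c(force_plan, si)
      }
    }

    # divisions (spontaneous + conversion-forced)
    if (length(cells$id) > 0) {
      p_div <- config$division_prob[cells$arche]
      divide <- runif(length(cells$id)) < p_div
      divide[cells$id %in% force_div] <- TRUE
      div_idx <- which(divide)
      for (i in div_idx) {
        pid <- cells$id[i]
        old_arche <- cells$arche[i]
        target <- if (pid %in% force_div)
          force_target[match(pid, force_div)] else cells$arche[i]
        placed <- FALSE
        crop_a <- render_archetype(target, config$shape_params)
        crop_b <- render_archetype(target, config$shape_params)
        off_a <- crop_offsets(crop_a); off_b <- crop_offsets(crop_b)
        n_ang <- 24L
        ang0 <- runif(1, 0, 2 * pi)
        grid <- expand.grid(ang = ang0 + 2 * pi * seq_len(n_ang) / n_ang,
                            mult = c(1, 1.3, 1.6, 2),
                            relax = c(1, 0.85, 0))
        grid <- grid[order(-grid$relax, grid$mult), , drop = FALSE]
        for (try in seq_len(nrow(grid))) {
          relax <- grid$relax[try]
          ang <- grid$ang[try]
          d <- ((off_a$radius + off_b$radius) / 2 + 1.5) * grid$mult[try]
          ra <- clamp(cells$r[i] + d * cos(ang), off_a$radius + 1,
                      nr - off_a$radius - 1)
          ca <- clamp(cells$c[i] + d * sin(ang), off_a$radius + 1,
                      nc - off_a$radius - 1)
          rb <- clamp(cells$r[i] - d * cos(ang), off_b$radius + 1,
                      nr - off_b$radius - 1)
          cb <- clamp(cells$c[i] - d * sin(ang), off_b$radius + 1,
                      nc - off_b$radius - 1)
          ok <- if (relax > 0) {
            (ra - rb)^2 + (ca - cb)^2 >=
              (relax * (off_a$radius + off_b$radius) + 1)^2 &&
              !collides(ra, ca, off_a$radius, exclude = i, factor = relax) &&
              !collides(rb, cb, off_b$radius, exclude = i, factor = relax)
          } else {
            # relax == 0: pixel-accurate pass for contact-dense clusters
            masks_disjoint(ra, ca, off_a, rb, cb, off_b) &&
              pixels_free(ra, ca, off_a, exclude = i) &&
              pixels_free(rb, cb, off_b, exclude = i)
          }
          if (ok) {
            # replace parent slot with daughter a, append daughter b
            lin <- cells$lineage[i]
            ca_id <- next_id; next_id <- next_id + 1L
            cb_id <- next_id; next_id <- next_id + 1L
            cells$id[i] <- ca_id; cells$parent[i] <- pid
            cells$arche[i] <- target
            cells$r[i] <- ra; cells$c[i] <- ca; cells$offs[[i]] <- off_a
            j <- length(cells$id) + 1L
            cells$id[j] <- cb_id; cells$lineage[j] <- lin
            cells$parent[j] <- pid; cells$arche[j] <- target
            cells$r[j] <- rb; cells$c[j] <- cb; cells$offs[[j]] <- off_b
            divisions[[length(divisions) + 1L]] <- data.frame(
              frame = t, parent = pid, child_a = ca_id, child_b = cb_id)
            if (pid %in% force_div) {
              conversions[[length(conversions) + 1L]] <- data.frame(
                frame = t, cell = pid, lineage = lin, mode = "with-mitosis",
                from = old_arche, to = target)
              conv_plan$done[force_plan[match(pid, force_div)]] <- TRUE
            }
            placed <- TRUE
            break
          }
        }
        # contact inhibition: when no placement exists the division simply
        # does not happen this frame (a pending with-mitosis conversion
        # retries on later frames)
      }
    }

    # motion (new daughters were placed this frame; they also take a step,
    # which keeps the walk homogeneous across cells)
    if (length(cells$id) > 0) {
      sds <- config$motion_step_sd[cells$arche]
      step_r <- rnorm(length(cells$id), 0, sds)
      step_c <- rnorm(length(cells$id), 0, sds)
      for (i in seq_along(cells$id)) {
        rad <- radius_of(i)
        for (damp in c(1, 0.5, 0.25, 0)) {
          r2 <- clamp(cells$r[i] + damp * step_r[i], rad + 1, nr - rad - 1)
          c2 <- clamp(cells$c[i] + damp * step_c[i], rad + 1, nc - rad - 1)
          if (!collides(r2, c2, rad, exclude = i)) {
            cells$r[i] <- r2; cells$c[i] <- c2
            break
          }
        }
      }
    }

    pf <- paint()
    frames[[t]] <- pf[[1L]]; nuclei[[t]] <- pf[[2L]]
    truth_cells[[t]] <- snapshot(t, prev_pos)
  }

  cells_df <- do.call(rbind, truth_cells)
  final <- cells_df[cells_df$frame == config$n_frames, , drop = FALSE]
  tuj <- data.frame(cell = final$cell,
                    tuj = final$archetype == "neuron-like")
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  structure(list(
    frames = frames, nuclei = nuclei,
    truth = list(
      cells = cells_df,
      divisions = bind0(divisions, data.frame(frame = integer(),
                                              parent = integer(),
                                              child_a = integer(),
                                              child_b = integer())),
      deaths = bind0(deaths, data.frame(frame = integer(), cell = integer())),
      conversions = bind0(conversions, data.frame(
        frame = integer(), cell = integer(), lineage = integer(),
        mode = character(), from = character(), to = character())),
      tuj = tuj),
    config = config), class = "synthetic_movie")
}

#' @export
print.synthetic_movie <- function(x, ...) {
  counts <- table(factor(x$truth$cells$frame, levels = seq_along(x$frames)))
  cat("synthetic_movie:", length(x$frames), "frames,",
      x$config$field_size[1L], "x", x$config$field_size[2L], "px\n")
  cat("  cells: frame 1 =", counts[1L], ", final =",
      counts[length(counts)], "\n")
  cat("  divisions:", nrow(x$truth$divisions),
      " deaths:", nrow(x$truth$deaths),
      " conversions:", nrow(x$truth$conversions), "\n")
  invisible(x)
}
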