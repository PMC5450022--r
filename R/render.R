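## Rasterisation of the three morphological archetypes. All shapes are drawn
## on a small odd-sized crop centred on the cell; the movie generator pastes
## the crop into the frame at the cell position.

## Filled ellipse mask: semi-axes a >= b (pixels), orientation theta
## (radians, counter-clockwise from the row axis of the major axis).
raster_ellipse <- function(a, b, theta = 0) {
  half <- ceiling(a) + 2L
  n <- 2L * half + 1L
  ctr <- half + 1
  rows <- matrix(seq_len(n) - ctr, n, n)
  cols <- t(rows)
  u <- rows * cos(theta) + cols * sin(theta)
  v <- -rows * sin(theta) + cols * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

## Draw a thick ray of `len` pixels from `from` (row, col) at `angle` into an
## existing mask, width `w` pixels. Steps at sub-pixel resolution so the ray
## is 8-connected.
draw_ray <- function(mask, from, angle, len, w = 2) {
  n <- nrow(mask)
  ts <- seq(0, len, by = 0.4)
  r <- from[1L] + ts * cos(angle)
  c <- from[2L] + ts * sin(angle)
  half <- (w - 1) / 2
  for (dr in seq(-half, half, by = 1)) {
    for (dc in seq(-half, half, by = 1)) {
      ri <- round(r + dr); ci <- round(c + dc)
      ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
      mask[cbind(ri[ok], ci[ok])] <- TRUE
    }
  }
  mask
}

## Grow/shrink a crop so both masks fit in an odd square of side `side`.
pad_crop <- function(mask, side) {
  n <- nrow(mask)
  if (n == side) return(mask)
  out <- matrix(FALSE, side, side)
  off <- (side - n) %/% 2L
  out[(off + 1L):(off + n), (off + 1L):(off + n)] <- mask
  out
}

#' Default per-archetype shape parameters
#'
#' Areas are in squared pixels; `lw` is the target length-to-width ratio of
#' the cell body; `nucleus_frac` the fraction of cell area occupied by the
#' nucleus; neuron-like cells additionally carry neurite count and length
#' distributions. These defaults define archetypes that satisfy the
#' classification rules: MEF-like large with a dim nucleus (below 1:10),
#' neuron-like elongated with protruding neurites, shrunken small and round
#' with a prominent nucleus (over 1:5).
#'
#' @return named list of per-archetype parameter lists.
#' @export
default_shape_params <- function() {
  list(
    "MEF-like" = list(area_mean = 1200, area_sd = 110, lw_mean = 2.5,
                      lw_sd = 0.4, nucleus_frac = 0.06),
    "neuron-like" = list(soma_area_mean = 150, soma_area_sd = 25,
                         soma_lw = 3, neurite_count_range = c(2L, 4L),
                         neurite_len_mean = 22, neurite_len_sd = 3,
                         neurite_width = 2, nucleus_frac = 0.25),
    "shrunken" = list(area_mean = 120, area_sd = 20, lw_mean = 1.15,
                      lw_sd = 0.1, nucleus_frac = 0.30)
  )
}

render_once <- function(archetype, p) {
  if (archetype == "neuron-like") {
    area <- max(60, rnorm(1, p$soma_area_mean, p$soma_area_sd))
    ratio <- p$soma_lw
    b <- sqrt(area / (pi * ratio)); a <- ratio * b
    theta <- runif(1, 0, pi)
    nneur <- sample(seq(p$neurite_count_range[1L], p$neurite_count_range[2L]),
                    1L)
    lens <- pmax(12, rnorm(nneur, p$neurite_len_mean, p$neurite_len_sd))
    side <- 2L * (ceiling(a + max(lens)) + 3L) + 1L
    mask <- pad_crop(raster_ellipse(a, b, theta), side)
    ctr <- c((side + 1) / 2, (side + 1) / 2)
    # two main neurites extend the major axis (opposite directions, small
    # jitter); any extra ones leave at shallow angles so elongation is kept
    angles <- c(theta + runif(1, -0.15, 0.15),
                theta + pi + runif(1, -0.15, 0.15))
    if (nneur > 2L) {
      extra <- sample(c(theta + runif(1, 0.3, 0.6),
                        theta + pi - runif(1, 0.3, 0.6),
                        theta - runif(1, 0.3, 0.6),
                        theta + pi + runif(1, 0.3, 0.6)))[seq_len(nneur - 2L)]
      angles <- c(angles, extra)
      lens[seq(3L, nneur)] <- pmin(lens[seq(3L, nneur)], 16)
    }
    starts_r <- ctr[1L] + (a - 1) * cos(angles) * 0.9
    starts_c <- ctr[2L] + (a - 1) * sin(angles) * 0.9
    for (k in seq_len(nneur)) {
      mask <- draw_ray(mask, c(starts_r[k], starts_c[k]), angles[k],
                       lens[k], w = p$neurite_width)
    }
    nuc_r <- sqrt(area * p$nucleus_frac / pi)
    nuc <- pad_crop(raster_ellipse(nuc_r + 0.5, nuc_r * 0.9 + 0.5, theta),
                    side)
  } else {
    area <- max(40, rnorm(1, p$area_mean, p$area_sd))
    ratio <- max(1, rnorm(1, p$lw_mean, p$lw_sd))
    if (archetype == "shrunken") ratio <- min(ratio, 1.3)
    b <- sqrt(area / (pi * ratio)); a <- ratio * b
    theta <- runif(1, 0, pi)
    mask <- raster_ellipse(a, b, theta)
    side <- nrow(mask)
    nuc_area <- area * p$nucleus_frac
    nr <- sqrt(nuc_area * ratio / pi); nb <- nuc_area / (pi * nr)
    nuc <- pad_crop(raster_ellipse(nr, nb, theta), side)
  }
  list(mask = mask, nucleus = nuc & mask)
}

#' Render one archetype cell mask (with nucleus)
#'
#' Draws a cell of the requested archetype from the shape-parameter
#' distributions and verifies the measured features against the archetype's
#' classification contract: neuron-like masks must measure length-to-width
#' > 5 with at least two neurites, shrunken masks < 1.5 with a
#' nucleus-to-cytosol ratio over 1:5, MEF-like masks below 1:10. Off-contract
#' draws are redrawn; parameters that cannot satisfy the contract raise an
#' error rather than silently emitting an off-contract mask.
#'
#' @param archetype one of `"MEF-like"`, `"neuron-like"`, `"shrunken"`.
#' @param shape_params per-archetype parameters, see
#'   [default_shape_params()].
#' @param thresholds the [class_thresholds()] the masks must satisfy.
#' @param max_tries redraw budget before failing.
#' @return list with logical matrices `mask` and `nucleus` (odd square
#'   crops) and the measured `features` row.
#' @export
render_archetype <- function(archetype, shape_params = default_shape_params(),
                             thresholds = class_thresholds(),
                             max_tries = 25L) {
  archetype <- match.arg(archetype, c("MEF-like", "neuron-like", "shrunken"))
  p <- shape_params[[archetype]]
  if (is.null(p)) stop("no shape parameters for archetype ", archetype)
  for (try in seq_len(max_tries)) {
    cand <- render_once(archetype, p)
    if (max(EBImage::bwlabel(matrix(as.numeric(cand$mask),
                                    nrow(cand$mask)))) != 1L) next
    f <- shape_features(cand$mask, cand$nucleus,
                        min_neurite_len = thresholds$min_neurite_len)
    if (classify_cell(f, thresholds) == archetype) {
      cand$features <- f
      return(cand)
    }
  }
  stop("shape parameters cannot satisfy the ", archetype,
       " archetype contract after ", max_tries, " draws")
}
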