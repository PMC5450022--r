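#' Classification thresholds for the three morphology classes
#'
#' Cells are classified by rules applied in fixed order, first match wins:
#' neuron-like (length-to-width ratio over `lw_neuron` and at least
#' `min_neurites` neurite outgrowths), then shrunken (small size, nearly
#' spherical shape with length-to-width below `lw_shrunken`, and
#' nucleus-to-cytosol ratio above `nc_shrunken`, i.e. over 1:5), then
#' MEF-like (large size and nucleus-to-cytosol below `nc_mef`, i.e. below
#' 1:10). Anything else is unclassified.
#'
#' The size cut-offs `area_small`/`area_large` are in squared pixels; the
#' defaults sit between the area modes of the synthetic archetypes (see the
#' package vignette) because no physical pixel scale is assumed.
#'
#' @param lw_neuron minimum length-to-width ratio for neuron-like calls.
#' @param min_neurites minimum neurite count for neuron-like calls.
#' @param lw_shrunken maximum length-to-width ratio for shrunken calls.
#' @param nc_shrunken minimum nucleus-to-cytosol ratio for shrunken calls.
#' @param nc_mef maximum nucleus-to-cytosol ratio for MEF-like calls.
#' @param area_small maximum area (px^2) for "small" (shrunken) cells.
#' @param area_large minimum area (px^2) for "large" (MEF-like) cells.
#' @param min_neurite_len minimum skeleton-path length (px) for a neurite.
#' @return an object of class `class_thresholds`.
#' @export
class_thresholds <- function(lw_neuron = 5, min_neurites = 2,
                             lw_shrunken = 1.5, nc_shrunken = 0.2,
                             nc_mef = 0.1, area_small = 400,
                             area_large = 800, min_neurite_len = 5) {
  stopifnot(lw_neuron > lw_shrunken, lw_shrunken >= 1,
            nc_mef > 0, nc_mef < nc_shrunken,
            area_small < area_large, min_neurites >= 1,
            min_neurite_len >= 0)
  structure(list(lw_neuron = lw_neuron, min_neurites = min_neurites,
                 lw_shrunken = lw_shrunken, nc_shrunken = nc_shrunken,
                 nc_mef = nc_mef, area_small = area_small,
                 area_large = area_large,
                 min_neurite_len = min_neurite_len),
            class = "class_thresholds")
}

#' The four morphology class labels
#' @export
MORPH_CLASSES <- c("neuron-like", "shrunken", "MEF-like", "unclassified")

#' Shape features of a single cell mask
#'
#' Computes the features used by the morphology rules: area, perimeter
#' (number of 4-neighbour mask/background transitions), the geometric
#' gravity centre (unweighted mean of member pixel coordinates),
#' ellipse-equivalent axis lengths (`4 * sqrt(eigenvalue)` of the pixel
#' coordinate covariance, with a +1/12 diagonal term for finite pixel
#' extent), the length-to-width ratio, the neurite count
#' (see [count_neurites()]) and, when a nucleus mask is supplied, the
#' nucleus area and nucleus-to-cytosol area ratio
#' `nucleus_area / (area - nucleus_area)`.
#'
#' A one-pixel mask uses the convention length = width = 1 and zero
#' neurites.
#'
#' @param mask logical matrix, one connected component.
#' @param nucleus_mask optional logical matrix (same dimensions) marking the
#'   nucleus pixels of this cell.
#' @param min_neurite_len minimum neurite length in pixels.
#' @param neurites set `FALSE` to skip neurite counting.
#' @return a one-row `data.frame` of features.
#' @export
shape_features <- function(mask, nucleus_mask = NULL, min_neurite_len = 5,
                           neurites = TRUE) {
  stopifnot(length(dim(mask)) == 2L)
  mask <- mask > 0
  px <- which(mask, arr.ind = TRUE)
  area <- nrow(px)
  if (area == 0L) stop("empty mask")
  centroid <- colMeans(px)
  # perimeter: count of (pixel in mask, 4-neighbour outside) transitions
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  i <- 2:(nrow(mask) + 1L); j <- 2:(ncol(mask) + 1L)
  perim <- sum(pad[i, j] & !pad[i - 1L, j]) + sum(pad[i, j] & !pad[i + 1L, j]) +
    sum(pad[i, j] & !pad[i, j - 1L]) + sum(pad[i, j] & !pad[i, j + 1L])
  if (area == 1L) {
    len <- 1; wid <- 1
  } else {
    cv <- stats::cov(px) * (area - 1) / area + diag(1 / 12, 2L)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    len <- 4 * sqrt(max(ev[1L], 0))
    wid <- 4 * sqrt(max(ev[2L], 0))
  }
  n_neur <- if (neurites) count_neurites(mask, min_len = min_neurite_len)
  else NA_integer_
  nuc_area <- NA_real_; nc <- NA_real_
  if (!is.null(nucleus_mask)) {
    nuc_area <- sum(nucleus_mask > 0 & mask)
    cyt <- area - nuc_area
    nc <- if (cyt > 0) nuc_area / cyt else Inf
  }
  data.frame(row = centroid[1L], col = centroid[2L], area = area,
             perimeter = perim, perimeter_to_area = perim / area,
             length = len, width = wid, length_to_width = len / wid,
             neurite_count = n_neur, nucleus_area = nuc_area,
             nucleus_to_cytosol = nc)
}

#' Detect cells in a frame and compute their shape features
#'
#' The frame may be a label image (each cell a distinct positive integer) or
#' a binary image, in which case 8-connected components are labelled
#' internally. One observation is returned per region of at least
#' `min_area` pixels, sorted by label. Centroids are the unweighted means of
#' member pixel coordinates ("geometric gravity centres"), 0-based,
#' in (row, col) order.
#'
#' @param frame 2-D integer label image or binary image.
#' @param nucleus optional 2-D image of nucleus labels/masks, same size.
#' @param min_area minimum region area in pixels.
#' @param min_neurite_len minimum neurite length in pixels.
#' @param neurites set `FALSE` to skip neurite counting (`neurite_count`
#'   becomes `NA`); useful when only centroids/axes are needed.
#' @return a `data.frame` with one row per cell: `label`, centroid
#'   `row`/`col` (0-based pixel coordinates), and the [shape_features()]
#'   columns.
#' @export
detect_cells <- function(frame, nucleus = NULL, min_area = 5,
                         min_neurite_len = 5, neurites = TRUE) {
  if (length(dim(frame)) != 2L)
    stop("frame must be a 2-D image, got ", length(dim(frame)), " dimensions")
  if (!is.null(nucleus)) stopifnot(all(dim(nucleus) == dim(frame)))
  if (max(frame) <= 1) {
    frame <- EBImage::bwlabel(matrix(as.numeric(frame > 0), nrow(frame)))
  }
  nr <- nrow(frame)
  idx <- which(frame != 0)
  pix <- split(idx, frame[idx])
  npix <- if (!is.null(nucleus)) {
    nidx <- which(nucleus != 0)
    split(nidx, nucleus[nidx])
  }
  labels <- sort(as.numeric(names(pix)))
  out <- vector("list", length(labels))
  keep <- logical(length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    p <- pix[[as.character(lab)]]
    if (length(p) < min_area) next
    pr <- (p - 1L) %% nr + 1L
    pc <- (p - 1L) %/% nr + 1L
    r0 <- range(pr); c0 <- range(pc)
    crop <- matrix(FALSE, r0[2L] - r0[1L] + 1L, c0[2L] - c0[1L] + 1L)
    crop[cbind(pr - r0[1L] + 1L, pc - c0[1L] + 1L)] <- TRUE
    ncrop <- NULL
    if (!is.null(nucleus)) {
      np <- npix[[as.character(lab)]]
      ncrop <- matrix(FALSE, nrow(crop), ncol(crop))
      if (!is.null(np) && length(np)) {
        nrw <- (np - 1L) %% nr + 1L
        ncl <- (np - 1L) %/% nr + 1L
        inb <- nrw >= r0[1L] & nrw <= r0[2L] & ncl >= c0[1L] & ncl <= c0[2L]
        ncrop[cbind(nrw[inb] - r0[1L] + 1L, ncl[inb] - c0[1L] + 1L)] <- TRUE
      }
    }
    f <- shape_features(crop, ncrop, min_neurite_len = min_neurite_len,
                        neurites = neurites)
    # back to frame coordinates, 0-based
    f$row <- f$row + r0[1L] - 2
    f$col <- f$col + c0[1L] - 2
    out[[k]] <- cbind(data.frame(label = lab), f)
    keep[k] <- TRUE
  }
  if (!any(keep)) {
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area = numeric(), perimeter = numeric(),
                      perimeter_to_area = numeric(), length = numeric(),
                      width = numeric(), length_to_width = numeric(),
                      neurite_count = integer(), nucleus_area = numeric(),
                      nucleus_to_cytosol = numeric()))
  }
  res <- do.call(rbind, out[keep])
  rownames(res) <- NULL
  res
}

#' Classify one cell observation into a morphology class
#'
#' Rules are evaluated in order neuron-like, shrunken, MEF-like; the first
#' match wins and anything else is "unclassified". Rules that need
#' nucleus features cannot fire when those features are missing.
#'
#' @param obs a one-row data.frame (or list) with at least
#'   `length_to_width`, `neurite_count`, `area`, and optionally
#'   `nucleus_to_cytosol`.
#' @param thresholds a [class_thresholds()] object.
#' @return one of `r paste(MORPH_CLASSES, collapse=", ")`.
#' @export
classify_cell <- function(obs, thresholds = class_thresholds()) {
  t <- thresholds
  lw <- obs$length_to_width
  nc <- obs$nucleus_to_cytosol %||% NA_real_
  if (!is.na(lw) && lw > t$lw_neuron &&
      !is.na(obs$neurite_count) && obs$neurite_count >= t$min_neurites)
    return("neuron-like")
  if (!is.na(lw) && lw < t$lw_shrunken && obs$area < t$area_small &&
      !is.na(nc) && nc > t$nc_shrunken)
    return("shrunken")
  if (obs$area > t$area_large && !is.na(nc) && nc < t$nc_mef)
    return("MEF-like")
  "unclassified"
}

#' Classify every observation in a table
#'
#' @param obs a data.frame from [detect_cells()].
#' @param thresholds a [class_thresholds()] object.
#' @return `obs` with an added `class` column.
#' @export
classify_cells <- function(obs, thresholds = class_thresholds()) {
  obs$class <- vapply(seq_len(nrow(obs)), function(i)
    classify_cell(obs[i, ], thresholds), character(1L))
  obs
}

#' Overlap between morphology-called and marker-positive cells
#'
#' Quantifies agreement between the cells called neuron-like by morphology
#' and the marker-positive (TuJ+) cells of the same frame. The primary
#' statistic is the Jaccard overlap `100 * |intersection| / |union|`;
#' recall against the marker set is reported alongside. Two empty sets are
#' vacuous agreement: 100%, flagged.
#'
#' @param predicted ids called neuron-like.
#' @param truth marker-positive ids.
#' @return list with `jaccard` and `recall` (percent), `n_predicted`,
#'   `n_truth`, and `both_empty`.
#' @export
marker_overlap <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  if (length(predicted) == 0L && length(truth) == 0L) {
    return(list(jaccard = 100, recall = 100, n_predicted = 0L, n_truth = 0L,
                both_empty = TRUE))
  }
  inter <- length(intersect(predicted, truth))
  uni <- length(union(predicted, truth))
  list(jaccard = 100 * inter / uni,
       recall = if (length(truth)) 100 * inter / length(truth) else NA_real_,
       n_predicted = length(predicted), n_truth = length(truth),
       both_empty = FALSE)
}
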