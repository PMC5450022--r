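## Morphological skeletonization (Zhang-Suen thinning) and skeleton-graph
## traversal. Used to count neurite outgrowths: a neurite is a skeleton
## endpoint whose along-skeleton distance from the soma (largest inscribed
## disc) exceeds a minimum length.

## Number of 8-neighbours set, per pixel, for a padded logical matrix.
neighbour_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  m[i - 1, j - 1] + m[i - 1, j] + m[i - 1, j + 1] +
    m[i, j - 1]              + m[i, j + 1] +
    m[i + 1, j - 1] + m[i + 1, j] + m[i + 1, j + 1]
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iteratively peels border pixels while preserving connectivity until the
#' mask is one pixel wide. Operates on a logical matrix; the result is a
#' logical matrix of the same dimension.
#'
#' @param mask logical (or 0/1) matrix, one connected component.
#' @return logical matrix marking skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(length(dim(mask)) == 2L)
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- m[i - 1, j];     p3 <- m[i - 1, j + 1]
      p4 <- m[i, j + 1];     p5 <- m[i + 1, j + 1]
      p6 <- m[i + 1, j];     p7 <- m[i + 1, j - 1]
      p8 <- m[i, j - 1];     p9 <- m[i - 1, j - 1]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m[i, j] & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m[i, j] & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        sub <- m[i, j]
        sub[cond] <- FALSE
        m[i, j] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

## Endpoints of a skeleton: pixels with exactly one 8-connected skeleton
## neighbour (an isolated pixel counts as an endpoint of a degenerate
## skeleton).
skeleton_endpoints <- function(skel) {
  m <- matrix(FALSE, nrow(skel) + 2L, ncol(skel) + 2L)
  m[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- skel
  nb <- neighbour_count(m)
  which(skel & (nb <= 1L), arr.ind = TRUE)
}

## Breadth-first distances along the skeleton graph (8-connectivity, unit
## steps) from a set of source pixels. Returns a matrix of distances with
## NA off-skeleton / unreachable.
skeleton_bfs <- function(skel, sources) {
  dist <- matrix(NA_real_, nrow(skel), ncol(skel))
  if (nrow(sources) == 0L) return(dist)
  queue <- sources
  dist[queue] <- 0
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  nr <- nrow(skel); nc <- ncol(skel)
  while (nrow(queue) > 0L) {
    nxt <- vector("list", 8L)
    for (k in seq_len(8L)) {
      r <- queue[, 1L] + off$dr[k]
      c <- queue[, 2L] + off$dc[k]
      ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
      r <- r[ok]; c <- c[ok]
      idx <- cbind(r, c)
      keep <- skel[idx] & is.na(dist[idx])
      if (any(keep)) {
        idx <- idx[keep, , drop = FALSE]
        d <- dist[cbind(queue[ok, 1L][keep], queue[ok, 2L][keep])] + 1
        # duplicates within a wave: first write wins, all same distance +-1
        dup <- duplicated(idx[, 1L] * (nc + 1L) + idx[, 2L])
        idx <- idx[!dup, , drop = FALSE]
        dist[idx] <- d[!dup]
        nxt[[k]] <- idx
      }
    }
    queue <- do.call(rbind, nxt)
    if (is.null(queue)) break
  }
  dist
}

#' Count neurite outgrowths of a cell mask
#'
#' The soma is taken as the largest inscribed disc of the mask (centre and
#' radius from the Euclidean distance transform). The mask is skeletonized
#' and a neurite is counted for every skeleton endpoint whose along-skeleton
#' distance from the soma exceeds `min_len` pixels.
#'
#' @param mask logical matrix, one connected component.
#' @param min_len minimum skeleton-path length (pixels) from the soma for an
#'   endpoint to count as a neurite. Default 5.
#' @return integer neurite count.
#' @export
count_neurites <- function(mask, min_len = 5) {
  mask <- mask > 0
  if (sum(mask) <= 1L) return(0L)
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  r0 <- max(dm)
  p0 <- which(dm == r0, arr.ind = TRUE)[1L, , drop = FALSE]
  # soma = disc of the largest inscribed radius around its centre
  rows <- row(mask); cols <- col(mask)
  soma <- mask & ((rows - p0[1L])^2 + (cols - p0[2L])^2 <= r0^2)
  skel <- skeletonize(mask)
  if (!any(skel)) return(0L)
  src <- which(skel & soma, arr.ind = TRUE)
  if (nrow(src) == 0L) {
    # degenerate: skeleton misses the soma disc; seed from the skeleton
    # pixel nearest the soma centre
    sk <- which(skel, arr.ind = TRUE)
    d2 <- (sk[, 1L] - p0[1L])^2 + (sk[, 2L] - p0[2L])^2
    src <- sk[which.min(d2), , drop = FALSE]
  }
  dist <- skeleton_bfs(skel, src)
  ep <- skeleton_endpoints(skel)
  if (nrow(ep) == 0L) return(0L)
  d <- dist[ep]
  sum(!is.na(d) & d > min_len)
}
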