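# Geometry fixtures built in code, plus independent oracles.

solid_rect <- function(h, w, pad = 0) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

solid_disc <- function(radius, pad = 2) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <=
    radius^2
  m
}

# disc soma with `n_rays` straight rays of length `len` leaving the rim
disc_with_rays <- function(radius = 10, n_rays = 3, len = 20, pad = 2) {
  n <- 2 * (radius + len + pad) + 1
  ctr <- radius + len + pad + 1
  m <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <=
    radius^2
  angles <- 2 * pi * seq_len(n_rays) / n_rays
  for (ang in angles) {
    t <- seq(0, radius + len - 1, by = 0.4)
    rr <- round(ctr + t * cos(ang)); cc <- round(ctr + t * sin(ang))
    m[cbind(rr, cc)] <- TRUE
  }
  m
}

# independent axis-ratio oracle: eigendecomposition of the exact pixel-set
# covariance (population, +1/12 finite-pixel term), done from scratch
oracle_axis_ratio <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  mu <- colMeans(px)
  d <- sweep(px, 2, mu)
  cv <- crossprod(d) / n + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# brute-force minimum-total-distance assignment over all permutations
oracle_assignment <- function(obs_n, obs_n1, gate) {
  n <- nrow(obs_n); m <- nrow(obs_n1)
  k <- min(n, m)
  D <- sqrt(outer(obs_n$row, obs_n1$row, "-")^2 +
              outer(obs_n$col, obs_n1$col, "-")^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  rows <- utils::combn(seq_len(n), k, simplify = FALSE)
  cols <- utils::combn(seq_len(m), k, simplify = FALSE)
  for (rs in rows) {
    for (cs in cols) {
      for (p in perms(cs)) {
        d <- D[cbind(rs, p)]
        if (any(d > gate)) next
        cost <- sum(d)
        if (cost < best_cost) {
          best_cost <- cost
          best <- data.frame(from = obs_n$label[rs], to = obs_n1$label[p])
        }
      }
    }
  }
  best
}

# exhaustive per-field nearest-centroid search (grid-sampling oracle)
oracle_grid_sample <- function(obs, bounds, k) {
  h <- bounds[1] / k; w <- bounds[2] / k
  sel <- integer()
  for (gi in seq_len(k)) {
    for (gj in seq_len(k)) {
      inside <- which(obs$row + 0.5 >= (gi - 1) * h & obs$row + 0.5 < gi * h &
                        obs$col + 0.5 >= (gj - 1) * w &
                        obs$col + 0.5 < gj * w)
      if (!length(inside)) next
      ctr <- c((gi - 0.5) * h - 0.5, (gj - 0.5) * w - 0.5)
      d <- sqrt((obs$row[inside] - ctr[1])^2 + (obs$col[inside] - ctr[2])^2)
      sel <- c(sel, obs$label[inside][order(d, obs$label[inside])[1]])
    }
  }
  sort(unique(sel))
}
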