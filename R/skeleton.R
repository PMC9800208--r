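# Binary skeletonization (Zhang-Suen thinning) and branch pruning.
# Masks are logical matrices indexed [y, x]; coordinates are pixel centers,
# origin top-left, x right / y down.

shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' @param mask Logical matrix ([y, x]).
#' @return Logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors clockwise from north: p2..p9
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# BFS over 8-connected skeleton pixels from a start index; returns distances
# (steps) and parents, both named by linear pixel index
skel_bfs <- function(coords, adj, start) {
  n <- nrow(coords)
  dist <- rep(NA_integer_, n); parent <- rep(0L, n)
  dist[start] <- 0L
  queue <- c(start); head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        parent[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Prune a skeleton to its longest simple path
#'
#' Removes side branches by extracting the longest geodesic path through the
#' skeleton (double breadth-first search: farthest pixel from an arbitrary
#' start, then farthest pixel from that one). The result is an ordered
#' polyline with no branch pixels.
#'
#' @param skel Logical skeleton matrix ([y, x]).
#' @return A data.frame with ordered columns \code{x}, \code{y} (px), or NULL
#'   for an empty skeleton.
#' @export
prune_skeleton <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  if (nrow(idx) == 1) return(data.frame(x = idx[1, 2], y = idx[1, 1]))
  coords <- idx[, c(2, 1), drop = FALSE]   # x, y
  colnames(coords) <- c("x", "y")
  # adjacency by 8-connectivity
  key <- paste(coords[, 1], coords[, 2])
  lookup <- stats::setNames(seq_len(nrow(coords)), key)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  adj <- lapply(seq_len(nrow(coords)), function(i) {
    nb <- paste(coords[i, 1] + offs$dx, coords[i, 2] + offs$dy)
    unname(lookup[nb[nb %in% key]])
  })
  b1 <- skel_bfs(coords, adj, 1L)
  far1 <- which.max(b1$dist)
  b2 <- skel_bfs(coords, adj, far1)
  far2 <- which.max(b2$dist)
  path <- far2
  while (path[1] != far1) path <- c(b2$parent[path[1]], path)
  data.frame(x = coords[path, 1], y = coords[path, 2])
}

#' Arc-length midpoint of a polyline
#'
#' @param path Data.frame with \code{x}, \code{y} columns (ordered polyline).
#' @return Named numeric \code{c(x, y)}: the point at half the cumulative arc
#'   length, linearly interpolated between vertices (sub-pixel).
#' @export
path_midpoint <- function(path) {
  n <- nrow(path)
  if (n == 1) return(c(x = path$x[1], y = path$y[1]))
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  s <- c(0, cumsum(seg))
  half <- s[n] / 2
  i <- findInterval(half, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  f <- if (seg[i] > 0) (half - s[i]) / seg[i] else 0
  c(x = path$x[i] + f * (path$x[i + 1] - path$x[i]),
    y = path$y[i] + f * (path$y[i + 1] - path$y[i]))
}
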