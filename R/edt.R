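# Exact Euclidean distance transform (squared), separable lower-envelope
# algorithm applied axis by axis with anisotropic voxel spacing. Distances
# are measured to the nearest background voxel center, in mm.

# 1-D squared-distance transform of sampled function f at spacing h
dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  h2 <- h * h
  for (q in 2:n) {
    fq <- f[q]
    repeat {
      p <- v[k]
      s <- ((fq + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    d[q] <- h2 * (q - p)^2 + f[p]
  }
  d
}

dt_axis <- function(a, axis, h, big) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col >= big) || all(col == 0)) next
    m[, j] <- dt1d(col, h)
  }
  ap <- array(m, dim(ap))
  aperm(ap, order(perm))
}

#' Euclidean distance transform of a foreground region
#'
#' @param fg logical 3-D array (TRUE = foreground / lumen).
#' @param voxel_size voxel spacing, mm.
#' @return numeric array: distance (mm) from each foreground voxel center to
#'   the nearest background voxel center (0 on background). Infinite if there
#'   is no background.
#' @export
distance_transform <- function(fg, voxel_size) {
  # large finite sentinel (greater than any attainable squared distance)
  big <- 4 * sum((dim(fg) * voxel_size)^2)
  f <- array(ifelse(fg, big, 0), dim(fg))
  for (axis in 1:3) f <- dt_axis(f, axis, voxel_size[axis], big)
  f[f >= big] <- Inf
  sqrt(f)
}
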