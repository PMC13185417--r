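# Internal helpers shared across modules.

# Neighbour offsets for 3D connectivity. `half = TRUE` returns one offset per
# unordered voxel pair (lexicographically positive), for edge-list building.
neighbor_offsets <- function(connectivity = 26, half = FALSE) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.", class = "g4quant_error")
  }
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), , drop = FALSE]
  manh <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- switch(as.character(connectivity),
    "6"  = manh == 1,
    "18" = manh <= 2,
    "26" = rep(TRUE, nrow(g))
  )
  g <- g[keep, , drop = FALSE]
  if (half) {
    pos <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
    g <- g[pos, , drop = FALSE]
  }
  as.matrix(g)
}

# Linear index into a (z, y, x) array from coordinate matrix (n x 3).
linear_index <- function(co, dm) {
  co[, 1L] + (co[, 2L] - 1L) * dm[1L] + (co[, 3L] - 1L) * dm[1L] * dm[2L]
}

in_bounds <- function(co, dm) {
  co[, 1L] >= 1L & co[, 1L] <= dm[1L] &
    co[, 2L] >= 1L & co[, 2L] <= dm[2L] &
    co[, 3L] >= 1L & co[, 3L] <= dm[3L]
}

# Robust z-score on median/MAD; identical values score 0, deviants from a
# zero-MAD population score Inf.
robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) {
    z <- ifelse(x == med, 0, Inf)
  } else {
    z <- (x - med) / s
  }
  z
}

# Dilate a set of voxel coordinates by one voxel (26-neighbourhood), returning
# unique linear indices clipped to the array.
dilate_coords <- function(co, dm) {
  offs <- rbind(c(0L, 0L, 0L), neighbor_offsets(26))
  out <- lapply(seq_len(nrow(offs)), function(i) {
    nb <- sweep(co, 2L, offs[i, ], "+")
    nb[in_bounds(nb, dm), , drop = FALSE]
  })
  unique(linear_index(do.call(rbind, out), dm))
}

check_positive_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "g4quant_error")
  }
  invisible(x)
}
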