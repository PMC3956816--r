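# 3D morphology primitives: box-filter sums, flood fill, connected
# components and hole filling. No installed R package offers these in 3D
# (EBImage is used for the 2D per-slice operations), so they are
# implemented here with cumulative sums and frontier BFS in flattened
# index space.

# sliding-window sum along the first axis, window half-width `half`,
# zero-padded at the ends
axis1_boxsum <- function(a, half) {
  d <- dim(a); n <- d[1]
  cs <- apply(a, c(2, 3), cumsum)          # n x d2 x d3 cumulative sums
  hi <- pmin(seq_len(n) + half, n)
  lo <- seq_len(n) - half - 1L
  out <- cs[hi, , , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos)) out[pos, , ] <- out[pos, , , drop = FALSE] -
      cs[lo[pos], , , drop = FALSE]
  out
}

# sum over the box with per-axis half-widths centred on each voxel
# (zero padding); half = 0 on an axis leaves it unfiltered
box_sum3 <- function(a, half) {
  half <- rep_len(half, 3)
  if (half[1] > 0) a <- axis1_boxsum(a, half[1])
  if (half[2] > 0)
    a <- aperm(axis1_boxsum(aperm(a, c(2, 1, 3)), half[2]), c(2, 1, 3))
  if (half[3] > 0)
    a <- aperm(axis1_boxsum(aperm(a, c(3, 2, 1)), half[3]), c(3, 2, 1))
  a
}

# neighbour offsets in flattened index space for an array padded so that
# frontier arithmetic cannot wrap; d are the padded dims
neighbor_offsets <- function(d, connectivity = 26) {
  sts <- c(1L, d[1], d[1] * d[2])
  offs <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
    offs <- c(offs, dx * sts[1] + dy * sts[2] + dz * sts[3])
  }
  offs
}

pad_false <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d + 2L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  out
}

unpad <- function(mask, d) mask[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]

# BFS flood: all voxels of padded `region` reachable from `seeds`
# (flattened indices into the padded array)
flood3 <- function(region, seeds, offs) {
  visited <- logical(length(region))
  seeds <- seeds[region[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0) {
    cand <- unique(as.vector(outer(frontier, offs, `+`)))
    cand <- cand[cand >= 1L & cand <= length(region)]
    cand <- cand[region[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# connected-component labels (padded-space internal); returns integer array
label_components3 <- function(mask, connectivity = 26) {
  d <- dim(mask)
  pm <- pad_false(mask)
  offs <- neighbor_offsets(dim(pm), connectivity)
  labels <- integer(length(pm))
  remaining <- which(pm)
  lab <- 0L
  while (length(remaining) > 0) {
    lab <- lab + 1L
    vis <- flood3(pm, remaining[1], offs)
    labels[vis] <- lab
    remaining <- remaining[!vis[remaining]]
  }
  array(labels, dim(pm))[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# fill 3D holes: background regions (6-connected) not reachable from the
# array border are absorbed into the mask
fill_holes3 <- function(mask) {
  d <- dim(mask)
  pm <- pad_false(mask)
  bg <- !pm
  offs <- neighbor_offsets(dim(pm), 6)
  # all padded-border voxels are background seeds
  dp <- dim(pm)
  idx <- array(seq_along(pm), dp)
  border <- c(idx[c(1, dp[1]), , ], idx[, c(1, dp[2]), ], idx[, , c(1, dp[3])])
  reach <- flood3(bg, unique(border), offs)
  filled <- pm | (bg & !array(reach, dp))
  unpad(filled, d)
}

# fill holes slice-by-slice in the axial (third-axis) planes
fill_holes_axial <- function(mask) {
  num <- mask * 1
  filled <- EBImage::fillHull(num)
  as.array(filled) > 0.5
}
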