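# Connected components of a set of voxels under 26-connectivity.
# `voxels`: linear indices into a grid of dimension `shape`.
# Returns an integer cluster label per voxel (labels are arbitrary but
# contiguous from 1), using union-find over the 13 forward neighbour
# offsets.
label_clusters <- function(voxels, shape) {
  n <- length(voxels)
  if (n == 0L) return(integer(0))
  ijk <- arrayInd(voxels, shape)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[seq_len(13L), , drop = FALSE] # forward half
  for (o in seq_len(nrow(offsets))) {
    ni <- ijk[, 1L] + offsets[o, 1L]
    nj <- ijk[, 2L] + offsets[o, 2L]
    nk <- ijk[, 3L] + offsets[o, 3L]
    ok <- ni >= 1L & ni <= shape[1L] & nj >= 1L & nj <= shape[2L] &
      nk >= 1L & nk <= shape[3L]
    lin <- ni[ok] + shape[1L] * (nj[ok] - 1L) + prod(shape[1:2]) * (nk[ok] - 1L)
    hit <- match(lin, voxels)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (m in seq_along(src)) {
      a <- find(src[m]); b <- find(dst[m])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# max cluster extent (voxel count) among suprathreshold voxels; 0 when none
max_cluster_extent <- function(voxels, shape) {
  if (length(voxels) == 0L) return(0L)
  lab <- label_clusters(voxels, shape)
  max(tabulate(lab))
}
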