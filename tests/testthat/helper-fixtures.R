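# small programmatic fixtures shared across tests

# digitized ball with its center exactly on a voxel center
ball_mask <- function(radius_vox, pad = 3L) {
  n <- 2L * (radius_vox + pad) + 1L
  ctr <- radius_vox + pad + 1L
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius_vox^2,
        c(n, n, n))
}

ball_volume <- function(radius_vox, spacing = 4.35, pad = 3L) {
  binary_volume(ball_mask(radius_vox, pad), spacing)
}

# axis-aligned slab occupying `layers` full voxel layers
slab_volume <- function(layers, nx = 40L, spacing = 4.35, pad = 6L) {
  arr <- array(FALSE, c(nx, nx, layers + 2L * pad))
  arr[, , pad + seq_len(layers)] <- TRUE
  binary_volume(arr, spacing)
}

# brute-force flood-fill component count (independent oracle for labeling)
flood_count <- function(mask, connectivity = 6) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
          c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  count <- 0
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (seen[p[1], p[2], p[3]]) next
    count <- count + 1
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    while (length(queue)) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (m in seq_len(nrow(offs))) {
        nb <- q + offs[m, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  count
}

# small isotropic foam binary for property tests
small_foam <- function(seed = 3, spacing = 4.35, extent = 400, vf = 0.35,
                       corr_length = 30) {
  rasterize_phantom(make_phantom(phantom_spec(
    "foam", extent = extent, seed = seed, vf = vf,
    corr_length = corr_length)), spacing)
}
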