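# internal helpers shared across modules

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# separable Gaussian filter with edge replication; sigma in voxels
gauss3d <- function(arr, sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(arr)
  offs <- -radius:radius
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (m in seq_along(offs)) {
      idx <- pmin(pmax(seq_len(n) + offs[m], 1L), n)
      out <- out + w[m] * switch(axis,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# quasi-uniform directions on the hemisphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smallest domain extent >= min_extent spanning an odd number of voxels, so
# the domain center falls exactly on a voxel center (removes the subvoxel
# lattice offset of centered test solids)
odd_extent <- function(min_extent, spacing) {
  n <- ceiling(min_extent / spacing)
  if (n %% 2 == 0) n <- n + 1
  n * spacing
}
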