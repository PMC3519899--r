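# Fixtures built in code: random segmentation instances, tiny line volumes,
# and simple geometric masks. All randomness is seeded by the caller.

# a random intensity volume with n_fg + n_bg randomly placed scribble voxels
random_instance <- function(shape = c(12, 12, 12), n_fg = 10L, n_bg = 10L) {
  n <- prod(shape)
  vals <- array(stats::runif(n, 0, 100), shape)
  lab <- array(0L, shape)
  idx <- sample.int(n, n_fg + n_bg)
  lab[idx[seq_len(n_fg)]] <- 1L
  lab[idx[n_fg + seq_len(n_bg)]] <- 2L
  list(image = scalar_volume(vals),
       scribbles = as_scribbles(label_map(lab)))
}

# 1x1xN line image with seeds at both ends (fg at 1, bg at N)
line_instance <- function(intensities) {
  n <- length(intensities)
  lab <- integer(n)
  lab[1L] <- 1L
  lab[n] <- 2L
  list(image = scalar_volume(array(intensities, c(1, 1, n))),
       scribbles = as_scribbles(label_map(array(lab, c(1, 1, n)))))
}

# binary label_map from a logical/integer array
as_mask <- function(arr, spacing = c(1, 1, 1)) {
  lab <- array(0L, dim(arr))
  lab[arr != 0] <- 1L
  label_map(lab, spacing = spacing, meaning = c("1" = "tumor"))
}

# solid axis-aligned cuboid mask inside a grid
cuboid_mask <- function(shape, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(0L, shape)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  as_mask(a, spacing)
}
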