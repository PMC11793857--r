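# Shared fixtures: small phantoms and brute-force oracles used across tests.

# A quick phantom at desk scale (fits grade-2 osteophytes).
small_params <- function(head_radius_mm = 12, ...) {
  phantom_params(grid_shape = c(64, 64, 64), spacing_mm = 1,
                 head_radius_mm = head_radius_mm, noise_sd_hu = 15, ...)
}

# Tiny grid for fast training smoke tests (edges divisible by 8).
tiny_params <- function(...) {
  phantom_params(grid_shape = c(32, 32, 32), spacing_mm = 1,
                 head_radius_mm = 6, noise_sd_hu = 15, ...)
}

# Exhaustive all-pairs nearest-vertex distances (oracle for cpp grid query).
brute_nn_dist <- function(query, ref) {
  apply(query, 1, function(p) sqrt(min(colSums((t(ref) - p)^2))))
}

# Exhaustive 3^3-neighbourhood edge oracle: voxel is an edge of class k when
# its 3^3 neighbourhood holds both class-k and non-class-k voxels (lower
# class wins).
brute_edges <- function(lab) {
  d <- dim(lab)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    nb <- lab[max(1, i - 1):min(d[1], i + 1),
              max(1, j - 1):min(d[2], j + 1),
              max(1, k - 1):min(d[3], k + 1)]
    for (cls in sort(unique(as.vector(lab)))) {
      if (cls == 0) next
      if (any(nb == cls) && any(nb != cls)) {
        out[i, j, k] <- cls
        break
      }
    }
  }
  out
}

# Toy model whose bottleneck has two feature maps on a 2^3 grid (one encoder
# block with a single base filter), used for activation-map oracles.
toy_cam_model <- function(seed = 1L) {
  build_model(network_config(base_filters = 1L, n_blocks = 1L), seed = seed)
}

# Random watertight-ish point cloud mesh (vertices only matter for the
# distance metrics).
random_mesh <- function(n, seed) {
  set.seed(seed)
  surface_mesh(matrix(rnorm(3 * n, sd = 10), ncol = 3),
               matrix(c(1, 2, 3), 1, 3))
}

expect_seg_shapes <- function(fw, d, k = 3) {
  expect_identical(dim(fw$md_probs), as.integer(c(d, k)))
  expect_identical(dim(fw$cd_probs), as.integer(c(d, k)))
}
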