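# Shared fixtures (built once per test run) and small independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# High-resolution phantom for the neuromast / hair-cell mask experiments
# (super-resolution-scale lateral sampling so the sigma-6 blur is small
# relative to the rosette).
fine_phantom <- function() cached("fine", function() {
  p <- stack_phantom_params(seed = 7, voxel_size_um = c(1, 0.05, 0.05),
                            shape_px = c(14, 448, 448),
                            vesicles_per_cell = c(3, 20))
  gen_neuromast_stack(p)
})

# Default-scale phantom for vesicle detection work.
vesicle_phantom <- function() cached("vesicle", function() {
  gen_neuromast_stack(stack_phantom_params(seed = 3, diffuse_fraction = 0,
                                           shape_px = c(14, 110, 110)))
})

# ground-truth cell centroids as a seed_set
gt_seeds <- function(cells_lab) {
  d <- dim(cells_lab)
  pts <- do.call(rbind, lapply(seq_len(max(cells_lab)), function(i) {
    w <- which(cells_lab == i)
    data.frame(z = round(mean((w - 1) %% d[1] + 1)),
               y = round(mean(((w - 1) %/% d[1]) %% d[2] + 1)),
               x = round(mean((w - 1) %/% (d[1] * d[2]) + 1)))
  }))
  seed_set(pts)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# independent triangle-threshold oracle: explicit point-to-line distance
# maximization on a given histogram (counts h over bin centres)
triangle_oracle <- function(h, centers) {
  pk <- which.max(h)
  nz <- which(h > 0)
  far <- if (nz[length(nz)] - pk >= pk - nz[1]) nz[length(nz)] else nz[1]
  idx <- if (pk < far) pk:far else far:pk
  hn <- h / max(h) * length(h)
  p1 <- c(pk, hn[pk]); p2 <- c(far, hn[far])
  dd <- vapply(idx, function(i) {
    abs((p2[2] - p1[2]) * i - (p2[1] - p1[1]) * hn[i] +
          p2[1] * p1[2] - p2[2] * p1[1])
  }, 1)
  centers[idx[which.max(dd)]]
}

# brute-force Pearson chi-square from a count matrix
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# brute-force two-sided permutation test on the difference of means
perm_test <- function(a, b, n_perm = 400, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), length(a))
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}
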