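# Independent oracles and fixture builders used across the suite.

# scalar breadth-first flood fill over an inclusion lattice; the slow,
# obviously-correct counterpart of region_grow_3d
flood_oracle <- function(include, seed0, connectivity = 6L) {
  d <- dim(include)
  offs <- if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    as.matrix(g[rowSums(abs(g)) > 0, ])
  }
  visited <- array(FALSE, d)
  s <- seed0 + 1L
  if (!include[s[1], s[2], s[3]]) return(visited)
  visited[s[1], s[2], s[3]] <- TRUE
  queue <- list(s)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(offs))) {
      nb <- cur + offs[k, ]
      if (any(nb < 1L) || any(nb > d)) next
      if (include[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  visited
}

# random small volume with a mix of in- and out-of-interval HU, plus a
# guaranteed in-interval seed voxel
random_volume_with_seed <- function(max_dim = 10L) {
  d <- sample(2:max_dim, 3, replace = TRUE)
  vals <- sample(c(-800L, -500L, -450L, 0L, 60L, 200L, 1500L, 1600L),
                 prod(d), replace = TRUE)
  vox <- array(vals, d)
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  ok <- which(vox >= -450 & vox <= 1500, arr.ind = TRUE)
  if (nrow(ok) == 0) return(random_volume_with_seed(max_dim))
  seed0 <- ok[sample(nrow(ok), 1), ] - 1L
  list(volume = vol, seed = as.integer(seed0))
}

# wrap a plain voxel-value vector as a unit-bin histogram over a range
# that covers it
hist_of <- function(values, bin_width = 1) {
  noduletex:::histogram_from_values(values, bin_width = bin_width,
                                    range = c(-450, 1500))
}

# a one-voxel-thick volume holding given HU values inside a -800 shell,
# fully connected along x, with the seed on the first value
line_volume <- function(values) {
  n <- length(values)
  vox <- array(-800L, c(n, 3, 3))
  vox[, 2, 2] <- as.integer(values)
  ct_volume(vox, c(1, 1, 1))
}

# ICC(2,1) through R's aov() mean squares: an independent
# variance-components route
icc21_aov_oracle <- function(a, b) {
  n <- length(a)
  dat <- data.frame(y = c(a, b),
                    subject = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = dat))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}
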