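# Shared fixtures: tiny volumes, random masks, and small network/training
# configurations that keep CPU time low.

tiny_volume <- function(shape = c(12, 10, 8), spacing = c(1, 1, 1),
                        seed = 1) {
  set.seed(seed)
  volume3d(array(stats::runif(prod(shape), 10, 100), shape), spacing)
}

random_mask <- function(shape = c(12, 10, 8), p = 0.1,
                        spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  lesion_mask(array(stats::rbinom(prod(shape), 1, p), shape), spacing)
}

test_net_config <- function(patch = c(16, 16, 16), ...) {
  network_config(base_channels = c(4, 8, 16, 32), patch_shape = patch, ...)
}

# Independent 3D connected-component labelling by breadth-first search,
# used as the oracle for the C++ labeller and the volume post-filter.
bfs_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nxt <- 0L
  for (s in which(mask > 0)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        q <- pos + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (mask[qi] > 0 && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# A joint model whose output probability is a constant, for plumbing tests.
constant_model <- function(p = 0.3, patch = c(16, 16, 16)) {
  cfg <- network_config(base_channels = c(2, 2, 2, 2), patch_shape = patch,
                        df_source = "none")
  m <- build_joint_model(cfg, seed = 1)
  m$params$seg_head$W[] <- 0
  m$params$seg_head$b[] <- log(p / (1 - p))
  m
}
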