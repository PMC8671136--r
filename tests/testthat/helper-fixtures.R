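# Shared fixtures, all generated in code.

# Small network spec for fast tests.
tinyNetSpec <- function(input_dim, seed = 1L, c_oc = 4L)
  networkSpec(input_dim, hidden_dims = c(8L, 8L, 4L, 4L), c_oc = c_oc,
              seed = seed)

# Two well-separated Gaussian classes as ready-made feature matrices.
separableFeatures <- function(n_per_class = 30L, d = 10L, sep = 3,
                              seed = 42L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d, mean = -sep / 2), n_per_class, d),
             matrix(rnorm(n_per_class * d, mean = sep / 2), n_per_class, d))
  y <- rep(c(0L, 1L), each = n_per_class)
  ord <- sample(nrow(X))
  list(X = X[ord, ], y = y[ord])
}

# Small multi-site ConnectivitySet built through the simulator.
smallSimSet <- function(n_per_site = 10L, sites = c("S1", "S2", "S3"),
                        n_rois = 10L, t_points = 80L, effect_size = 0.6,
                        seed = 7L, ...) {
  spec <- simSpec(n_rois = n_rois,
                  sites = lapply(sites, function(s)
                    simSite(s, n_per_site, t_points, ...)),
                  effect_edges = 0.2, effect_size = effect_size, seed = seed)
  sim <- simulateDataset(spec)
  list(cs = buildConnectivitySet(sim$records), mask = sim$effect_mask,
       records = sim$records)
}

# Random batch of softmax rows.
randomSoftmax <- function(n, C) {
  z <- matrix(rnorm(n * C), n, C)
  e <- exp(z)
  e / rowSums(e)
}

expect_paramsIdentical <- function(a, b, skip = NULL) {
  walk <- function(x, y, path) {
    if (is.list(x)) {
      for (i in seq_along(x))
        walk(x[[i]], y[[i]], c(path, names(x)[i]))
    } else if (is.null(skip) || !identical(path[1:2], skip)) {
      expect_identical(x, y,
                       label = paste(path, collapse = "$"))
    }
  }
  walk(a, b, character(0))
}
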